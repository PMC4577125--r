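# Readers and writers for the on-disk dialects: TSV matrices (first column
# feature ID, header row of sample IDs), two-column group labels, 3-column
# weighted edge lists, GMT memberships plus 4-column signed topology,
# 2-column target maps, JSON truth/manifest, GraphML networks.

read_tsv_strict <- function(path, col_types = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- suppressWarnings(readr::read_tsv(path, col_types = col_types,
                                          progress = FALSE,
                                          show_col_types = FALSE))
  pb <- readr::problems(out)
  if (nrow(pb) > 0) {
    abort(sprintf("malformed TSV %s: %s (first at line %d, column %d).",
                  path, pb$expected[1], pb$row[1] + 1L, pb$col[1]))
  }
  out
}

#' Read a feature-by-sample matrix from TSV
#'
#' Expects a header row of sample IDs, a first column of feature IDs and
#' numeric cells. Duplicate feature IDs, ragged rows and non-numeric cells
#' are errors.
#'
#' @param path TSV file path.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 2L) abort(sprintf("%s: need a feature column plus samples.", path))
  feats <- as.character(df[[1]])
  if (anyDuplicated(feats)) {
    abort(sprintf("%s: duplicate feature IDs (e.g. %s).", path,
                  feats[duplicated(feats)][1]))
  }
  vals <- df[, -1, drop = FALSE]
  bad <- !vapply(vals, is.numeric, logical(1))
  if (any(bad)) {
    abort(sprintf("%s: non-numeric cells in column(s) %s.", path,
                  paste(names(vals)[bad], collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- feats
  m
}

#' Write a feature-by-sample matrix to TSV
#' @param mat Numeric matrix with dimnames.
#' @param path Output path.
#' @param feature_col Name of the first column (default "feature").
#' @export
write_matrix_tsv <- function(mat, path, feature_col = "feature") {
  df <- tibble::as_tibble(mat, rownames = feature_col)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read per-sample group labels from a two-column TSV (`sample`, `group`)
#' @param path TSV file path.
#' @return Named character vector of group labels.
#' @export
read_groups_tsv <- function(path) {
  df <- read_tsv_strict(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("sample", "group") %in% names(df))) {
    abort(sprintf("%s: need columns `sample` and `group`.", path))
  }
  setNames(df$group, df$sample)
}

#' Read a weighted edge list (`node1`, `node2`, `reliability`)
#' @param path TSV file path.
#' @return Tibble `from`, `to`, `reliability` with reliabilities in `[0, 1]`.
#' @export
read_edge_list <- function(path) {
  df <- read_tsv_strict(path)
  if (ncol(df) < 3L) abort(sprintf("%s: need node1, node2, reliability.", path))
  names(df)[1:3] <- c("from", "to", "reliability")
  if (!is.numeric(df$reliability)) abort(sprintf("%s: reliability must be numeric.", path))
  bad <- which(df$reliability < 0 | df$reliability > 1)
  if (length(bad) > 0) {
    abort(sprintf("%s: reliability out of [0, 1] at line %d (value %g).",
                  path, bad[1] + 1L, df$reliability[bad[1]]))
  }
  tibble(from = as.character(df$from), to = as.character(df$to),
         reliability = df$reliability)
}

#' Read pathway memberships from a GMT file
#'
#' Each line: pathway, description, then member genes, tab-separated.
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      abort(sprintf("%s: line %d has fewer than 3 fields.", path, i))
    }
    out[[parts[1]]] <- unique(parts[-(1:2)])
  }
  out
}

#' Write pathway memberships as GMT
#' @param memberships Named list of character vectors (or a
#'   `tromics_pathways` tibble).
#' @param path Output path.
#' @export
write_gmt <- function(memberships, path) {
  if (inherits(memberships, "tromics_pathways")) {
    memberships <- setNames(memberships$members, memberships$pathway)
  }
  lines <- vapply(names(memberships), function(p) {
    paste(c(p, "synthetic", memberships[[p]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a signed pathway topology TSV (`pathway`, `source`, `target`, `beta`)
#' @param path TSV file path.
#' @return Tibble with those four columns.
#' @export
read_topology_tsv <- function(path) {
  df <- read_tsv_strict(path)
  need <- c("pathway", "source", "target", "beta")
  if (!all(need %in% names(df))) {
    abort(sprintf("%s: need columns %s.", path, paste(need, collapse = ", ")))
  }
  if (!is.numeric(df$beta)) abort(sprintf("%s: beta must be numeric.", path))
  as_tibble(df[need])
}

#' Assemble pathway specs from GMT membership plus topology
#' @param memberships Named list from [read_gmt()].
#' @param topology Tibble from [read_topology_tsv()].
#' @return A `tromics_pathways` tibble.
#' @export
pathways_from_files <- function(memberships, topology) {
  rows <- lapply(names(memberships), function(p) {
    ed <- topology[topology$pathway == p, c("source", "target", "beta")]
    bad <- !(c(ed$source, ed$target) %in% memberships[[p]])
    if (any(bad)) {
      abort(sprintf("pathway %s: topology endpoints outside the member set.", p))
    }
    tibble(pathway = p, members = list(sort(memberships[[p]])),
           edges = list(as_tibble(ed)))
  })
  res <- bind_rows(rows)
  class(res) <- c("tromics_pathways", class(res))
  res
}

#' Read a miRNA-target map TSV (`mirna`, `gene`)
#' @param path TSV file path.
#' @return Tibble `mirna`, `gene`.
#' @export
read_target_map <- function(path) {
  df <- read_tsv_strict(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2L) abort(sprintf("%s: need columns mirna, gene.", path))
  names(df)[1:2] <- c("mirna", "gene")
  as_tibble(df[c("mirna", "gene")])
}

#' Write a synthetic dataset to a directory
#'
#' Writes all matrices, group labels, the interactome, pathway GMT +
#' topology, the target map, the ground truth (JSON) and the generating
#' configuration (JSON).
#'
#' @param dataset A `tromics_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_matrix_tsv(dataset$expression$values, fp("expression.tsv"))
  write_matrix_tsv(dataset$methylation$values, fp("methylation.tsv"))
  write_matrix_tsv(dataset$mirna_expression$values, fp("mirna_expression.tsv"),
                   feature_col = "mirna")
  write_matrix_tsv(dataset$mirna_methylation$values, fp("mirna_methylation.tsv"),
                   feature_col = "mirna")
  readr::write_tsv(tibble(sample = colnames(dataset$expression$values),
                          group = as.character(dataset$expression$groups)),
                   fp("groups.tsv"))
  readr::write_tsv(
    tibble(node1 = dataset$interactome$from, node2 = dataset$interactome$to,
           reliability = dataset$interactome$reliability),
    fp("interactome.tsv")
  )
  write_gmt(dataset$pathways, fp("pathways.gmt"))
  topo <- bind_rows(lapply(seq_len(nrow(dataset$pathways)), function(i) {
    ed <- dataset$pathways$edges[[i]]
    if (nrow(ed) == 0) return(NULL)
    tibble(pathway = dataset$pathways$pathway[i], ed)
  }))
  if (is.null(topo) || nrow(topo) == 0) {
    topo <- tibble(pathway = character(), source = character(),
                   target = character(), beta = numeric())
  }
  readr::write_tsv(topo, fp("pathway_topology.tsv"))
  readr::write_tsv(dataset$target_map, fp("target_map.tsv"))
  jsonlite::write_json(dataset$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  jsonlite::write_json(unclass(dataset$config), fp("config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write all pipeline results to a directory
#'
#' @param bundle A `tromics_results` list from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_results <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  readr::write_tsv(bundle$integration_genes, fp("integration_genes.tsv"))
  readr::write_tsv(bundle$integration_mirnas, fp("integration_mirnas.tsv"))
  readr::write_tsv(bundle$pathway_impact, fp("pathway_impact.tsv"))
  readr::write_tsv(bundle$module$nodes, fp("module_nodes.tsv"))
  readr::write_tsv(bundle$module$edges, fp("module_edges.tsv"))
  readr::write_tsv(bundle$patterns, fp("patterns.tsv"))
  readr::write_tsv(bundle$mirna_pairs, fp("mirna_pairs.tsv"))
  if (!is.null(bundle$calibration)) {
    readr::write_tsv(bundle$calibration$sweep, fp("lambda_sweep.tsv"))
  }
  if (!is.null(bundle$network) && igraph::vcount(bundle$network) > 0) {
    igraph::write_graph(bundle$network, fp("network.graphml"), format = "graphml")
  }
  jsonlite::write_json(bundle$manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
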