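# End-to-end orchestration: integration -> pathway impact -> PCST module
# -> miRNA network and regulation patterns, from files on disk to a results
# bundle with a reproducibility manifest.

#' Pipeline configuration
#'
#' Collects file paths, thresholds and solver settings for one pipeline
#' run. All paths must exist when [run_pipeline()] is called; a missing
#' path raises a configuration error naming the field.
#'
#' @param expression,methylation,mirna_expression,mirna_methylation Paths
#'   to feature-by-sample TSV matrices (see [read_matrix_tsv()]).
#' @param groups Path to the two-column sample/group TSV.
#' @param interactome Path to the 3-column weighted edge list.
#' @param pathways_gmt,pathway_topology Paths to the GMT membership file
#'   and the signed topology TSV.
#' @param target_map Path to the 2-column miRNA-target TSV.
#' @param outdir Output directory (`NULL` to skip writing).
#' @param alpha_seed Seed-gene threshold on the integrated p (default 0.05).
#' @param q_candidates,p_candidates Candidate thresholds (defaults 0.05).
#' @param corr_cutoff miRNA-gene anti-correlation cutoff (default -0.55).
#' @param alpha_m,rho_neg,rho_pos Pattern-classification thresholds.
#' @param method Integrated p-value method (see [integrate_omics()]).
#' @param lambda Prize weight: a number in `(0, 1]` or `"calibrate"`.
#' @param b_reps Perturbation bootstrap replicates.
#' @param scheme Permutation scheme for score standardization.
#' @param allow_linkers Allow zero-prize connector nodes in the module.
#' @param seed Global integer seed; per-stage seeds are derived from it by
#'   a fixed offset scheme so stages can be re-run in isolation.
#' @return A validated list of class `tromics_pipeline_config`.
#' @export
pipeline_config <- function(expression, methylation, groups,
                            mirna_expression, mirna_methylation,
                            interactome, pathways_gmt, pathway_topology,
                            target_map, outdir = NULL,
                            alpha_seed = 0.05, q_candidates = 0.05,
                            p_candidates = 0.05, corr_cutoff = -0.55,
                            alpha_m = 0.10, rho_neg = -0.55, rho_pos = 0.55,
                            method = "exact_convolution",
                            lambda = "calibrate", b_reps = 2000,
                            scheme = "auto", allow_linkers = FALSE,
                            seed = 1L) {
  assert_number(alpha_seed, "alpha_seed", 0, 1)
  assert_number(q_candidates, "q_candidates", 0, 1)
  assert_number(p_candidates, "p_candidates", 0, 1)
  assert_number(corr_cutoff, "corr_cutoff", upper = 0, strict_upper = TRUE)
  if (!identical(lambda, "calibrate")) {
    assert_number(lambda, "lambda", 0, 1, strict_lower = TRUE)
  }
  cfg <- list(
    paths = list(expression = expression, methylation = methylation,
                 groups = groups, mirna_expression = mirna_expression,
                 mirna_methylation = mirna_methylation,
                 interactome = interactome, pathways_gmt = pathways_gmt,
                 pathway_topology = pathway_topology, target_map = target_map),
    outdir = outdir,
    alpha_seed = alpha_seed, q_candidates = q_candidates,
    p_candidates = p_candidates, corr_cutoff = corr_cutoff,
    alpha_m = alpha_m, rho_neg = rho_neg, rho_pos = rho_pos,
    method = method, lambda = lambda,
    b_reps = assert_count(b_reps, "b_reps", lower = 100L),
    scheme = scheme, allow_linkers = isTRUE(allow_linkers),
    seed = assert_seed(seed)
  )
  structure(cfg, class = "tromics_pipeline_config")
}

#' Run the full trans-omics pipeline
#'
#' Executes, in order: (1) gene- and miRNA-level integration of expression
#' and methylation evidence; (2) pathway impact analysis; (3) candidate
#' selection and prize-collecting Steiner tree module discovery (with
#' lambda calibration when requested); (4) miRNA anti-correlation network
#' construction and regulation-pattern classification. All stages are
#' deterministic given the configuration.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `tromics_results`: `integration_genes`,
#'   `integration_mirnas`, `mirna_expression_stats`, `pathway_impact`,
#'   `candidates`, `calibration` (or `NULL`), `module`, `mirna_candidates`,
#'   `mirna_pairs`, `patterns`, `network` (igraph), `manifest`. Written to
#'   `config$outdir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "tromics_pipeline_config"))
  for (field in names(config$paths)) {
    if (!is.character(config$paths[[field]]) || !file.exists(config$paths[[field]])) {
      abort(sprintf("configuration error: path `%s` does not exist (%s).",
                    field, as.character(config$paths[[field]])))
    }
  }
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- expr
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  ## load -----------------------------------------------------------------
  groups <- read_groups_tsv(config$paths$groups)
  load_om <- function(path) {
    m <- read_matrix_tsv(path)
    omics_matrix(m, groups[colnames(m)])
  }
  expr <- load_om(config$paths$expression)
  meth <- load_om(config$paths$methylation)
  mirna_expr <- load_om(config$paths$mirna_expression)
  mirna_meth <- load_om(config$paths$mirna_methylation)
  interactome <- read_edge_list(config$paths$interactome)
  pathways <- pathways_from_files(read_gmt(config$paths$pathways_gmt),
                                  read_topology_tsv(config$paths$pathway_topology))
  target_map <- read_target_map(config$paths$target_map)

  ## stage 1: integration ---------------------------------------------------
  integration_genes <- tick("integration_genes", integrate_omics(
    list(expression = expr, methylation = meth),
    method = config$method, scheme = config$scheme, seed = config$seed
  ))
  em_ids <- rownames(mirna_meth$values)
  mirna_expr_em <- omics_matrix(
    mirna_expr$values[intersect(em_ids, rownames(mirna_expr$values)), ,
                      drop = FALSE],
    setNames(as.character(mirna_expr$groups), colnames(mirna_expr$values))
  )
  integration_mirnas <- tick("integration_mirnas", integrate_omics(
    list(expression = mirna_expr_em, methylation = mirna_meth),
    method = config$method, scheme = config$scheme, seed = config$seed
  ))
  mirna_expression_stats <- integrate_omics(
    list(expression = mirna_expr),
    method = if (config$method == "closed_form") "exact_convolution" else config$method,
    scheme = config$scheme, seed = config$seed
  )

  ## stage 2: pathway impact ------------------------------------------------
  pathway_impact <- tick("pathway_impact", run_pathway_impact(
    pathways, integration_genes, expr, alpha = config$alpha_seed,
    b_reps = config$b_reps, seed = config$seed
  ))

  ## stage 3: module --------------------------------------------------------
  candidates <- select_candidates(integration_genes, pathway_impact, pathways,
                                  q_thresh = config$q_candidates,
                                  p_thresh = config$p_candidates)
  pg <- build_prize_graph(candidates, interactome, expr, integration_genes,
                          allow_linkers = config$allow_linkers,
                          methylation = meth)
  calibration <- NULL
  lambda <- config$lambda
  if (identical(lambda, "calibrate")) {
    calibration <- tick("calibration", calibrate_lambda(
      template = pg, seed = stage_seed(config$seed, "calibration")
    ))
    lambda <- calibration$lambda_star
  }
  module <- tick("module", pcst_solve(
    pg, lambda, seed = stage_seed(config$seed, "module")
  ))

  ## stage 4: miRNA network and patterns -------------------------------------
  mirna_candidates <- select_mirnas(integration_mirnas, mirna_expression_stats,
                                    alpha = 0.05)
  module_genes <- module$nodes$id[module$nodes$candidate %||% TRUE]
  corrs <- mirna_gene_correlations(mirna_expr, expr, module_genes,
                                   mirnas = mirna_candidates$mirna)
  mirna_pairs <- screen_pairs(corrs, cutoff = config$corr_cutoff, target_map)

  meth_p <- setNames(integration_genes$p_methylation, integration_genes$feature)
  shared <- intersect(rownames(expr$values), rownames(meth$values))
  meth_corr <- setNames(
    vapply(shared, function(g) cor(expr$values[g, ], meth$values[g, ]),
           numeric(1)),
    shared
  )
  neighbor_edges <- interactome[interactome$from %in% module_genes &
                                  interactome$to %in% module_genes,
                                c("from", "to"), drop = FALSE]
  patterns <- tick("patterns", classify_regulation(
    module_genes, meth_p, meth_corr, mirna_pairs, neighbor_edges, expr,
    alpha_m = config$alpha_m, rho_neg = config$rho_neg,
    rho_pos = config$rho_pos
  ))
  network <- if (nrow(module$nodes) > 0) {
    build_bipartite(module, mirna_pairs, patterns, mirna_candidates)
  } else NULL

  manifest <- list(
    package = "tromics",
    version = as.character(utils::packageVersion("tromics")),
    seed = config$seed,
    lambda = lambda,
    config_hash = rlang::hash(config[setdiff(names(config), "outdir")]),
    n_genes = nrow(expr$values), n_mirnas = nrow(mirna_expr$values),
    n_candidates = length(candidates),
    module_size = nrow(module$nodes),
    timings = timings
  )
  bundle <- structure(
    list(integration_genes = integration_genes,
         integration_mirnas = integration_mirnas,
         mirna_expression_stats = mirna_expression_stats,
         pathway_impact = pathway_impact,
         candidates = candidates, calibration = calibration,
         module = module, mirna_candidates = mirna_candidates,
         mirna_pairs = mirna_pairs, patterns = patterns,
         network = network, manifest = manifest),
    class = "tromics_results"
  )
  if (!is.null(config$outdir)) write_results(bundle, config$outdir)
  bundle
}

#' @export
print.tromics_results <- function(x, ...) {
  cat(sprintf(
    paste0("<tromics_results>\n",
           "  genes integrated: %d (q <= 0.05: %d)\n",
           "  miRNAs integrated (EM): %d; pathways tested: %d\n",
           "  candidates: %d; module: %d nodes (lambda = %.3g)\n",
           "  screened miRNA pairs: %d (%d target-supported)\n"),
    nrow(x$integration_genes), sum(x$integration_genes$q_inte <= 0.05),
    nrow(x$integration_mirnas), nrow(x$pathway_impact),
    length(x$candidates), nrow(x$module$nodes), x$module$lambda,
    nrow(x$mirna_pairs), sum(x$mirna_pairs$target_supported)
  ))
  invisible(x)
}
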