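# miRNA attachment to the protein-coding module: selection of candidate
# miRNAs, anti-correlation screening against module genes, target-map
# support, and classification of each module gene into one of four
# regulation patterns.

#' Select candidate miRNAs
#'
#' miRNAs with both expression and methylation data (the EM class) are
#' selected on their integrated p-value; miRNAs with expression only (the E
#' class) on their expression-only p-value. The classes are disjoint: any
#' miRNA present in the integration (EM) table is classified EM only and is
#' never re-selected through the E route.
#'
#' @param mirna_integration `tromics_integration` table over the miRNAs with
#'   both layers.
#' @param mirna_expression_stats Tibble with columns `feature` and `p` (or a
#'   single-layer `tromics_integration` table) for all measured miRNAs.
#' @param alpha Selection threshold (default 0.05).
#' @return Tibble with columns `mirna`, `class` ("EM"/"E"), `p_select`.
#' @export
select_mirnas <- function(mirna_integration, mirna_expression_stats,
                          alpha = 0.05) {
  assert_number(alpha, "alpha", 0, 1)
  em_ids <- mirna_integration$feature
  em <- tibble(
    mirna = em_ids[mirna_integration$p_inte <= alpha],
    class = "EM",
    p_select = mirna_integration$p_inte[mirna_integration$p_inte <= alpha]
  )
  es <- mirna_expression_stats
  p_col <- if ("p" %in% names(es)) "p" else if ("p_inte" %in% names(es)) "p_inte" else {
    abort("`mirna_expression_stats` needs a `p` (or `p_inte`) column.")
  }
  keep <- !(es$feature %in% em_ids) & es[[p_col]] <= alpha
  e <- tibble(mirna = es$feature[keep], class = "E", p_select = es[[p_col]][keep])
  bind_rows(em, e) |> arrange(.data$mirna)
}

#' Pairwise miRNA-gene expression correlations
#'
#' Pearson correlation between every candidate miRNA and every module gene
#' across the shared samples. Pairs involving a constant vector are
#' excluded (undefined correlation).
#'
#' @param mirna_expr miRNA expression [omics_matrix()].
#' @param gene_expr Gene expression [omics_matrix()].
#' @param module_genes Character vector of module gene IDs.
#' @param mirnas Character vector of candidate miRNA IDs (default: all rows
#'   of `mirna_expr`).
#' @return Tibble with columns `mirna`, `gene`, `r`.
#' @export
mirna_gene_correlations <- function(mirna_expr, gene_expr, module_genes,
                                    mirnas = rownames(mirna_expr$values)) {
  if (!identical(colnames(mirna_expr$values), colnames(gene_expr$values))) {
    abort("miRNA and gene matrices must share the same ordered samples.")
  }
  mirnas <- intersect(mirnas, rownames(mirna_expr$values))
  genes <- intersect(module_genes, rownames(gene_expr$values))
  if (length(mirnas) == 0L || length(genes) == 0L) {
    return(tibble(mirna = character(), gene = character(), r = numeric()))
  }
  M <- mirna_expr$values[mirnas, , drop = FALSE]
  G <- gene_expr$values[genes, , drop = FALSE]
  const_m <- apply(M, 1, function(v) length(unique(v)) == 1L)
  const_g <- apply(G, 1, function(v) length(unique(v)) == 1L)
  if (any(const_m) || any(const_g)) {
    inform(sprintf("excluding %d constant miRNA(s) and %d constant gene(s) from correlation.",
                   sum(const_m), sum(const_g)))
    M <- M[!const_m, , drop = FALSE]
    G <- G[!const_g, , drop = FALSE]
  }
  if (nrow(M) == 0L || nrow(G) == 0L) {
    return(tibble(mirna = character(), gene = character(), r = numeric()))
  }
  R <- cor(t(M), t(G))                       # mirnas x genes
  tibble(
    mirna = rep(rownames(R), times = ncol(R)),
    gene = rep(colnames(R), each = nrow(R)),
    r = as.vector(R)
  ) |> arrange(.data$mirna, .data$gene)
}

#' Screen anti-correlated miRNA-gene pairs
#'
#' Keeps pairs at or below the (negative, strict) correlation cutoff and
#' flags each kept pair with its target-map support. Both supported and
#' unsupported pairs are reported -- unsupported pairs remain in the
#' displayed network but only target-supported pairs provide miRNA-pattern
#' evidence downstream.
#'
#' @param correlations Tibble from [mirna_gene_correlations()].
#' @param cutoff Negative correlation cutoff (default -0.55; a pair is kept
#'   when its correlation is at or below the cutoff).
#' @param target_map Tibble with columns `mirna`, `gene`.
#' @return Tibble `mirna`, `gene`, `r`, `target_supported`.
#' @export
screen_pairs <- function(correlations, cutoff = -0.55, target_map) {
  assert_number(cutoff, "cutoff", upper = 0, strict_upper = TRUE)
  kept <- correlations[correlations$r <= cutoff, , drop = FALSE]
  key <- paste(target_map$mirna, target_map$gene, sep = "\r")
  kept$target_supported <- paste(kept$mirna, kept$gene, sep = "\r") %in% key
  as_tibble(kept)
}

#' Classify module genes into regulation patterns
#'
#' Each module gene receives exactly one of four regulation-pattern labels
#' (or UNCLASSIFIED):
#'
#' * `METHYLATION`: nominal methylation p-value at or below `alpha_m` and
#'   expression-methylation correlation at or below `rho_neg`.
#' * `MIRNA`: a target-supported anti-correlated miRNA partner exists.
#' * `CO_REGULATED`: both of the above.
#' * `NEIGHBOR_TF`: neither, but some module neighbor's expression
#'   correlation reaches `rho_pos` (a transcription-factor-style regulator).
#' * `UNCLASSIFIED`: none of the above.
#'
#' @param module_genes Character vector of module gene IDs.
#' @param methylation_p Named numeric of nominal methylation p-values per
#'   gene (genes without methylation data get no methylation evidence).
#' @param methylation_corr Named numeric of expression-methylation Pearson
#'   correlations per gene.
#' @param validated_pairs Tibble from [screen_pairs()].
#' @param neighbor_edges Tibble `from`, `to`: adjacency among module genes
#'   (interactome edges restricted to the module).
#' @param gene_expr Gene expression [omics_matrix()] (for neighbor
#'   correlations).
#' @param alpha_m Methylation evidence p threshold (default 0.10).
#' @param rho_neg Negative-correlation threshold (default -0.55).
#' @param rho_pos Positive neighbor-correlation threshold (default +0.55).
#' @return Tibble of class `tromics_patterns`: `gene`, `pattern`,
#'   `methyl_p`, `methyl_corr`, `mirna_partner`, `mirna_corr`,
#'   `neighbor_partner`, `neighbor_corr`.
#' @export
classify_regulation <- function(module_genes, methylation_p, methylation_corr,
                                validated_pairs, neighbor_edges, gene_expr,
                                alpha_m = 0.10, rho_neg = -0.55,
                                rho_pos = 0.55) {
  assert_number(alpha_m, "alpha_m", 0, 1)
  assert_number(rho_neg, "rho_neg", -1, 0)
  assert_number(rho_pos, "rho_pos", 0, 1)
  missing_meth <- setdiff(module_genes, names(methylation_p))
  if (length(missing_meth) > 0) {
    inform(sprintf("%d module gene(s) lack methylation data; methylation evidence set to absent.",
                   length(missing_meth)))
  }
  vp <- validated_pairs[validated_pairs$target_supported, , drop = FALSE]

  rows <- lapply(module_genes, function(g) {
    mp <- unname(methylation_p[g])
    mc <- unname(methylation_corr[g])
    meth_ev <- isTRUE(mp <= alpha_m) && isTRUE(mc <= rho_neg)
    gp <- vp[vp$gene == g, , drop = FALSE]
    mirna_ev <- nrow(gp) > 0
    partner <- if (mirna_ev) gp$mirna[which.min(gp$r)] else NA_character_
    partner_r <- if (mirna_ev) min(gp$r) else NA_real_
    nb_partner <- NA_character_; nb_r <- NA_real_
    pattern <- if (meth_ev && mirna_ev) "CO_REGULATED"
    else if (meth_ev) "METHYLATION"
    else if (mirna_ev) "MIRNA"
    else {
      nbs <- unique(c(neighbor_edges$to[neighbor_edges$from == g],
                      neighbor_edges$from[neighbor_edges$to == g]))
      nbs <- setdiff(intersect(nbs, rownames(gene_expr$values)), g)
      if (length(nbs) > 0 && g %in% rownames(gene_expr$values)) {
        rs <- vapply(nbs, function(nb) {
          cor(gene_expr$values[g, ], gene_expr$values[nb, ])
        }, numeric(1))
        if (max(rs) >= rho_pos) {
          nb_partner <- nbs[which.max(rs)]
          nb_r <- max(rs)
          "NEIGHBOR_TF"
        } else "UNCLASSIFIED"
      } else "UNCLASSIFIED"
    }
    tibble(gene = g, pattern = pattern,
           methyl_p = mp %||% NA_real_, methyl_corr = mc %||% NA_real_,
           mirna_partner = partner, mirna_corr = partner_r,
           neighbor_partner = nb_partner, neighbor_corr = nb_r)
  })
  out <- bind_rows(rows)
  class(out) <- c("tromics_patterns", class(out))
  out
}

#' Combine the module tree and miRNA edges into one network
#'
#' Graph union of the module tree edges and the screened miRNA-gene edges
#' (restricted to genes in the module). Gene nodes carry their prize,
#' p-values and regulation pattern; miRNA nodes their class; edges carry
#' the tree cost or the miRNA-gene correlation. Every miRNA node in the
#' output has degree >= 1 by construction.
#'
#' @param module A `tromics_module`.
#' @param validated_pairs Tibble from [screen_pairs()].
#' @param patterns Optional `tromics_patterns` table for node annotation.
#' @param mirna_candidates Optional tibble from [select_mirnas()] for miRNA
#'   class annotation.
#' @return An [igraph::igraph] with vertex attributes `type`
#'   ("gene"/"mirna"), `prize`, `p_inte`, `pattern`, `class`, and edge
#'   attributes `kind` ("module"/"mirna"), `cost`, `r`.
#' @export
build_bipartite <- function(module, validated_pairs, patterns = NULL,
                            mirna_candidates = NULL) {
  if (nrow(module$nodes) == 0L) abort("the module is empty.")
  vp <- validated_pairs[validated_pairs$gene %in% module$nodes$id, , drop = FALSE]
  gene_tbl <- tibble(
    name = module$nodes$id, type = "gene",
    prize = module$nodes$prize,
    p_inte = module$nodes$p_inte %||% NA_real_,
    pattern = if (!is.null(patterns)) {
      patterns$pattern[match(module$nodes$id, patterns$gene)]
    } else NA_character_,
    class = NA_character_
  )
  mirna_tbl <- tibble(
    name = unique(vp$mirna), type = "mirna", prize = 0, p_inte = NA_real_,
    pattern = NA_character_,
    class = if (!is.null(mirna_candidates)) {
      mirna_candidates$class[match(unique(vp$mirna), mirna_candidates$mirna)]
    } else NA_character_
  )
  edges <- bind_rows(
    if (nrow(module$edges) > 0) {
      tibble(from = module$edges$from, to = module$edges$to,
             kind = "module", cost = module$edges$cost, r = NA_real_)
    },
    if (nrow(vp) > 0) {
      tibble(from = vp$mirna, to = vp$gene, kind = "mirna",
             cost = NA_real_, r = vp$r)
    }
  )
  if (is.null(edges) || ncol(edges) == 0) {
    edges <- tibble(from = character(), to = character(),
                    kind = character(), cost = numeric(), r = numeric())
  }
  igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = bind_rows(gene_tbl, mirna_tbl)
  )
}
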