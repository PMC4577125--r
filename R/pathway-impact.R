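# Pathway impact analysis: hypergeometric over-representation evidence
# combined with topology-propagated perturbation evidence into one global
# per-pathway probability.

#' Select seed genes and their expression shifts
#'
#' Seed genes are those with integrated p-value at or below `alpha`; each
#' seed gene's perturbation input is its observed log2 expression difference
#' (high minus low group mean), zero for non-seeds.
#'
#' @param integration A `tromics_integration` table (genes).
#' @param expression The gene expression [omics_matrix()].
#' @param alpha Seed threshold on `p_inte` (default 0.05).
#' @return List with `seeds` (character) and `delta_e` (named numeric over
#'   all measured genes; non-seeds are 0).
#' @export
select_seed_genes <- function(integration, expression, alpha = 0.05) {
  assert_number(alpha, "alpha", 0, 1)
  if (!all(c("feature", "p_inte") %in% names(integration))) {
    abort("`integration` must have columns `feature` and `p_inte`.")
  }
  seeds <- integration$feature[integration$p_inte <= alpha]
  g1 <- expression$groups == levels(expression$groups)[1]
  de_all <- rowMeans(expression$values[, g1, drop = FALSE]) -
    rowMeans(expression$values[, !g1, drop = FALSE])
  delta_e <- setNames(rep(0, nrow(expression$values)), rownames(expression$values))
  seeds <- intersect(seeds, names(delta_e))
  delta_e[seeds] <- de_all[seeds]
  if (length(seeds) == 0L) {
    warn("empty seed gene set: all pathway over-representation p-values will be 1.")
  }
  list(seeds = seeds, delta_e = delta_e)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least `k` differentially
#' expressed genes in a pathway of size `K`, given `n` DE genes among `N`
#' measured genes.
#'
#' @param k DE genes in the pathway.
#' @param K Pathway size on the array.
#' @param n Total DE genes.
#' @param N Background (measured) gene count.
#' @return `P(X >= k)`; 1 when `k = 0`.
#' @export
overrepresentation_p <- function(k, K, n, N) {
  k <- assert_count(k, "k", lower = 0L); K <- assert_count(K, "K", lower = 0L)
  n <- assert_count(n, "n", lower = 0L); N <- assert_count(N, "N", lower = 0L)
  if (k > min(K, n) || K > N || n > N) abort("inconsistent hypergeometric counts.")
  if (k == 0L) return(1)
  phyper(k - 1L, n, N - n, K, lower.tail = FALSE)
}

# Propagation matrix B with B[i, j] = beta(j -> i) / N_ds(j), where N_ds(j)
# is the number of downstream targets of j within the pathway.
propagation_matrix <- function(members, edges) {
  B <- matrix(0, length(members), length(members),
              dimnames = list(members, members))
  if (nrow(edges) > 0) {
    nds <- table(factor(edges$source, levels = members))
    for (r in seq_len(nrow(edges))) {
      B[edges$target[r], edges$source[r]] <-
        B[edges$target[r], edges$source[r]] +
        edges$beta[r] / nds[[edges$source[r]]]
    }
  }
  B
}

#' Perturbation factors and net accumulated perturbation
#'
#' Solves the linear signal-propagation model `PF = deltaE + B PF`, i.e.
#' `PF = (I - B)^{-1} deltaE`, where `B[i, j] = beta_{j->i} / N_ds(j)`
#' distributes each gene's perturbation equally over its downstream targets
#' with the edge sign. The net accumulation is `Acc = PF - deltaE` and the
#' pathway's total net accumulated perturbation is `t_A = sum(Acc)`
#' (log2-fold-change units).
#'
#' @param pathway List or one-row `tromics_pathways` entry with `members`
#'   (character) and `edges` (tibble `source`, `target`, `beta`).
#' @param delta_e Named numeric of expression shifts; members missing from
#'   it count as 0.
#' @return List with `pf`, `acc` (named), `t_a`, and `status` ("ok" or
#'   "inversion_failed", in which case `t_a` is `NA`).
#' @export
perturbation_factors <- function(pathway, delta_e) {
  members <- pathway$members
  if (is.list(members) && !is.character(members)) members <- members[[1]]
  edges <- pathway$edges
  if (is.list(edges) && !is.data.frame(edges)) edges <- edges[[1]]
  if (length(members) < 1L) abort("pathway must have at least one member.")
  if (nrow(edges) > 0 &&
      !all(c(edges$source, edges$target) %in% members)) {
    abort("topology endpoints must be pathway members.")
  }
  de <- setNames(rep(0, length(members)), members)
  shared <- intersect(members, names(delta_e))
  de[shared] <- delta_e[shared]
  B <- propagation_matrix(members, edges)
  A <- diag(length(members)) - B
  pf <- tryCatch(solve(A, de), error = function(e) NULL)
  if (is.null(pf) || any(!is.finite(pf)) || rcond(A) < 1e-12) {
    return(list(pf = NULL, acc = NULL, t_a = NA_real_, status = "inversion_failed"))
  }
  pf <- setNames(as.vector(pf), members)
  acc <- pf - de
  list(pf = pf, acc = acc, t_a = sum(acc), status = "ok")
}

#' Bootstrap perturbation p-value
#'
#' Builds the null distribution of the total net accumulated perturbation by
#' repeatedly assigning the observed number of DE values (resampled from the
#' pool of all seed-gene shifts) to random pathway genes, and compares the
#' observed `t_A` against it two-sidedly after median-centering. Bounded
#' below by `1/B`.
#'
#' @param pathway As in [perturbation_factors()].
#' @param delta_e Named numeric of observed shifts (seed genes non-zero).
#' @param delta_e_pool Numeric pool of all seed-gene shifts.
#' @param b_reps Bootstrap replicates (>= 100).
#' @param seed Integer seed.
#' @return List with `p_pert`, `t_a`, `status`.
#' @export
perturbation_p <- function(pathway, delta_e, delta_e_pool, b_reps = 2000,
                           seed = 1L) {
  b_reps <- assert_count(b_reps, "b_reps", lower = 100L)
  obs <- perturbation_factors(pathway, delta_e)
  if (obs$status != "ok") {
    return(list(p_pert = 1, t_a = NA_real_, status = obs$status))
  }
  members <- pathway$members
  if (is.list(members) && !is.character(members)) members <- members[[1]]
  edges <- pathway$edges
  if (is.list(edges) && !is.data.frame(edges)) edges <- edges[[1]]
  n_de <- sum(names(delta_e) %in% members & delta_e != 0)
  if (length(delta_e_pool) == 0L || n_de == 0L || all(delta_e_pool == 0)) {
    return(list(p_pert = 1, t_a = obs$t_a, status = "ok"))
  }
  B <- propagation_matrix(members, edges)
  Ainv <- solve(diag(length(members)) - B)
  set.seed(assert_seed(seed))
  t_null <- numeric(b_reps)
  for (b in seq_len(b_reps)) {
    de_b <- numeric(length(members))
    de_b[sample.int(length(members), min(n_de, length(members)))] <-
      sample(delta_e_pool, min(n_de, length(members)), replace = TRUE)
    pf_b <- Ainv %*% de_b
    t_null[b] <- sum(pf_b - de_b)
  }
  med <- median(t_null)
  if (all(t_null == t_null[1]) && isTRUE(all.equal(obs$t_a, med))) {
    return(list(p_pert = 1, t_a = obs$t_a, status = "ok"))
  }
  p <- mean(abs(t_null - med) >= abs(obs$t_a - med) - 1e-12)
  list(p_pert = max(p, 1 / b_reps), t_a = obs$t_a, status = "ok")
}

#' Combine over-representation and perturbation evidence
#'
#' Global pathway probability from the product of the two evidence
#' p-values: with `c = p_nde * p_pert`, `P_G = c - c * ln(c)` (natural
#' log), the probability that a product of two independent uniforms is
#' below `c`.
#'
#' @param p_nde,p_pert Evidence p-values in `(0, 1]`.
#' @return `P_G` in `(0, 1]`.
#' @examples
#' combine_global(6.09e-3, 0.79)  # 0.0305
#' @export
combine_global <- function(p_nde, p_pert) {
  if (any(p_nde <= 0) || any(p_pert <= 0) || any(p_nde > 1) || any(p_pert > 1)) {
    abort("`p_nde` and `p_pert` must lie in (0, 1].")
  }
  cc <- p_nde * p_pert
  cc - cc * log(cc)
}

#' Run the full pathway impact analysis
#'
#' For each pathway computes the over-representation p-value `P_NDE`
#' (hypergeometric, against the measured-gene background), the perturbation
#' p-value `P_PERT` (bootstrap over the propagation model), the global
#' `P_G = c - c ln c`, and BH-adjusted q-values across pathways. A pathway
#' is flagged significant by the dual criterion `q_G <= sig_q` OR
#' `q_NDE <= sig_q`. Pathways with fewer than `min_genes` members on the
#' array are skipped.
#'
#' @param pathways A `tromics_pathways` tibble.
#' @param integration Gene-level `tromics_integration` table.
#' @param expression Gene expression [omics_matrix()].
#' @param alpha Seed-gene threshold on `p_inte`.
#' @param b_reps Bootstrap replicates for `P_PERT`.
#' @param seed Integer seed.
#' @param min_genes Minimum pathway members on the array (default 3).
#' @param sig_q Significance threshold on the q-values (default 0.20).
#' @return Tibble of class `tromics_pathway_impact`, sorted by `P_G`:
#'   columns `pathway`, `n_members`, `n_de`, `p_nde`, `t_a`, `p_pert`,
#'   `p_g`, `q_nde`, `q_pert`, `q_g`, `status`, `significant`.
#' @export
run_pathway_impact <- function(pathways, integration, expression,
                               alpha = 0.05, b_reps = 2000, seed = 1L,
                               min_genes = 3L, sig_q = 0.20) {
  if (nrow(pathways) == 0L) {
    abort("`pathways` is empty.")
  }
  seeded <- select_seed_genes(integration, expression, alpha = alpha)
  measured <- rownames(expression$values)
  N <- length(measured)
  n_de_total <- length(seeded$seeds)
  pool <- seeded$delta_e[seeded$seeds]

  rows <- vector("list", nrow(pathways))
  skipped <- character(0)
  for (i in seq_len(nrow(pathways))) {
    members_all <- pathways$members[[i]]
    members <- intersect(members_all, measured)
    if (length(members) < min_genes) {
      skipped <- c(skipped, pathways$pathway[i])
      next
    }
    edges <- pathways$edges[[i]]
    edges <- edges[edges$source %in% members & edges$target %in% members, ,
                   drop = FALSE]
    pw <- list(members = members, edges = edges)
    k <- sum(members %in% seeded$seeds)
    p_nde <- overrepresentation_p(k, length(members), n_de_total, N)
    pert <- perturbation_p(pw, seeded$delta_e, pool, b_reps = b_reps,
                           seed = stage_seed(seed, "pathway_impact") + i)
    rows[[i]] <- tibble(
      pathway = pathways$pathway[i], n_members = length(members), n_de = k,
      p_nde = p_nde, t_a = pert$t_a, p_pert = pert$p_pert,
      p_g = combine_global(p_nde, pert$p_pert), status = pert$status
    )
  }
  if (length(skipped) > 0) {
    inform(sprintf("skipped %d pathway(s) with < %d genes on the array: %s",
                   length(skipped), min_genes,
                   paste(head(skipped, 10), collapse = ", ")))
  }
  res <- bind_rows(rows)
  if (nrow(res) == 0L) abort("no pathway had enough genes on the array.")
  res$q_nde <- bh_fdr(res$p_nde)
  res$q_pert <- bh_fdr(res$p_pert)
  res$q_g <- bh_fdr(res$p_g)
  res$significant <- res$q_g <= sig_q | res$q_nde <= sig_q
  res <- arrange(res, .data$p_g, .data$pathway) |>
    select("pathway", "n_members", "n_de", "p_nde", "q_nde", "t_a",
           "p_pert", "q_pert", "p_g", "q_g", "status", "significant")
  class(res) <- c("tromics_pathway_impact", class(res))
  attr(res, "alpha") <- alpha
  attr(res, "sig_q") <- sig_q
  res
}
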