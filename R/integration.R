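# Multi-omics meta-integration: per-layer two-group t scores, permutation
# standardization, half-normal combined score and integrated p-values.

#' Pooled-variance two-group t statistic
#'
#' The per-layer association score: a pooled-variance two-sample t statistic
#' contrasting the high against the low phenotype group (positive = higher in
#' the high group). Pooled rather than Welch variance is used so the statistic
#' is exchangeable under label permutation.
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Group label per sample (two distinct values).
#' @param high Label of the high arm (difference is high minus low).
#' @return A single t statistic.
#' @examples
#' two_group_t(c(1, 2, 3, 4, 5, 6), rep(c("low", "high"), each = 3))
#' @export
two_group_t <- function(values, labels, high = "high") {
  if (!is.numeric(values)) abort("`values` must be numeric.")
  labels <- as.character(labels)
  if (length(labels) != length(values)) {
    abort("`values` and `labels` must have the same length.")
  }
  lev <- unique(labels)
  if (length(lev) != 2L) abort("`labels` must have exactly two distinct values.")
  if (!high %in% lev) abort(sprintf("high label '%s' not present in `labels`.", high))
  x <- values[labels == high]
  y <- values[labels != high]
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group must contain at least 2 samples.")
  }
  ssx <- sum((x - mean(x))^2)
  ssy <- sum((y - mean(y))^2)
  sp2 <- (ssx + ssy) / (length(x) + length(y) - 2L)
  if (sp2 <= 0) {
    abort("zero pooled variance: the t statistic is undefined for this feature.")
  }
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / length(x) + 1 / length(y)))
}

# Row-wise pooled t statistics for a feature x sample matrix against one or
# more high-arm indicator columns. `ind` is an n_samples x n_relabelings 0/1
# matrix; returns a features x relabelings matrix of t statistics.
row_t_stats <- function(mat, ind) {
  ind <- as.matrix(ind)
  n <- nrow(ind)
  n1 <- colSums(ind)
  n2 <- n - n1
  rs <- rowSums(mat)
  rq <- rowSums(mat^2)
  s1 <- mat %*% ind                       # group-1 sums, features x perms
  q1 <- (mat^2) %*% ind
  m1 <- sweep(s1, 2, n1, "/")
  m2 <- sweep(rs - s1, 2, n2, "/")
  ss1 <- q1 - sweep(m1^2, 2, n1, "*")
  ss2 <- (rq - q1) - sweep(m2^2, 2, n2, "*")
  sp2 <- sweep(ss1 + ss2, 2, n1 + n2 - 2, "/")
  sp2[sp2 < 0] <- 0                       # numerical guard
  se <- sqrt(sweep(sp2, 2, 1 / n1 + 1 / n2, "*"))
  (m1 - m2) / se
}

# All (or sampled) balanced relabelings of a two-group design, as an
# n_samples x n_perm 0/1 indicator matrix of high-arm membership. The
# identity labeling is always the first column.
balanced_relabelings <- function(ind_obs, scheme = c("auto", "exhaustive", "sampled"),
                                 n_perm = 10000, max_exhaustive = 10000,
                                 seed = 1L) {
  scheme <- match.arg(scheme)
  n <- length(ind_obs)
  n1 <- sum(ind_obs)
  n_total <- choose(n, n1)
  if (scheme == "auto") {
    scheme <- if (n_total <= max_exhaustive) "exhaustive" else "sampled"
  }
  if (scheme == "exhaustive") {
    sets <- combn(n, n1)
    ind <- matrix(0L, n, ncol(sets))
    ind[cbind(as.vector(sets), rep(seq_len(ncol(sets)), each = n1))] <- 1L
    # put the identity labeling first
    obs_col <- which(colSums(ind == ind_obs) == n)[1]
    ind[, c(obs_col, setdiff(seq_len(ncol(ind)), obs_col))]
  } else {
    if (n_perm < 2) abort("`n_perm` must be at least 2.")
    set.seed(assert_seed(seed))
    ind <- matrix(0L, n, n_perm)
    ind[, 1] <- ind_obs
    for (j in 2:n_perm) ind[sample.int(n, n1), j] <- 1L
    ind
  }
}

#' Permutation standard deviation of the two-group t statistic
#'
#' Standard deviation of the pooled t statistic over balanced relabelings of
#' the group labels, used to standardize per-layer scores before half-normal
#' combination. The exhaustive scheme enumerates all `choose(n, n1)` distinct
#' relabelings (252 for a 5-vs-5 design), always including the observed
#' labeling in the null set; the sampled scheme draws `n_perm` relabelings.
#'
#' @inheritParams two_group_t
#' @param scheme `"auto"` (exhaustive when `choose(n, n1)` <= 10000, the
#'   5-vs-5 case included, else sampled), `"exhaustive"`, or `"sampled"`.
#' @param n_perm Number of sampled relabelings (sampled scheme only).
#' @param seed Integer seed for the sampled scheme.
#' @return The standard deviation (> 0) of the permuted t statistics.
#' @export
permutation_sd <- function(values, labels, scheme = c("auto", "exhaustive", "sampled"),
                           n_perm = 10000, seed = 1L, high = "high") {
  scheme <- match.arg(scheme)
  labels <- as.character(labels)
  if (length(unique(values)) == 1L) {
    abort("constant feature vector: permutation sd is undefined.")
  }
  two_group_t(values, labels, high = high)  # validates design, errors early
  ind_obs <- as.integer(labels == high)
  ind <- balanced_relabelings(ind_obs, scheme, n_perm = n_perm, seed = seed)
  ts <- as.vector(row_t_stats(matrix(values, nrow = 1), ind))
  s <- sd(ts)
  if (!is.finite(s) || s <= 0) abort("permutation sd is not positive.")
  s
}

#' Standardize a per-layer score
#'
#' @param s Per-layer association score (t statistic).
#' @param sd_s Its permutation standard deviation (> 0).
#' @return The standardized score `s / sd_s`.
#' @export
standardize <- function(s, sd_s) {
  if (any(!is.finite(sd_s)) || any(sd_s <= 0)) abort("`sd_s` must be positive.")
  s / sd_s
}

#' Half-normal combined score
#'
#' Combines D standardized per-layer scores into one gene-specific score,
#' the sum of their absolute values. Under the null each standardized score
#' is (approximately) standard normal, so each absolute score is half-normal.
#'
#' @param z Numeric vector of standardized scores (length D >= 1).
#' @return `sum(abs(z))`.
#' @export
combined_score <- function(z) {
  if (length(z) < 1L) abort("`z` must contain at least one score.")
  if (any(!is.finite(z))) abort("`z` must be finite.")
  sum(abs(z))
}

# Upper tail P(sum_{k=1..d} |Z_k| > s) for iid standard normal Z_k, by
# recursive quadrature on the tail (preserves precision for small p).
half_normal_sum_tail <- function(s, d) {
  if (d == 1L) return(2 * pnorm(s, lower.tail = FALSE))
  f <- function(x) 2 * dnorm(x) * vapply(s - x, half_normal_sum_tail,
                                         numeric(1), d = d - 1L)
  tail_d <- 2 * pnorm(s, lower.tail = FALSE)
  if (s <= 0) return(1)
  int <- integrate(f, 0, s, rel.tol = 1e-10, abs.tol = 1e-14)$value
  min(1, tail_d + int)
}

#' Integrated p-value for the combined score
#'
#' Tail probability of the combined half-normal score under the null of no
#' association in any layer.
#'
#' Methods: `"exact_convolution"` (default) evaluates
#' `P(sum of D iid half-normals > s)` by numerical quadrature for any D;
#' `"closed_form"` is the closed form `1 - (2 * pnorm(s / sqrt(2)) - 1)^2`,
#' defined for D = 2 only. The two agree exactly at D = 2: the region
#' `|x| + |y| <= s` is a square that a 45-degree rotation (under which the
#' bivariate standard normal is invariant) maps to the axis-aligned box
#' with half-width `s / sqrt(2)`. `"monte_carlo"` estimates the convolution
#' tail by simulation.
#'
#' @param s Combined score (>= 0).
#' @param d Number of layers combined (D >= 1).
#' @param method One of `"exact_convolution"`, `"closed_form"`, `"monte_carlo"`.
#' @param mc_reps Monte-Carlo replicates.
#' @param seed Seed for the Monte-Carlo method.
#' @return A p-value in (0, 1].
#' @examples
#' combined_pvalue(2, 2)                       # convolution tail
#' combined_pvalue(2, 2, method = "closed_form") # closed form
#' @export
combined_pvalue <- function(s, d, method = c("exact_convolution", "closed_form",
                                             "monte_carlo"),
                            mc_reps = 1e6, seed = 1L) {
  method <- match.arg(method)
  assert_number(s, "s", lower = 0)
  d <- assert_count(d, "d")
  switch(method,
    closed_form = {
      if (d != 2L) abort("method 'closed_form' is defined for d = 2 only.")
      # 1 - (2*Phi(y) - 1)^2 factored as 4*Phi(y)*(1 - Phi(y)) to avoid
      # cancellation in the far tail
      y <- s * sqrt(2) / 2
      p <- 4 * pnorm(y) * pnorm(y, lower.tail = FALSE)
      max(p, .Machine$double.xmin)
    },
    exact_convolution = {
      p <- half_normal_sum_tail(s, d)
      max(p, .Machine$double.xmin)
    },
    monte_carlo = {
      set.seed(assert_seed(seed))
      mc_reps <- assert_count(mc_reps, "mc_reps")
      hits <- 0
      left <- mc_reps
      while (left > 0) {
        chunk <- min(left, 2e6)
        sims <- matrix(abs(rnorm(chunk * d)), nrow = d)
        hits <- hits + sum(colSums(sims) > s)
        left <- left - chunk
      }
      (hits + 1) / (mc_reps + 1)   # never exactly 0
    }
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone, capped at 1, order-preserving in the
#' p-value ranks).
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Vector of BH q-values.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("all p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Collapse probe-level records to feature level
#'
#' When several probes map to one feature, the most significant probe
#' represents the feature: smallest p-value, ties broken by larger absolute
#' score, then by lexicographic probe ID. Probes without a feature mapping
#' are dropped with a warning.
#'
#' @param probe_table Data frame with columns `probe`, `feature`, `p`, `score`.
#' @return Tibble with one row per feature (columns `feature`, `probe`, `p`,
#'   `score`).
#' @export
collapse_probes <- function(probe_table) {
  pt <- as_tibble(probe_table)
  need <- c("probe", "feature", "p", "score")
  if (!all(need %in% names(pt))) {
    abort(paste0("`probe_table` must have columns: ", paste(need, collapse = ", ")))
  }
  unmapped <- is.na(pt$feature) | pt$feature == ""
  if (any(unmapped)) {
    warn(sprintf("dropping %d unmapped probe(s): %s", sum(unmapped),
                 paste(head(pt$probe[unmapped], 5), collapse = ", ")))
    pt <- pt[!unmapped, ]
  }
  pt |>
    arrange(.data$feature, .data$p, dplyr::desc(abs(.data$score)), .data$probe) |>
    distinct(.data$feature, .keep_all = TRUE) |>
    select("feature", "probe", "p", "score")
}

#' Integrate association evidence across omics layers
#'
#' Runs the full meta-integration for each feature: per-layer pooled t
#' score, permutation standardization, half-normal combined score, integrated
#' p-value and BH FDR across features. Features present in a subset of the
#' supplied layers are combined over the layers they appear in (D = 1 uses
#' the half-normal tail of the single absolute standardized score).
#'
#' The `"permutation"` p-value method pools permuted combined scores across
#' all features sharing the same layer set and compares each observed
#' combined score against that pooled null; it is exactly calibrated in
#' finite samples and is the method of choice for null-calibration checks.
#' The other methods are as in [combined_pvalue()].
#'
#' @param omics Named list of [omics_matrix()] objects (the layers), sharing
#'   sample IDs and group labels.
#' @param method Integrated p-value method: `"exact_convolution"` (default),
#'   `"closed_form"` (two layers only), `"monte_carlo"`, or `"permutation"`.
#' @param scheme Permutation scheme for the standardization sd, see
#'   [permutation_sd()].
#' @param n_perm Sampled relabelings when the sampled scheme is in effect.
#' @param mc_reps Monte-Carlo replicates for `method = "monte_carlo"`.
#' @param seed Integer seed (sampled permutations / Monte Carlo).
#' @return A tibble of class `tromics_integration`, one row per feature,
#'   sorted by integrated p-value: columns `feature`, per-layer `s_*`, `sd_*`,
#'   `z_*`, `p_*`, plus `n_layers`, `s_meta`, `p_inte`, `q_inte`.
#' @export
integrate_omics <- function(omics, method = c("exact_convolution", "closed_form",
                                              "monte_carlo", "permutation"),
                            scheme = c("auto", "exhaustive", "sampled"),
                            n_perm = 10000, mc_reps = 1e6, seed = 1L) {
  method <- match.arg(method)
  scheme <- match.arg(scheme)
  if (!is.list(omics) || length(omics) < 1L) {
    abort("`omics` must be a non-empty named list of omics_matrix objects.")
  }
  if (is.null(names(omics)) || any(names(omics) == "")) {
    abort("`omics` must be a *named* list (layer names).")
  }
  ok <- vapply(omics, inherits, logical(1), "omics_matrix")
  if (!all(ok)) abort("all elements of `omics` must be omics_matrix objects.")

  layers <- names(omics)
  all_features <- sort(unique(unlist(lapply(omics, function(o) rownames(o$values)))))
  if (length(all_features) == 0L) {
    abort("no features found in the supplied layers.")
  }
  samp1 <- colnames(omics[[1]]$values)
  grp1 <- as.character(omics[[1]]$groups)
  for (k in seq_along(omics)) {
    if (!identical(colnames(omics[[k]]$values), samp1) ||
        !identical(as.character(omics[[k]]$groups), grp1)) {
      abort("all layers must share the same ordered sample IDs and group labels.")
    }
  }

  # One set of balanced relabelings shared by all layers, so that permuted
  # combined scores sum per-layer statistics under the *same* relabeling.
  ind_shared <- balanced_relabelings(high_indicator(omics[[1]]), scheme,
                                     n_perm = n_perm,
                                     seed = stage_seed(seed, "integration"))

  # Per-layer observed t, permutation sd and permuted t matrices.
  per_layer <- lapply(seq_along(omics), function(k) {
    om <- omics[[k]]
    ind <- ind_shared
    keep <- matrixStats_row_ok(om$values, om$groups)
    if (!all(keep)) {
      warn(sprintf("layer '%s': dropping %d feature(s) with zero pooled variance.",
                   layers[k], sum(!keep)))
    }
    vals <- om$values[keep, , drop = FALSE]
    tmat <- row_t_stats(vals, ind)          # features x relabelings (obs first)
    sds <- apply(tmat, 1, sd)
    pos <- sds > 0 & is.finite(sds)
    tmat <- tmat[pos, , drop = FALSE]
    sds <- sds[pos]
    list(
      features = rownames(vals)[pos],
      t_obs = tmat[, 1],
      sd = sds,
      z_obs = tmat[, 1] / sds,
      z_perm = sweep(abs(tmat), 1, sds, "/")  # |t|/sd per relabeling
    )
  })
  names(per_layer) <- layers

  # Assemble per-feature layer membership.
  z_by_layer <- lapply(per_layer, function(pl) setNames(pl$z_obs, pl$features))
  t_by_layer <- lapply(per_layer, function(pl) setNames(pl$t_obs, pl$features))
  sd_by_layer <- lapply(per_layer, function(pl) setNames(pl$sd, pl$features))

  present <- vapply(layers, function(l) all_features %in% names(z_by_layer[[l]]),
                    logical(length(all_features)))
  present <- matrix(present, ncol = length(layers),
                    dimnames = list(all_features, layers))
  keep_feat <- rowSums(present) >= 1L
  features <- all_features[keep_feat]
  present <- present[keep_feat, , drop = FALSE]

  zmat <- vapply(layers, function(l) unname(z_by_layer[[l]][features]),
                 numeric(length(features)))
  zmat <- matrix(zmat, ncol = length(layers), dimnames = list(features, layers))
  s_meta <- rowSums(abs(zmat), na.rm = TRUE)
  n_layers <- rowSums(present)

  p_inte <- numeric(length(features))
  if (method == "permutation") {
    # Pool permuted combined scores across features with the same layer set.
    sig <- apply(present, 1, function(r) paste(layers[r], collapse = "+"))
    for (cls in unique(sig)) {
      idx <- which(sig == cls)
      lset <- strsplit(cls, "+", fixed = TRUE)[[1]]
      feats <- features[idx]
      null_s <- Reduce(`+`, lapply(lset, function(l) {
        pl <- per_layer[[l]]
        pl$z_perm[match(feats, pl$features), , drop = FALSE]
      }))
      pooled <- sort(as.vector(null_s))
      n_pool <- length(pooled)
      obs <- s_meta[idx]
      # count of pooled null >= obs (the observed labeling is in the pool)
      n_ge <- n_pool - findInterval(obs - 1e-12, pooled)
      p_inte[idx] <- pmax(n_ge, 1L) / n_pool
    }
  } else {
    for (i in seq_along(features)) {
      d_i <- n_layers[i]
      p_inte[i] <- if (method == "closed_form" && d_i != 2L) {
        combined_pvalue(s_meta[i], d_i, method = "exact_convolution")
      } else {
        combined_pvalue(s_meta[i], d_i, method = method,
                        mc_reps = mc_reps, seed = stage_seed(seed, "integration") + i)
      }
    }
  }

  out <- tibble(feature = features)
  for (l in layers) {
    out[[paste0("s_", l)]] <- unname(t_by_layer[[l]][features])
    out[[paste0("sd_", l)]] <- unname(sd_by_layer[[l]][features])
    out[[paste0("z_", l)]] <- unname(z_by_layer[[l]][features])
    zl <- out[[paste0("z_", l)]]
    out[[paste0("p_", l)]] <- 2 * pnorm(abs(zl), lower.tail = FALSE)
  }
  out$n_layers <- as.integer(n_layers)
  out$s_meta <- unname(s_meta)
  out$p_inte <- p_inte
  out$q_inte <- bh_fdr(p_inte)
  out <- arrange(out, .data$p_inte, .data$feature)
  class(out) <- c("tromics_integration", class(out))
  attr(out, "method") <- method
  attr(out, "layers") <- layers
  out
}

# TRUE for rows with positive pooled variance.
matrixStats_row_ok <- function(mat, groups) {
  g1 <- groups == levels(groups)[1]
  v1 <- apply(mat[, g1, drop = FALSE], 1, var)
  v2 <- apply(mat[, !g1, drop = FALSE], 1, var)
  (v1 + v2) > 0
}
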