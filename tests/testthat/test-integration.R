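# The meta-integration stage: per-layer scores, permutation
# standardization, half-normal combination, FDR.

test_that("pooled t statistic matches the hand-computed oracle", {
  # groups {1,2,3} vs {4,5,6}: pooled sp^2 = 1, se = sqrt(2/3)
  t_obs <- two_group_t(c(1, 2, 3, 4, 5, 6), rep(c("high", "low"), each = 3))
  expect_equal(t_obs, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(round(t_obs, 3), -3.674)
  # identical groups give exactly zero
  expect_equal(two_group_t(c(1, 2, 3, 1, 2, 3), rep(c("high", "low"), each = 3)), 0)
  # sign convention: positive = higher in the high arm
  expect_gt(two_group_t(c(4, 5, 6, 1, 2, 3), rep(c("high", "low"), each = 3)), 0)
})

test_that("degenerate inputs to two_group_t error", {
  expect_error(two_group_t(rep(5, 6), rep(c("high", "low"), each = 3)),
               "zero pooled variance")
  expect_error(two_group_t(c(1, 2, 3), c("high", "low", "low")), "at least 2")
  expect_error(two_group_t(1:4, rep("high", 4)), "two distinct")
})

test_that("exhaustive permutation sd equals the brute-force enumeration", {
  set.seed(8)
  for (rep in 1:5) {
    x <- rnorm(6)
    sd_pkg <- permutation_sd(x, rep(c("high", "low"), each = 3),
                             scheme = "exhaustive")
    expect_equal(sd_pkg, brute_perm_sd(x, 3), tolerance = 1e-12)
  }
})

test_that("exhaustive permutation sd is invariant to swapping the group labels", {
  set.seed(9)
  x <- rnorm(10)
  lab <- rep(c("high", "low"), each = 5)
  swapped <- rep(c("low", "high"), each = 5)
  expect_equal(permutation_sd(x, lab, scheme = "exhaustive"),
               permutation_sd(x, swapped, scheme = "exhaustive"),
               tolerance = 1e-12)
})

test_that("permutation sd rejects constant vectors and tiny n_perm", {
  expect_error(permutation_sd(rep(1, 6), rep(c("high", "low"), each = 3)),
               "constant")
  expect_error(permutation_sd(rnorm(6), rep(c("high", "low"), each = 3),
                              scheme = "sampled", n_perm = 1),
               "n_perm")
})

test_that("standardize and combined_score follow their definitions", {
  expect_equal(standardize(2, 1), 2)
  expect_equal(standardize(0, 5), 0)
  expect_equal(round(standardize(-3.674, 1.155), 3), -3.181)
  expect_error(standardize(1, 0), "positive")
  expect_equal(combined_score(c(0, 0)), 0)
  expect_equal(combined_score(c(1, -1)), 2)
  expect_equal(combined_score(c(2.74, 3.07)), 5.81)
  expect_error(combined_score(numeric(0)), "at least one")
})

test_that("combined_pvalue honors its closed forms and preconditions", {
  for (m in c("exact_convolution", "closed_form", "monte_carlo")) {
    expect_equal(combined_pvalue(0, 2, method = m), 1, tolerance = 1e-3)
  }
  # the closed form at s = 2
  expect_equal(combined_pvalue(2, 2, method = "closed_form"),
               1 - (2 * pnorm(sqrt(2)) - 1)^2, tolerance = 1e-12)
  expect_equal(round(combined_pvalue(2, 2, method = "closed_form"), 4), 0.2899)
  expect_error(combined_pvalue(2, 3, method = "closed_form"), "d = 2")
  expect_error(combined_pvalue(-1, 2), "in \\[0")
})

test_that("the D = 1 convolution tail is the half-normal tail", {
  for (s in c(0.2, 1, 2.5, 4)) {
    expect_equal(combined_pvalue(s, 1), 2 * pnorm(s, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("the closed form and the quadrature tail coincide at D = 2", {
  # |x| + |y| <= s is a rotated square; rotation invariance of the
  # bivariate normal makes the closed form exact
  for (s in c(0.5, 1, 2, 3, 5)) {
    expect_equal(combined_pvalue(s, 2, method = "exact_convolution"),
                 combined_pvalue(s, 2, method = "closed_form"),
                 tolerance = 1e-8)
  }
})

test_that("combined_pvalue is strictly decreasing in the score", {
  for (d in 1:3) {
    grid <- seq(0.2, 6, by = 0.2)
    p <- vapply(grid, combined_pvalue, numeric(1), d = d)
    expect_true(all(diff(p) < 0))
  }
})

test_that("bh_fdr matches the hand oracle and a brute-force implementation", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p), brute_bh(p), tolerance = 1e-12)
  }
})

test_that("probe collapsing keeps the most significant probe with stated tie-breaks", {
  pt <- tibble::tibble(
    probe = c("a1", "a2", "b1", "c1", "c2", "d1"),
    feature = c("A", "A", "B", "C", "C", NA),
    p = c(0.3, 0.01, 0.5, 0.05, 0.05, 0.2),
    score = c(1, 2, 1, 1.0, -2.0, 3)
  )
  expect_warning(out <- collapse_probes(pt), "unmapped")
  expect_equal(out$probe[out$feature == "A"], "a2")     # smaller p wins
  expect_equal(out$probe[out$feature == "B"], "b1")     # singleton identity
  expect_equal(out$probe[out$feature == "C"], "c2")     # tie -> larger |score|
  expect_false("d1" %in% out$probe)
})

test_that("single-layer integration reduces to the half-normal tail of |Z|", {
  om <- toy_matrix(n_features = 30, seed = 2)
  res <- suppressMessages(integrate_omics(list(expression = om), seed = 1))
  expect_equal(res$p_inte,
               2 * pnorm(abs(res$z_expression), lower.tail = FALSE),
               tolerance = 1e-9)
  expect_true(all(diff(res$p_inte) >= 0))                # sorted ascending
  expect_true(all(res$q_inte >= res$p_inte - 1e-12))     # BH never shrinks
  expect_equal(res$s_meta, abs(res$z_expression))
})

test_that("two-layer integration combines scores as the sum of |Z|", {
  ds <- generate_dataset(synthetic_config(n_genes = 80, frac_diff_genes = 0.1,
                                          module_size = 4, seed = 6))
  res <- dataset_integration(ds)
  expect_equal(res$s_meta, abs(res$z_expression) + abs(res$z_methylation),
               tolerance = 1e-12)
  expect_equal(res$n_layers, rep(2L, nrow(res)))
})

test_that("planted genes rank ahead of null genes in the integrated ordering", {
  ds <- generate_dataset(synthetic_config(n_genes = 400, frac_diff_genes = 0.05,
                                          seed = 12))
  res <- dataset_integration(ds)
  planted <- res$feature %in% ds$truth$diff_genes  # row order = p_inte rank
  expect_lt(median(which(planted)), median(which(!planted)))
})

test_that("the pooled permutation method is calibrated under the global null", {
  ds <- generate_dataset(synthetic_config(n_genes = 600, frac_diff_genes = 0,
                                          seed = 19))
  res <- dataset_integration(ds, method = "permutation")
  expect_gt(stats::ks.test(res$p_inte, "punif")$p.value, 0.01)
  expect_true(all(res$p_inte > 0 & res$p_inte <= 1))
})

test_that("integration demands aligned layers", {
  a <- toy_matrix(n_features = 10, seed = 1)
  b <- toy_matrix(n_features = 10, n_per_group = 4, seed = 2)
  expect_error(integrate_omics(list(x = a, y = b)), "same ordered sample")
  expect_error(integrate_omics(list(a)), "named")
})
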