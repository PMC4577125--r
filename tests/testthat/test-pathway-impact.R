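# Pathway impact: hypergeometric over-representation, linear perturbation
# propagation, bootstrap perturbation p, global combination.

test_that("seed-gene selection respects the threshold edge cases", {
  ds <- generate_dataset(synthetic_config(n_genes = 100, frac_diff_genes = 0.1,
                                          module_size = 4, seed = 2))
  integ <- dataset_integration(ds)
  expect_length(suppressWarnings(select_seed_genes(integ, ds$expression,
                                                   alpha = 0))$seeds, 0)
  expect_length(select_seed_genes(integ, ds$expression, alpha = 1)$seeds, 100)
  expect_warning(select_seed_genes(integ, ds$expression, alpha = 0), "empty seed")
  sel <- select_seed_genes(integ, ds$expression, alpha = 0.05)
  expect_true(all(sel$delta_e[setdiff(names(sel$delta_e), sel$seeds)] == 0))
})

test_that("over-representation p is the hypergeometric upper tail", {
  expect_equal(overrepresentation_p(2, 2, 5, 10), 10 / 45, tolerance = 1e-12)
  expect_equal(overrepresentation_p(0, 5, 3, 20), 1)
  expect_equal(overrepresentation_p(4, 4, 4, 4), 1)
  expect_error(overrepresentation_p(5, 4, 4, 10), "inconsistent")
})

test_that("perturbation factors solve the propagation system on hand fixtures", {
  # no edges: PF = deltaE, t_A = 0
  pw0 <- list(members = c("A", "B"),
              edges = tibble::tibble(source = character(),
                                     target = character(), beta = numeric()))
  r0 <- perturbation_factors(pw0, c(A = 1, B = 2))
  expect_equal(r0$t_a, 0)
  expect_equal(unname(r0$pf), c(1, 2))

  # chain A -> B with beta +1: PF = (1, 1), Acc(B) = 1, t_A = 1
  pw1 <- list(members = c("A", "B"),
              edges = tibble::tibble(source = "A", target = "B", beta = 1))
  r1 <- perturbation_factors(pw1, c(A = 1, B = 0))
  expect_equal(unname(r1$pf), c(1, 1))
  expect_equal(unname(r1$acc["B"]), 1)
  expect_equal(r1$t_a, 1)

  # fan A -> {B, C}: downstream count 2 halves the propagated signal
  pw2 <- list(members = c("A", "B", "C"),
              edges = tibble::tibble(source = c("A", "A"),
                                     target = c("B", "C"), beta = c(1, 1)))
  r2 <- perturbation_factors(pw2, c(A = 1, B = 0, C = 0))
  expect_equal(unname(r2$pf), c(1, 0.5, 0.5))
  expect_equal(r2$t_a, 1)

  # inhibition flips the propagated sign
  pw3 <- list(members = c("A", "B"),
              edges = tibble::tibble(source = "A", target = "B", beta = -1))
  expect_equal(perturbation_factors(pw3, c(A = 1, B = 0))$t_a, -1)
})

test_that("a symmetric two-cycle is flagged as singular", {
  pw <- list(members = c("A", "B"),
             edges = tibble::tibble(source = c("A", "B"), target = c("B", "A"),
                                    beta = c(1, 1)))
  r <- perturbation_factors(pw, c(A = 1, B = 0))
  expect_identical(r$status, "inversion_failed")
  expect_true(is.na(r$t_a))
})

test_that("perturbation is linear in the expression shifts", {
  pw <- list(members = c("A", "B", "C"),
             edges = tibble::tibble(source = c("A", "B"), target = c("B", "C"),
                                    beta = c(1, 1)))
  t1 <- perturbation_factors(pw, c(A = 1, B = 0.5, C = 0))$t_a
  t2 <- perturbation_factors(pw, c(A = 2, B = 1.0, C = 0))$t_a
  expect_equal(t2, 2 * t1, tolerance = 1e-12)
})

test_that("bootstrap perturbation p-values behave at the boundaries", {
  pw <- list(members = c("A", "B", "C"),
             edges = tibble::tibble(source = "A", target = "B", beta = 1))
  # all shifts zero: degenerate null, p = 1
  expect_equal(perturbation_p(pw, c(A = 0, B = 0, C = 0), numeric(0))$p_pert, 1)
  # edgeless pathway: t_A identically zero, p = 1
  pw_e <- list(members = c("A", "B"),
               edges = tibble::tibble(source = character(),
                                      target = character(), beta = numeric()))
  expect_equal(perturbation_p(pw_e, c(A = 2, B = 0), c(2, -1, 0.5))$p_pert, 1)
  # determinism and the 1/B floor
  r1 <- perturbation_p(pw, c(A = 2, B = 0, C = 0), c(2, -1, 3), b_reps = 500,
                       seed = 7)
  r2 <- perturbation_p(pw, c(A = 2, B = 0, C = 0), c(2, -1, 3), b_reps = 500,
                       seed = 7)
  expect_identical(r1, r2)
  expect_gte(r1$p_pert, 1 / 500)
})

test_that("the global combination obeys its closed form and bounds", {
  expect_equal(combine_global(1, 1), 1)
  expect_error(combine_global(0, 0.5), "\\(0, 1\\]")
  # P_G = c - c ln c >= c for c in (0, 1], and decreasing in c toward 0
  cs <- c(1e-6, 1e-3, 0.05, 0.4, 1)
  pg <- combine_global(cs, 1)
  expect_true(all(pg >= cs))
  expect_true(all(pg <= 1 + 1e-12))
  expect_true(all(diff(pg) > 0))
})

test_that("run_pathway_impact handles null pathways and sorts by P_G", {
  ds <- generate_dataset(synthetic_config(n_genes = 300, frac_diff_genes = 0.05,
                                          seed = 23))
  integ <- dataset_integration(ds)
  res <- suppressMessages(run_pathway_impact(ds$pathways, integ, ds$expression,
                                             b_reps = 200, seed = 1))
  expect_true(all(diff(res$p_g) >= 0))
  expect_true(all(res$p_g >= res$p_nde * res$p_pert - 1e-12))
  expect_true(all(res$p_g > 0 & res$p_g <= 1))
  # a pathway disjoint from the seeds, with no shifts, is entirely null
  null_pw <- structure(
    tibble::tibble(pathway = "nullpw",
                   members = list(c("zz1", "zz2", "zz3")),
                   edges = list(tibble::tibble(source = character(),
                                               target = character(),
                                               beta = numeric()))),
    class = c("tromics_pathways", class(tibble::tibble())))
  expr_null <- omics_matrix(
    matrix(rnorm(30), 3, 10,
           dimnames = list(c("zz1", "zz2", "zz3"), sprintf("s%02d", 1:10))),
    rep(c("high", "low"), each = 5))
  integ_null <- suppressMessages(integrate_omics(list(expression = expr_null)))
  integ_null$p_inte <- rep(1, 3)  # force an empty seed set
  res0 <- suppressWarnings(suppressMessages(
    run_pathway_impact(null_pw, integ_null, expr_null, b_reps = 200, seed = 1)))
  expect_equal(res0$p_nde, 1)
  expect_equal(res0$p_pert, 1)
  expect_equal(res0$p_g, 1)
})

test_that("the seeded pathway carries the strongest over-representation evidence", {
  hits <- 0
  for (s in 1:3) {
    ds <- generate_dataset(synthetic_config(seed = 400 + s))
    integ <- dataset_integration(ds, seed = s)
    res <- suppressMessages(run_pathway_impact(ds$pathways, integ, ds$expression,
                                               b_reps = 200, seed = s))
    if (res$pathway[which.min(res$q_nde)] == "pw001") hits <- hits + 1
  }
  expect_gte(hits, 2)
})
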