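# PCST module discovery: prizes, evidence-combined costs, exact and
# heuristic solvers, lambda calibration, module assembly.

test_that("node prizes are natural-log surprisals with an optional floor", {
  expect_equal(node_prize(1), 0)
  expect_equal(round(node_prize(0.05), 3), 2.996)
  expect_equal(round(suppressMessages(node_prize(1e-20, p_floor = 1e-16)), 2),
               36.84)
  expect_error(node_prize(0), "0, 1")
  expect_error(node_prize(-0.1), "0, 1")
})

test_that("edge evidence combines multiplicatively into the cost", {
  expect_equal(combine_edge_evidence(0.9, use_corr = FALSE)$cost, 0.1)
  expect_equal(combine_edge_evidence(0.9, -0.5, use_corr = TRUE)$cost, 0.55)
  expect_equal(combine_edge_evidence(0, 0.8, use_corr = TRUE)$cost, 1)
  # noisy-OR reliability
  expect_equal(combine_edge_evidence(0.9, -0.5, use_corr = TRUE)$reliability,
               1 - 0.1 * 0.5)
  expect_error(combine_edge_evidence(1.2), "\\[0, 1\\]")
  expect_error(combine_edge_evidence(0.5, 1.5, use_corr = TRUE), "\\[-1, 1\\]")
  # channel clipping keeps the cost strictly positive
  expect_gt(combine_edge_evidence(1, -1, use_corr = TRUE)$cost, 0)
})

test_that("prize_graph validates structure", {
  nodes <- tibble::tibble(id = c("a", "b"), prize = c(1, 2))
  expect_error(prize_graph(nodes, tibble::tibble(from = "a", to = "c", cost = 0.5)),
               "endpoints")
  expect_error(prize_graph(nodes, tibble::tibble(from = "a", to = "b", cost = 0)),
               "\\(0, 1\\]")
  expect_error(prize_graph(tibble::tibble(id = c("a", "a"), prize = c(1, 1)),
                           tibble::tibble(from = character(), to = character(),
                                          cost = numeric())),
               "unique")
  g <- prize_graph(nodes, tibble::tibble(from = c("a", "b"), to = c("b", "a"),
                                         cost = c(0.5, 0.3)))
  expect_equal(nrow(g$edges), 1)       # parallel edges collapse to min cost
  expect_equal(g$edges$cost, 0.3)
})

test_that("exact solver handles singletons and the lambda = 0 tie-break", {
  g <- prize_graph(tibble::tibble(id = "x", prize = 2),
                   tibble::tibble(from = character(), to = character(),
                                  cost = numeric()))
  m <- pcst_exact(g, 0.5)
  expect_equal(m$nodes$id, "x")
  expect_equal(m$objective, -0.5 * 2)

  g2 <- random_prize_graph(6, seed = 99)
  m0 <- pcst_exact(g2, 0)
  expect_equal(m0$objective, 0)
  expect_equal(m0$nodes$prize, max(g2$nodes$prize))  # highest-prize singleton
  expect_error(pcst_exact(random_prize_graph(16, 1), 0.5), "15 nodes")
})

test_that("exact solver matches the independent enumeration oracle", {
  lambdas <- c(0.1, 0.5, 1)
  for (s in 1:12) {
    g <- random_prize_graph(sample(5:9, 1), seed = 500 + s)
    mods <- pcst_exact(g, lambdas)
    expect_equal(vapply(mods, function(m) m$objective, numeric(1)),
                 pcst_oracle(g, lambdas), tolerance = 1e-9)
    for (m in mods) {
      expect_equal(nrow(m$edges), max(0, nrow(m$nodes) - 1))  # always a tree
      if (any(g$nodes$prize > 0)) expect_lte(m$objective, 0)
    }
  }
})

test_that("the returned module tree is connected and spans its nodes", {
  g <- random_prize_graph(8, seed = 31)
  m <- pcst_exact(g, 0.6)
  if (nrow(m$nodes) > 1) {
    ig <- igraph::graph_from_data_frame(m$edges, directed = FALSE,
                                        vertices = m$nodes$id)
    expect_true(igraph::is_connected(ig))
  }
  expect_true(all(c(m$edges$from, m$edges$to) %in% m$nodes$id))
})

test_that("heuristic is never worse than the best singleton and is deterministic", {
  for (s in 1:8) {
    g <- random_prize_graph(10, seed = 600 + s)
    lam <- 0.4
    m <- pcst_heuristic(g, lam)
    expect_lte(m$objective, -lam * max(g$nodes$prize) + 1e-9)
    expect_identical(m, pcst_heuristic(g, lam))
  }
})

test_that("heuristic equals the exact solver on trees", {
  for (s in 1:8) {
    set.seed(700 + s)
    n <- 9
    ids <- sprintf("t%02d", 1:n)
    parents <- vapply(2:n, function(k) sample(k - 1, 1), integer(1))
    g <- prize_graph(
      tibble::tibble(id = ids, prize = -log(runif(n))),
      tibble::tibble(from = ids[parents], to = ids[2:n],
                     cost = runif(n - 1, 0.05, 1))
    )
    for (lam in c(0.2, 0.6)) {
      expect_equal(pcst_heuristic(g, lam)$objective,
                   pcst_exact(g, lam)$objective, tolerance = 1e-9)
    }
  }
})

test_that("heuristic stays close to exact on general small graphs", {
  ok <- 0; total <- 0
  for (s in 1:25) {
    g <- random_prize_graph(sample(6:11, 1), seed = 800 + s)
    for (lam in c(0.2, 0.5, 0.9)) {
      ex <- pcst_exact(g, lam)$objective
      hb <- pcst_heuristic(g, lam)$objective
      total <- total + 1
      if (abs(hb - ex) <= 0.05 * abs(ex) + 1e-9) ok <- ok + 1
    }
  }
  expect_gte(ok / total, 0.95)
})

test_that("collected prize is nondecreasing in lambda (exact sweep)", {
  for (s in 1:5) {
    g <- random_prize_graph(9, seed = 900 + s)
    mods <- pcst_exact(g, seq(0.05, 1, by = 0.05))
    prz <- vapply(mods, function(m) m$collected_prize, numeric(1))
    expect_true(all(diff(prz) >= -1e-9))
  }
})

test_that("lambda calibration honors its sweep contract", {
  # a recovery target of zero is met by the first sweep value
  cal0 <- calibrate_lambda(n_nodes = 8, density = 0.3, recovery_target = 0,
                           n_sim = 2, seed = 1)
  expect_equal(cal0$lambda_star, 0.01)
  # an unattainable target falls back to the sweep maximum with a warning
  expect_warning(
    cal2 <- calibrate_lambda(n_nodes = 8, density = 0.3, recovery_target = 1.01,
                             n_sim = 2, seed = 1),
    "not reached"
  )
  expect_equal(cal2$lambda_star, 1)
  # reproducibility and the self-consistency of the returned lambda
  cal <- calibrate_lambda(n_nodes = 10, density = 0.25, n_sim = 3, seed = 5)
  cal_b <- calibrate_lambda(n_nodes = 10, density = 0.25, n_sim = 3, seed = 5)
  expect_identical(cal$lambda_star, cal_b$lambda_star)
  if (cal$reached) {
    at_star <- cal$sweep$mean_recovery[cal$sweep$lambda == cal$lambda_star]
    expect_gte(at_star, 0.70)
  }
})

test_that("candidate selection takes the union of the two routes", {
  ds <- generate_dataset(synthetic_config(n_genes = 300, frac_diff_genes = 0.05,
                                          seed = 33))
  integ <- dataset_integration(ds)
  pw <- suppressMessages(run_pathway_impact(ds$pathways, integ, ds$expression,
                                            b_reps = 200, seed = 1))
  cand <- select_candidates(integ, pw, ds$pathways)
  expect_true(all(integ$feature[integ$q_inte <= 0.05] %in% cand))
  expect_false(anyDuplicated(cand) > 0)
  expect_error(select_candidates(integ, pw, ds$pathways,
                                 q_thresh = 0, p_thresh = 0),
               "no candidate")
})

test_that("find_module shrinks to a singleton as lambda vanishes and drops outsiders", {
  ds <- generate_dataset(synthetic_config(n_genes = 300, frac_diff_genes = 0.05,
                                          seed = 35))
  integ <- dataset_integration(ds)
  cand <- integ$feature[integ$p_inte <= 0.01]
  m <- suppressMessages(find_module(c(cand, "not_a_gene"), ds$interactome,
                                    ds$expression, integ, lambda = 1e-6))
  expect_lte(nrow(m$nodes), 1)
  expect_message(find_module(c(cand, "not_a_gene"), ds$interactome,
                             ds$expression, integ, lambda = 0.3),
                 "absent from the interactome")
})

test_that("zero-prize linkers can reconnect separated candidates", {
  # path a - x - b where x is not a candidate
  inter <- tibble::tibble(from = c("a", "x"), to = c("x", "b"),
                          reliability = c(0.95, 0.95))
  integ <- tibble::tibble(feature = c("a", "b"),
                          p_inte = c(1e-6, 1e-6), q_inte = c(1e-4, 1e-4))
  no_link <- find_module(c("a", "b"), inter, NULL, integ, lambda = 0.9,
                         allow_linkers = FALSE)
  expect_equal(nrow(no_link$nodes), 1)   # disconnected: best singleton
  with_link <- find_module(c("a", "b"), inter, NULL, integ, lambda = 0.9,
                           allow_linkers = TRUE)
  expect_setequal(with_link$nodes$id, c("a", "b", "x"))
  expect_equal(with_link$nodes$prize[with_link$nodes$id == "x"], 0)
})
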