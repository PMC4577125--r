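# miRNA selection, anti-correlation screening, pattern classification and
# the combined network.

test_that("miRNA selection keeps the classes disjoint with EM precedence", {
  em <- tibble::tibble(feature = c("m1", "m2", "m3"),
                       p_inte = c(0.01, 0.20, 0.04))
  class(em) <- c("tromics_integration", class(em))
  es <- tibble::tibble(feature = c("m1", "m2", "m3", "m4", "m5"),
                       p = c(0.001, 0.01, 0.5, 0.03, 0.9))
  out <- select_mirnas(em, es, alpha = 0.05)
  expect_setequal(out$mirna[out$class == "EM"], c("m1", "m3"))
  # m2 is present in the EM table, so the E route never picks it up
  expect_setequal(out$mirna[out$class == "E"], "m4")
  expect_equal(nrow(select_mirnas(em, es, alpha = 0)), 0)
})

test_that("correlation matrix is exact on constructed vectors", {
  samp <- sprintf("s%02d", 1:10)
  gv <- matrix(rnorm(20), 2, 10, dimnames = list(c("gA", "gB"), samp))
  mv <- rbind(m1 = -gv["gA", ], m2 = rep(1, 10))
  colnames(mv) <- samp
  ge <- omics_matrix(gv, rep(c("high", "low"), each = 5))
  me <- omics_matrix(mv, rep(c("high", "low"), each = 5))
  out <- suppressMessages(mirna_gene_correlations(me, ge, c("gA", "gB")))
  expect_equal(out$r[out$mirna == "m1" & out$gene == "gA"], -1, tolerance = 1e-12)
  expect_false("m2" %in% out$mirna)   # constant vector excluded
})

test_that("null correlations follow the analytic null distribution", {
  # r * sqrt(n-2) / sqrt(1-r^2) ~ t(n-2) for independent normal pairs
  set.seed(14)
  n <- 10
  samp <- sprintf("s%02d", 1:n)
  gv <- matrix(rnorm(200 * n), 200, n,
               dimnames = list(sprintf("g%03d", 1:200), samp))
  mv <- matrix(rnorm(50 * n), 50, n,
               dimnames = list(sprintf("m%03d", 1:50), samp))
  ge <- omics_matrix(gv, rep(c("high", "low"), each = 5))
  me <- omics_matrix(mv, rep(c("high", "low"), each = 5))
  out <- mirna_gene_correlations(me, ge, rownames(gv))
  tt <- out$r * sqrt(n - 2) / sqrt(1 - out$r^2)
  expect_gt(stats::ks.test(tt, stats::pt, df = n - 2)$p.value, 0.01)
  expect_lt(mean(abs(out$r) >= 0.95), 0.005)
})

test_that("pair screening applies a strict cutoff and annotates target support", {
  corrs <- tibble::tibble(
    mirna = c("m1", "m1", "m2", "m3"),
    gene = c("g1", "g2", "g1", "g2"),
    r = c(-0.80, -0.54, -0.80, -0.56)
  )
  tm <- tibble::tibble(mirna = "m1", gene = "g1")
  out <- screen_pairs(corrs, cutoff = -0.55, target_map = tm)
  expect_equal(nrow(out), 3)                     # -0.54 excluded
  expect_false(any(out$r > -0.55))
  expect_true(out$target_supported[out$mirna == "m1" & out$gene == "g1"])
  # anti-correlated pairs without a target relationship stay, unsupported
  expect_false(out$target_supported[out$mirna == "m2" & out$gene == "g1"])
  expect_error(screen_pairs(corrs, cutoff = 0.3, target_map = tm), "cutoff")
})

make_classifier_fixture <- function() {
  # expression for the neighbor-correlation route
  set.seed(3)
  samp <- sprintf("s%02d", 1:10)
  base <- rnorm(10)
  gv <- rbind(
    gMeth = rnorm(10), gMir = rnorm(10),
    gTf = base + rnorm(10, sd = 0.1), gHub = base,
    gCo = rnorm(10), gNone = rnorm(10)
  )
  colnames(gv) <- samp
  omics_matrix(gv, rep(c("high", "low"), each = 5))
}

test_that("the four regulation patterns are assigned from their evidence", {
  ge <- make_classifier_fixture()
  genes <- rownames(ge$values)
  meth_p <- c(gMeth = 0.09, gMir = 0.8, gTf = 0.7, gHub = 0.01,
              gCo = 0.02, gNone = 0.9)
  meth_c <- c(gMeth = -0.8, gMir = -0.1, gTf = 0.2, gHub = -0.9,
              gCo = -0.7, gNone = 0.1)
  vp <- tibble::tibble(
    mirna = c("mirX", "mirY"), gene = c("gMir", "gCo"),
    r = c(-0.65, -0.70), target_supported = c(TRUE, TRUE)
  )
  nb <- tibble::tibble(from = c("gTf", "gNone"), to = c("gHub", "gMeth"))
  out <- classify_regulation(genes, meth_p, meth_c, vp, nb, ge)
  lab <- stats::setNames(out$pattern, out$gene)
  # expression p 0.01 / methylation p 0.09 with corr -0.8: methylation-driven
  expect_identical(unname(lab["gMeth"]), "METHYLATION")
  # a target-supported pair at r = -0.65 and no methylation evidence
  expect_identical(unname(lab["gMir"]), "MIRNA")
  # both evidence channels: co-regulation
  expect_identical(unname(lab["gCo"]), "CO_REGULATED")
  # neither channel, but a strongly positively correlated module neighbor
  expect_identical(unname(lab["gTf"]), "NEIGHBOR_TF")
  expect_equal(unname(out$neighbor_partner[out$gene == "gTf"]), "gHub")
  expect_identical(unname(lab["gNone"]), "UNCLASSIFIED")
  # exactly one label per module gene
  expect_equal(nrow(out), length(genes))
  expect_false(anyNA(out$pattern))
})

test_that("classification is monotone in the strength of the evidence", {
  ge <- make_classifier_fixture()
  meth_p <- c(gMeth = 0.09)
  vp0 <- tibble::tibble(mirna = character(), gene = character(),
                        r = numeric(), target_supported = logical())
  nb <- tibble::tibble(from = character(), to = character())
  base <- classify_regulation("gMeth", meth_p, c(gMeth = -0.56), vp0, nb, ge)
  stronger <- classify_regulation("gMeth", c(gMeth = 0.001), c(gMeth = -0.95),
                                  vp0, nb, ge)
  expect_identical(base$pattern, "METHYLATION")
  expect_identical(stronger$pattern, "METHYLATION")
})

test_that("missing methylation data downgrades gracefully", {
  ge <- make_classifier_fixture()
  vp0 <- tibble::tibble(mirna = character(), gene = character(),
                        r = numeric(), target_supported = logical())
  nb <- tibble::tibble(from = character(), to = character())
  expect_message(
    out <- classify_regulation("gMeth", c(other = 0.01), c(other = -0.9),
                               vp0, nb, ge),
    "lack methylation"
  )
  expect_identical(out$pattern, "UNCLASSIFIED")
})

test_that("the combined network unions module and miRNA edges", {
  g <- prize_graph(
    tibble::tibble(id = c("g1", "g2"), prize = c(3, 2),
                   candidate = TRUE, p_inte = c(1e-3, 1e-2),
                   q_inte = c(0.01, 0.05)),
    tibble::tibble(from = "g1", to = "g2", cost = 0.4)
  )
  mod <- pcst_exact(g, 0.9)
  vp <- tibble::tibble(mirna = c("mA", "mB"), gene = c("g1", "g_out"),
                       r = c(-0.7, -0.8), target_supported = c(TRUE, FALSE))
  net <- build_bipartite(mod, vp)
  expect_setequal(igraph::V(net)$name, c("g1", "g2", "mA"))
  deg <- igraph::degree(net)
  expect_gte(deg[["mA"]], 1)                    # every miRNA node attached
  kinds <- igraph::E(net)$kind
  expect_setequal(unique(kinds), c("module", "mirna"))
  # with no pairs the network is the module alone
  net0 <- build_bipartite(mod, vp[0, ])
  expect_setequal(igraph::V(net0)$name, c("g1", "g2"))
  # a singleton module with no pairs still yields a (one-node) network
  g1 <- prize_graph(tibble::tibble(id = "g1", prize = 3,
                                   candidate = TRUE, p_inte = 1e-3,
                                   q_inte = 0.01),
                    tibble::tibble(from = character(), to = character(),
                                   cost = numeric()))
  net1 <- build_bipartite(pcst_exact(g1, 0.5), vp[0, ])
  expect_equal(igraph::vcount(net1), 1)
  expect_equal(igraph::ecount(net1), 0)
})

test_that("planted regulator edges are recovered end to end", {
  hits <- 0; total <- 0
  for (s in 1:3) {
    ds <- generate_dataset(synthetic_config(seed = 520 + s))
    mt <- dataset_mirna_tables(ds, seed = s)
    mcand <- select_mirnas(mt$em, mt$e)
    tg <- ds$truth$patterns$gene[ds$truth$patterns$pattern %in%
                                   c("MIRNA", "CO_REGULATED")]
    corrs <- mirna_gene_correlations(ds$mirna_expression, ds$expression,
                                     tg, mcand$mirna)
    pairs <- screen_pairs(corrs, -0.55, ds$target_map)
    reg <- ds$truth$regulators
    for (i in seq_len(nrow(reg))) {
      total <- total + 1
      if (any(pairs$mirna == reg$mirna[i] & pairs$gene == reg$gene[i] &
                pairs$target_supported)) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.7)
})
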