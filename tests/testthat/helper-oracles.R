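# Shared fixtures and independent brute-force oracles used across tests.

# Small balanced two-group omics matrix with optional planted shift.
toy_matrix <- function(n_features = 20, n_per_group = 5, shift = 0,
                       n_shifted = 0, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  m <- matrix(rnorm(n_features * n), n_features, n,
              dimnames = list(sprintf("f%03d", seq_len(n_features)),
                              sprintf("s%02d", seq_len(n))))
  if (n_shifted > 0) {
    m[seq_len(n_shifted), seq_len(n_per_group)] <-
      m[seq_len(n_shifted), seq_len(n_per_group)] + shift
  }
  omics_matrix(m, rep(c("high", "low"), each = n_per_group))
}

# Brute-force pooled t over all balanced relabelings via t.test().
brute_perm_sd <- function(values, n_high) {
  n <- length(values)
  sets <- utils::combn(n, n_high)
  ts <- apply(sets, 2, function(ix) {
    unname(stats::t.test(values[ix], values[-ix], var.equal = TRUE)$statistic)
  })
  stats::sd(ts)
}

# Step-up BH written out longhand, independently of p.adjust.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# Random prize graph for solver tests.
random_prize_graph <- function(n, seed, edge_prob = 0.4) {
  set.seed(seed)
  ids <- sprintf("v%02d", seq_len(n))
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < edge_prob
  pairs <- pairs[keep, , drop = FALSE]
  prize_graph(
    tibble::tibble(id = ids, prize = -log(runif(n))),
    tibble::tibble(from = ids[pairs[, 1]], to = ids[pairs[, 2]],
                   cost = runif(nrow(pairs), 0.05, 1))
  )
}

# Independent PCST oracle: node-subset enumeration through igraph,
# returning, for each lambda, the best objective (MST cost minus collected
# prize). Connectivity and MST both delegated to igraph.
pcst_oracle <- function(graph, lambdas) {
  ids <- graph$nodes$id
  n <- length(ids)
  ig <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                      vertices = ids)
  subsets <- list()
  k <- 0
  for (mask in seq_len(2^n - 1)) {
    sel <- ids[bitwAnd(mask, 2^(0:(n - 1))) > 0]
    sg <- igraph::induced_subgraph(ig, sel)
    if (!igraph::is_connected(sg)) next
    mc <- if (length(sel) == 1) 0 else {
      sum(igraph::E(igraph::mst(sg, weights = igraph::E(sg)$cost))$cost)
    }
    k <- k + 1
    subsets[[k]] <- c(mc, sum(graph$nodes$prize[match(sel, ids)]))
  }
  tab <- do.call(rbind, subsets)
  vapply(lambdas, function(lam) {
    min(0, tab[, 1] - lam * tab[, 2])
  }, numeric(1))
}

# Build the gene-level integration inputs for one synthetic dataset.
dataset_integration <- function(ds, seed = 1, method = "exact_convolution") {
  suppressMessages(integrate_omics(
    list(expression = ds$expression, methylation = ds$methylation),
    method = method, seed = seed
  ))
}

# miRNA-side integration tables (EM integration + expression-only stats).
dataset_mirna_tables <- function(ds, seed = 1) {
  em_ids <- rownames(ds$mirna_methylation$values)
  me <- omics_matrix(
    ds$mirna_expression$values[em_ids, , drop = FALSE],
    stats::setNames(as.character(ds$mirna_expression$groups),
                    colnames(ds$mirna_expression$values))
  )
  list(
    em = suppressMessages(integrate_omics(
      list(expression = me, methylation = ds$mirna_methylation), seed = seed)),
    e = suppressMessages(integrate_omics(
      list(expression = ds$mirna_expression), seed = seed))
  )
}
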