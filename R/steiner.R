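# Prize-collecting Steiner tree module discovery on the weighted
# interactome: node prizes -log p, edge costs 1 - product of evidence
# reliabilities, objective sum(costs) - lambda * sum(prizes).

#' Candidate genes for module discovery
#'
#' Union of the integration-significant genes (`q_inte <= q_thresh`) and the
#' members of significant pathways with nominal `p_inte <= p_thresh`.
#'
#' @param integration Gene-level `tromics_integration` table.
#' @param pathway_results A `tromics_pathway_impact` table (its
#'   `significant` column selects pathways).
#' @param pathways The `tromics_pathways` tibble holding member sets.
#' @param q_thresh FDR threshold for the direct route (default 0.05).
#' @param p_thresh Nominal threshold for the pathway route (default 0.05).
#' @return Character vector of candidate gene IDs.
#' @export
select_candidates <- function(integration, pathway_results, pathways,
                              q_thresh = 0.05, p_thresh = 0.05) {
  assert_number(q_thresh, "q_thresh", 0, 1)
  assert_number(p_thresh, "p_thresh", 0, 1)
  direct <- integration$feature[integration$q_inte <= q_thresh]
  sig_pw <- pathway_results$pathway[pathway_results$significant]
  pw_members <- unique(unlist(pathways$members[pathways$pathway %in% sig_pw]))
  via_pathway <- integration$feature[integration$feature %in% pw_members &
                                       integration$p_inte <= p_thresh]
  out <- sort(union(direct, via_pathway))
  if (length(out) == 0L) {
    abort(paste0(
      "no candidate genes at q <= ", q_thresh, " / pathway p <= ", p_thresh,
      "; relax the thresholds or check the integration results."
    ))
  }
  out
}

#' Combine edge evidence channels into a reliability and cost
#'
#' Interaction reliability (e.g. a STRING-style score) and expression
#' correlation are treated as independent evidence channels. The combined
#' reliability is the noisy-OR `1 - (1 - R1)(1 - R2)`; the edge cost is
#' `1 - prod(R_j)` over the channels in use. Channels are clipped at 0.99 so
#' costs stay strictly positive. The correlation channel uses `|r|`.
#'
#' @param string_score Reliability in `[0, 1]`.
#' @param corr Pearson correlation in `[-1, 1]` (ignored unless `use_corr`).
#' @param use_corr Whether the correlation channel is present.
#' @return Tibble with columns `reliability` and `cost` (in `(0, 1]`).
#' @examples
#' combine_edge_evidence(0.9, -0.5, use_corr = TRUE)  # cost 0.55
#' @export
combine_edge_evidence <- function(string_score, corr = 0, use_corr = TRUE) {
  if (any(!is.finite(string_score)) || any(string_score < 0) || any(string_score > 1)) {
    abort("`string_score` must lie in [0, 1].")
  }
  r1 <- pmin(string_score, 0.99)
  if (use_corr) {
    if (any(!is.finite(corr)) || any(abs(corr) > 1)) {
      abort("`corr` must lie in [-1, 1].")
    }
    r2 <- pmin(abs(corr), 0.99)
    tibble(reliability = 1 - (1 - r1) * (1 - r2), cost = 1 - r1 * r2)
  } else {
    tibble(reliability = r1, cost = 1 - r1)
  }
}

#' Node prize from an integration p-value
#'
#' `b = -ln(p)`, non-negative for p in (0, 1]. A p-value floor can be
#' configured to cap prizes for vanishingly small p.
#'
#' @param p P-value(s) in `(0, 1]`.
#' @param p_floor Optional lower floor applied to `p` before the log
#'   (e.g. `1e-16`); without it, `p <= 0` is an error.
#' @return Prize(s) `-log(p)` in nats.
#' @export
node_prize <- function(p, p_floor = NULL) {
  if (!is.null(p_floor)) {
    assert_number(p_floor, "p_floor", lower = 0, strict_lower = TRUE)
    n_floored <- sum(p < p_floor)
    if (n_floored > 0) {
      inform(sprintf("capping %d prize(s) at the p-value floor %g.",
                     n_floored, p_floor))
    }
    p <- pmax(p, p_floor)
  }
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must lie in (0, 1] (set `p_floor` to cap smaller values).")
  }
  -log(p)
}

#' Construct a prize graph
#'
#' @param nodes Tibble/data frame with columns `id` (unique) and `prize`
#'   (>= 0); extra columns are kept as annotations.
#' @param edges Tibble/data frame with columns `from`, `to`, `cost`
#'   (in `(0, 1]`); endpoints must be node IDs.
#' @return List of class `tromics_prize_graph` with sorted `nodes` and
#'   normalized `edges` (`from < to`, parallel edges collapsed to min cost).
#' @export
prize_graph <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  if (!all(c("id", "prize") %in% names(nodes))) {
    abort("`nodes` needs columns `id` and `prize`.")
  }
  if (anyDuplicated(nodes$id)) abort("node IDs must be unique.")
  if (any(nodes$prize < 0) || any(!is.finite(nodes$prize))) {
    abort("prizes must be finite and >= 0.")
  }
  if (nrow(edges) > 0) {
    if (!all(c("from", "to", "cost") %in% names(edges))) {
      abort("`edges` needs columns `from`, `to`, `cost`.")
    }
    if (!all(c(edges$from, edges$to) %in% nodes$id)) {
      abort("edge endpoints must be node IDs.")
    }
    if (any(edges$from == edges$to)) abort("self-loops are not allowed.")
    if (any(edges$cost <= 0) || any(edges$cost > 1)) {
      abort("edge costs must lie in (0, 1].")
    }
    edges <- tibble(from = pmin(edges$from, edges$to),
                    to = pmax(edges$from, edges$to),
                    cost = edges$cost) |>
      group_by(.data$from, .data$to) |>
      summarise(cost = min(.data$cost), .groups = "drop") |>
      arrange(.data$from, .data$to)
  } else {
    edges <- tibble(from = character(), to = character(), cost = numeric())
  }
  structure(list(nodes = arrange(nodes, .data$id), edges = edges),
            class = "tromics_prize_graph")
}

# Symmetric cost matrix (Inf = no edge) in node order.
cost_matrix <- function(graph) {
  ids <- graph$nodes$id
  C <- matrix(Inf, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(graph$edges) > 0) {
    i <- match(graph$edges$from, ids); j <- match(graph$edges$to, ids)
    C[cbind(i, j)] <- graph$edges$cost
    C[cbind(j, i)] <- graph$edges$cost
  }
  diag(C) <- 0
  C
}

# Prim's MST over the nodes `idx` of cost matrix C. Returns list(cost,
# edges = 2-column index matrix into idx-space) or NULL if disconnected.
prim_mst <- function(C, idx) {
  k <- length(idx)
  if (k == 1L) return(list(cost = 0, edges = matrix(integer(0), ncol = 2)))
  sub <- C[idx, idx, drop = FALSE]
  in_tree <- rep(FALSE, k); in_tree[1] <- TRUE
  dist <- sub[1, ]; parent <- rep(1L, k)
  total <- 0
  edges <- matrix(0L, k - 1L, 2L)
  for (step in seq_len(k - 1L)) {
    dist[in_tree] <- Inf
    v <- which.min(dist)
    if (!is.finite(dist[v])) return(NULL)
    total <- total + dist[v]
    edges[step, ] <- c(parent[v], v)
    in_tree[v] <- TRUE
    upd <- !in_tree & sub[v, ] < dist
    parent[upd] <- v
    dist[upd] <- sub[v, upd]
  }
  list(cost = total, edges = edges)
}

# Assemble a module result object.
module_result <- function(graph, node_idx, tree_edges_idx, lambda, solver) {
  ids <- graph$nodes$id
  sel <- sort(ids[node_idx])
  nodes <- graph$nodes[match(sel, ids), , drop = FALSE]
  if (is.null(tree_edges_idx) || nrow(tree_edges_idx) == 0) {
    edges <- tibble(from = character(), to = character(), cost = numeric())
  } else {
    C <- cost_matrix(graph)
    u <- ids[node_idx][tree_edges_idx[, 1]]
    v <- ids[node_idx][tree_edges_idx[, 2]]
    edges <- tibble(from = pmin(u, v), to = pmax(u, v),
                    cost = C[cbind(u, v)]) |>
      arrange(.data$from, .data$to)
  }
  objective <- sum(edges$cost) - lambda * sum(nodes$prize)
  structure(
    list(nodes = nodes, edges = edges, objective = objective,
         collected_prize = sum(nodes$prize), lambda = lambda, solver = solver),
    class = "tromics_module"
  )
}

#' @export
print.tromics_module <- function(x, ...) {
  cat(sprintf(
    "<tromics_module> %d nodes, %d edges; objective %.4f (lambda = %.3g, %s)\n",
    nrow(x$nodes), nrow(x$edges), x$objective, x$lambda, x$solver
  ))
  if (nrow(x$nodes) > 0) {
    cat("  nodes:", paste(head(x$nodes$id, 12), collapse = ", "),
        if (nrow(x$nodes) > 12) "..." else "", "\n")
  }
  invisible(x)
}

#' Exact prize-collecting Steiner tree solver
#'
#' Enumerates all connected node subsets (the minimum-cost connected
#' spanning structure of a node set is its minimum spanning tree, edge
#' costs being positive) and returns the global minimizer of
#' `sum(cost) - lambda * sum(prize)`. The empty module (objective 0) is
#' admissible. Ties are broken deterministically: smallest objective, then
#' largest collected prize, then fewest nodes, then lexicographic node IDs
#' (so at `lambda = 0` the highest-prize singleton is returned).
#'
#' @param graph A [prize_graph()] with at most 15 nodes.
#' @param lambda Prize weight(s) in the objective; a vector is solved in
#'   one enumeration pass.
#' @return A `tromics_module` (or a list of them when `lambda` is a
#'   vector): nodes, tree edges, objective, collected prize.
#' @export
pcst_exact <- function(graph, lambda) {
  stopifnot(inherits(graph, "tromics_prize_graph"))
  n <- nrow(graph$nodes)
  if (n > 15L) {
    abort("pcst_exact enumerates node subsets and is limited to 15 nodes; use pcst_heuristic().")
  }
  if (any(lambda < 0)) abort("`lambda` must be >= 0.")
  C <- cost_matrix(graph)
  prizes <- graph$nodes$prize
  ids <- graph$nodes$id
  bit_lists <- lapply(seq_len(2^n - 1), function(mask) which(bitwAnd(mask, 2^(0:(n - 1))) > 0))
  mst_cost <- rep(NA_real_, 2^n - 1)
  mst_edges <- vector("list", 2^n - 1)
  sub_prize <- vapply(bit_lists, function(ix) sum(prizes[ix]), numeric(1))
  for (mask in seq_len(2^n - 1)) {
    mst <- prim_mst(C, bit_lists[[mask]])
    if (!is.null(mst)) {
      mst_cost[mask] <- mst$cost
      mst_edges[[mask]] <- mst$edges
    }
  }
  conn <- which(!is.na(mst_cost))

  solve_one <- function(lam) {
    best_mask <- 0L         # empty module
    best_obj <- 0; best_prize <- 0; best_size <- 0L; best_key <- ""
    for (mask in conn) {
      obj <- mst_cost[mask] - lam * sub_prize[mask]
      ix <- bit_lists[[mask]]
      better <- obj < best_obj - 1e-12 ||
        (abs(obj - best_obj) <= 1e-12 &&
           (sub_prize[mask] > best_prize + 1e-12 ||
              (abs(sub_prize[mask] - best_prize) <= 1e-12 &&
                 (length(ix) < best_size ||
                    (length(ix) == best_size &&
                       paste(ids[ix], collapse = ",") < best_key)))))
      if (better) {
        best_mask <- mask; best_obj <- obj
        best_prize <- sub_prize[mask]; best_size <- length(ix)
        best_key <- paste(ids[ix], collapse = ",")
      }
    }
    if (best_mask == 0L) {
      return(module_result(graph, integer(0), NULL, lam, "exact"))
    }
    module_result(graph, bit_lists[[best_mask]], mst_edges[[best_mask]],
                  lam, "exact")
  }

  if (length(lambda) == 1L) solve_one(lambda) else lapply(lambda, solve_one)
}

# Exact PCST on a forest by dynamic programming over rooted subtrees:
# best[v] = -lambda*b[v] + sum over children c of min(0, cost(v,c) + best[c]).
# The optimum over connected subgraphs equals min over topmost nodes v.
pcst_tree_dp <- function(graph, lambda) {
  ids <- graph$nodes$id
  n <- length(ids)
  prizes <- setNames(graph$nodes$prize, ids)
  adj <- vector("list", n); names(adj) <- ids
  for (r in seq_len(nrow(graph$edges))) {
    f <- graph$edges$from[r]; t <- graph$edges$to[r]; cst <- graph$edges$cost[r]
    adj[[f]] <- rbind(adj[[f]], data.frame(v = t, cost = cst))
    adj[[t]] <- rbind(adj[[t]], data.frame(v = f, cost = cst))
  }
  best <- setNames(rep(NA_real_, n), ids)
  keep_children <- setNames(vector("list", n), ids)
  visited <- setNames(rep(FALSE, n), ids)
  # iterative post-order DFS per component
  for (root in ids) {
    if (visited[root]) next
    stack <- list(list(v = root, parent = NA_character_, stage = 1L))
    order_out <- character(0)
    parent_of <- setNames(NA_character_, root)
    while (length(stack) > 0) {
      fr <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      v <- fr$v
      if (visited[v]) next
      visited[v] <- TRUE
      order_out <- c(v, order_out)  # children processed before parent later
      nb <- adj[[v]]
      if (!is.null(nb)) for (i in seq_len(nrow(nb))) {
        w <- nb$v[i]
        if (!visited[w] && (is.na(fr$parent) || w != fr$parent)) {
          parent_of[w] <- v
          stack[[length(stack) + 1]] <- list(v = w, parent = v, stage = 1L)
        }
      }
    }
    # order_out currently has parents before children reversed; process
    # children-first by iterating in the order nodes were *finished*
    for (v in order_out) {
      val <- -lambda * prizes[v]
      kept <- character(0)
      nb <- adj[[v]]
      if (!is.null(nb)) for (i in seq_len(nrow(nb))) {
        w <- nb$v[i]
        if (!is.na(parent_of[w]) && parent_of[w] == v && !is.na(best[w])) {
          contrib <- nb$cost[i] + best[w]
          if (contrib < -1e-12) {
            val <- val + contrib
            kept <- c(kept, w)
          }
        }
      }
      best[v] <- val
      keep_children[[v]] <- kept
    }
  }
  v_star <- names(best)[which.min(best)]
  if (best[v_star] >= -1e-12) {
    # empty vs best single structure: prefer the non-empty optimum when tied
    if (best[v_star] > 1e-12) return(module_result(graph, integer(0), NULL, lambda, "tree_dp"))
  }
  sel <- character(0); frontier <- v_star
  edges_sel <- list()
  while (length(frontier) > 0) {
    v <- frontier[1]; frontier <- frontier[-1]
    sel <- c(sel, v)
    for (w in keep_children[[v]]) {
      edges_sel[[length(edges_sel) + 1]] <- c(v, w)
      frontier <- c(frontier, w)
    }
  }
  node_idx <- match(sort(sel), ids)
  tree_idx <- if (length(edges_sel) == 0) NULL else {
    m <- do.call(rbind, edges_sel)
    cbind(match(m[, 1], ids[node_idx]), match(m[, 2], ids[node_idx]))
  }
  module_result(graph, node_idx, tree_idx, lambda, "tree_dp")
}

#' Heuristic prize-collecting Steiner tree solver
#'
#' Deterministic growth-and-prune search: on forests it solves the problem
#' exactly by dynamic programming over rooted subtrees; on general graphs it
#' grows a tree greedily from every root (single-node and two-step additions
#' with positive marginal gain `lambda * prize - cost`), replaces the tree
#' by the minimum spanning tree of the selected nodes, prunes leaves with
#' negative contribution until stable, and keeps the best objective found.
#' The result is never worse than the best singleton.
#'
#' @param graph A [prize_graph()].
#' @param lambda Prize weight in the objective.
#' @param seed Unused (the search is deterministic); kept for interface
#'   stability.
#' @return A `tromics_module`.
#' @export
pcst_heuristic <- function(graph, lambda, seed = 1L) {
  stopifnot(inherits(graph, "tromics_prize_graph"))
  assert_number(lambda, "lambda", lower = 0)
  ids <- graph$nodes$id
  n <- length(ids)
  if (n == 0L) return(module_result(graph, integer(0), NULL, lambda, "heuristic"))

  n_comp <- n_components(graph)
  if (nrow(graph$edges) == n - n_comp) {          # forest: exact DP
    return(pcst_tree_dp(graph, lambda))
  }

  C <- cost_matrix(graph)
  prizes <- graph$nodes$prize
  finiteC <- is.finite(C) & C > 0

  eval_tree <- function(sel) {
    # MST + iterated leaf pruning on the selected index set
    repeat {
      mst <- prim_mst(C, sel)
      if (is.null(mst)) return(NULL)
      if (length(sel) == 1L) break
      deg <- tabulate(c(mst$edges), nbins = length(sel))
      leaf_cost <- rep(NA_real_, length(sel))
      for (r in seq_len(nrow(mst$edges))) {
        a <- mst$edges[r, 1]; b <- mst$edges[r, 2]
        if (deg[a] == 1L) leaf_cost[a] <- C[sel[a], sel[b]]
        if (deg[b] == 1L) leaf_cost[b] <- C[sel[a], sel[b]]
      }
      bad <- which(deg == 1L & leaf_cost > lambda * prizes[sel] + 1e-12)
      if (length(bad) == 0L) break
      worst <- bad[which.max(leaf_cost[bad] - lambda * prizes[sel[bad]])]
      sel <- sel[-worst]
    }
    mst <- prim_mst(C, sel)
    list(sel = sel, mst = mst,
         obj = mst$cost - lambda * sum(prizes[sel]))
  }

  roots <- order(-prizes, ids)
  if (n > 200L) roots <- roots[1:200]
  best <- list(obj = 0, sel = integer(0), mst = NULL)
  for (r in roots) {
    sel <- r
    in_sel <- rep(FALSE, n); in_sel[r] <- TRUE
    min_link <- C[r, ]                            # cheapest edge into tree
    repeat {
      out <- which(!in_sel & is.finite(min_link))
      if (length(out) == 0L) break
      gain1 <- lambda * prizes[out] - min_link[out]
      # two-step: bring in w (adjacent to tree) plus u adjacent to w
      best2 <- -Inf; pair2 <- NULL
      for (w in out) {
        nb <- which(finiteC[w, ] & !in_sel)
        nb <- nb[nb != w]
        if (length(nb) == 0) next
        g2 <- lambda * (prizes[w] + prizes[nb]) - (min_link[w] + C[w, nb])
        if (max(g2) > best2) {
          best2 <- max(g2)
          pair2 <- c(w, nb[which.max(g2)])
        }
      }
      g1max <- max(gain1)
      if (g1max < 1e-12 && best2 < 1e-12) break
      if (g1max >= best2) {
        v <- out[which.max(gain1)]
        add <- v
      } else {
        add <- pair2
      }
      for (v in add) {
        in_sel[v] <- TRUE
        sel <- c(sel, v)
        min_link <- pmin(min_link, C[v, ])
      }
    }
    cand <- eval_tree(sort(sel))
    if (!is.null(cand) && cand$obj < best$obj - 1e-12) {
      best <- cand
    }
  }
  if (length(best$sel) == 0L) {
    # fall back to the best singleton (objective -lambda * max prize <= 0)
    top <- which.max(prizes)
    if (lambda * prizes[top] > 0) {
      return(module_result(graph, top, NULL, lambda, "heuristic"))
    }
    return(module_result(graph, integer(0), NULL, lambda, "heuristic"))
  }
  module_result(graph, best$sel, best$mst$edges, lambda, "heuristic")
}

n_components <- function(graph) {
  g <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = graph$nodes$id)
  igraph::count_components(g)
}

#' Solve the PCST with automatic solver choice
#'
#' @param graph A [prize_graph()].
#' @param lambda Prize weight.
#' @param exact_limit Largest node count for the exhaustive solver.
#' @param seed Passed to the heuristic.
#' @return A `tromics_module`.
#' @export
pcst_solve <- function(graph, lambda, exact_limit = 15L, seed = 1L) {
  if (nrow(graph$nodes) <= exact_limit) {
    pcst_exact(graph, lambda)
  } else {
    pcst_heuristic(graph, lambda, seed = seed)
  }
}

#' Calibrate the prize weight lambda
#'
#' Simulates interactomes matched to a template network's size and density
#' with a planted, connected set of essential nodes, solves the PCST over
#' an ascending lambda sweep, and returns the smallest lambda at which the
#' essential-node recovery reaches `recovery_target` in **every** simulated
#' network (a conservative reading: the calibrated weight must meet the
#' target in each replicate, not merely on average; the sweep table reports
#' both the mean and the minimum recovery). If the target is never reached
#' the sweep maximum is returned with a warning.
#'
#' The template is either a [prize_graph()] -- in which case the simulated
#' networks resample its empirical edge-cost and node-prize distributions,
#' so the calibration reflects the prize/cost regime the solver will
#' actually face -- or explicit `n_nodes` and `density` values. Without
#' observed pools, essential nodes get prizes `-ln p` with
#' `p ~ 10^-U(2, 6)`, background nodes `p ~ U(0, 1)`, and costs are
#' `1 - R` with reliabilities as in [generate_interactome()]. Essential
#' nodes stand in for the scored disease-module genes; with an observed
#' prize pool every simulated node resamples from it and the essential set
#' is distinguished by its planted connectivity.
#'
#' @param template Optional [prize_graph()] whose statistics define the
#'   simulation (size, density, cost and prize pools).
#' @param n_nodes,density Template size and edge density (ignored when
#'   `template` is given).
#' @param essential_fraction Fraction of nodes planted as essential.
#' @param recovery_target Required mean recovery (default 0.70).
#' @param lambdas Ascending sweep (default `seq(0.01, 1, by = 0.01)`).
#' @param n_sim Simulated networks per sweep (default 10).
#' @param seed Integer seed.
#' @param exact_limit Node-count limit for the exhaustive solver.
#' @return List of class `tromics_calibration`: `lambda_star`, `sweep`
#'   (tibble `lambda`, `mean_recovery`, `min_recovery`), `reached` flag and
#'   the parameters.
#' @export
calibrate_lambda <- function(template = NULL, n_nodes = NULL, density = NULL,
                             essential_fraction = 0.25,
                             recovery_target = 0.70,
                             lambdas = seq(0.01, 1, by = 0.01),
                             n_sim = 10, seed = 1L, exact_limit = 15L) {
  cost_pool <- NULL
  prize_pool <- NULL
  if (!is.null(template)) {
    stopifnot(inherits(template, "tromics_prize_graph"))
    n_nodes <- nrow(template$nodes)
    density <- if (n_nodes >= 2) {
      max(min(nrow(template$edges) / choose(n_nodes, 2), 0.9), 1e-4)
    } else 0.1
    if (nrow(template$edges) > 0) cost_pool <- template$edges$cost
    if (any(template$nodes$prize > 0)) {
      prize_pool <- template$nodes$prize[template$nodes$prize > 0]
    }
  }
  n_nodes <- assert_count(n_nodes, "n_nodes", lower = 2L)
  assert_number(density, "density", 0, 1, strict_lower = TRUE, strict_upper = TRUE)
  assert_number(essential_fraction, "essential_fraction", 0, 1, strict_lower = TRUE)
  if (length(lambdas) == 0L) abort("`lambdas` must be non-empty.")
  lambdas <- sort(lambdas)
  n_sim <- assert_count(n_sim, "n_sim")
  seed <- assert_seed(seed)

  n_ess <- max(1L, ceiling(essential_fraction * n_nodes))
  recov <- matrix(0, n_sim, length(lambdas))
  for (s in seq_len(n_sim)) {
    ids <- sprintf("n%03d", seq_len(n_nodes))
    essential <- ids[seq_len(n_ess)]
    net <- generate_interactome(ids, density, module_nodes = essential,
                                seed = seed + 1000L + s)
    set.seed(seed + 2000L + s)
    prizes <- if (!is.null(prize_pool)) {
      sample(prize_pool, n_nodes, replace = TRUE)
    } else {
      p <- runif(n_nodes)
      p[seq_len(n_ess)] <- 10^(-runif(n_ess, 2, 6))
      node_prize(p)
    }
    costs <- if (!is.null(cost_pool)) {
      sample(cost_pool, nrow(net), replace = TRUE)
    } else {
      pmax(1 - net$reliability, 1e-6)
    }
    g <- prize_graph(
      nodes = tibble(id = ids, prize = prizes),
      edges = tibble(from = net$from, to = net$to, cost = costs)
    )
    if (n_nodes <= exact_limit) {
      mods <- pcst_exact(g, lambdas)
      recov[s, ] <- vapply(mods, function(m) {
        length(intersect(m$nodes$id, essential)) / n_ess
      }, numeric(1))
    } else {
      for (li in seq_along(lambdas)) {
        m <- pcst_heuristic(g, lambdas[li])
        recov[s, li] <- length(intersect(m$nodes$id, essential)) / n_ess
      }
    }
  }
  mean_rec <- colMeans(recov)
  min_rec <- apply(recov, 2, min)
  hit <- which(min_rec >= recovery_target)
  reached <- length(hit) > 0
  if (!reached) {
    warn(sprintf("recovery target %.2f not reached over the sweep; returning lambda = %.2f.",
                 recovery_target, max(lambdas)))
  }
  lambda_star <- if (reached) lambdas[hit[1]] else max(lambdas)
  structure(
    list(lambda_star = lambda_star,
         sweep = tibble(lambda = lambdas, mean_recovery = mean_rec,
                        min_recovery = min_rec),
         reached = reached,
         params = list(n_nodes = n_nodes, density = density,
                       essential_fraction = essential_fraction,
                       recovery_target = recovery_target, n_sim = n_sim,
                       seed = seed)),
    class = "tromics_calibration"
  )
}

#' @export
print.tromics_calibration <- function(x, ...) {
  cat(sprintf(
    "<tromics_calibration> lambda* = %.2f (target %.2f %s; %d sims, n = %d, density = %.3g)\n",
    x$lambda_star, x$params$recovery_target,
    if (x$reached) "reached" else "NOT reached",
    x$params$n_sim, x$params$n_nodes, x$params$density
  ))
  invisible(x)
}

#' Build the prize graph and find the disease module
#'
#' Restricts the interactome to the candidate genes (plus optional
#' zero-prize linker nodes one hop away), assigns node prizes
#' `-ln p_inte`, edge costs from the interaction reliability combined with
#' the expression correlation channel, and solves the PCST (exact solver up
#' to `exact_limit` nodes, heuristic beyond).
#'
#' @param candidates Character vector of candidate genes.
#' @param interactome Tibble `from`, `to`, `reliability`.
#' @param expression Gene expression [omics_matrix()] (correlation channel);
#'   `NULL` disables the correlation evidence.
#' @param integration Gene-level `tromics_integration` table (prizes and
#'   annotations).
#' @param lambda Prize weight (a number, or a `tromics_calibration`).
#' @param allow_linkers Include zero-prize connector nodes one hop from the
#'   candidates.
#' @param methylation Optional methylation [omics_matrix()] used only to
#'   annotate module genes with their expression-methylation correlation.
#' @param exact_limit Node-count limit for the exhaustive solver.
#' @param p_floor Floor for integration p-values before the prize log.
#' @param seed Passed to the heuristic.
#' @return A `tromics_module` whose `nodes` carry `p_inte`, `q_inte`,
#'   `candidate` and (if methylation is given) `methyl_corr`.
#' @export
find_module <- function(candidates, interactome, expression, integration,
                        lambda, allow_linkers = FALSE, methylation = NULL,
                        exact_limit = 15L, p_floor = 1e-16, seed = 1L) {
  if (inherits(lambda, "tromics_calibration")) lambda <- lambda$lambda_star
  assert_number(lambda, "lambda", lower = 0)
  g <- build_prize_graph(candidates, interactome, expression, integration,
                         allow_linkers = allow_linkers,
                         methylation = methylation, p_floor = p_floor)
  pcst_solve(g, lambda, exact_limit = exact_limit, seed = seed)
}

#' Assemble the prize graph for module discovery
#'
#' The graph-building half of [find_module()]: restricts the interactome to
#' the candidates (plus optional linkers), computes prizes and evidence-
#' combined edge costs, and returns the [prize_graph()] so that callers can
#' inspect it or use it as a calibration template.
#'
#' @inheritParams find_module
#' @return A `tromics_prize_graph` with annotated nodes.
#' @export
build_prize_graph <- function(candidates, interactome, expression, integration,
                              allow_linkers = FALSE, methylation = NULL,
                              p_floor = 1e-16) {
  net_nodes <- union(interactome$from, interactome$to)
  dropped <- setdiff(candidates, net_nodes)
  if (length(dropped) > 0) {
    inform(sprintf("%d candidate(s) absent from the interactome were dropped.",
                   length(dropped)))
  }
  cand <- intersect(candidates, net_nodes)
  if (length(cand) == 0L) abort("no candidate gene is present in the interactome.")

  keep_nodes <- cand
  if (allow_linkers) {
    touch <- interactome$from %in% cand | interactome$to %in% cand
    keep_nodes <- union(cand, union(interactome$from[touch], interactome$to[touch]))
  }
  sub <- interactome[interactome$from %in% keep_nodes &
                       interactome$to %in% keep_nodes, , drop = FALSE]

  p_map <- setNames(integration$p_inte, integration$feature)
  q_map <- setNames(integration$q_inte, integration$feature)
  prizes <- rep(0, length(keep_nodes))
  names(prizes) <- keep_nodes
  scored <- intersect(keep_nodes, names(p_map))
  prizes[intersect(scored, cand)] <- node_prize(p_map[intersect(scored, cand)],
                                                p_floor = p_floor)

  use_corr <- !is.null(expression)
  if (use_corr) {
    expr_ok <- sub$from %in% rownames(expression$values) &
      sub$to %in% rownames(expression$values)
    corr <- rep(0, nrow(sub))
    if (any(expr_ok)) {
      corr[expr_ok] <- vapply(which(expr_ok), function(r) {
        cor(expression$values[sub$from[r], ], expression$values[sub$to[r], ])
      }, numeric(1))
    }
    ev <- combine_edge_evidence(sub$reliability, corr, use_corr = TRUE)
    # rows without expression fall back to the single channel
    ev$cost[!expr_ok] <- combine_edge_evidence(sub$reliability[!expr_ok],
                                               use_corr = FALSE)$cost
  } else {
    ev <- combine_edge_evidence(sub$reliability, use_corr = FALSE)
  }

  nodes <- tibble(
    id = keep_nodes,
    prize = unname(prizes),
    candidate = keep_nodes %in% cand,
    p_inte = unname(p_map[keep_nodes]),
    q_inte = unname(q_map[keep_nodes])
  )
  if (!is.null(methylation)) {
    nodes$methyl_corr <- vapply(nodes$id, function(g) {
      if (g %in% rownames(expression$values) &&
          g %in% rownames(methylation$values)) {
        cor(expression$values[g, ], methylation$values[g, ])
      } else NA_real_
    }, numeric(1))
  }
  prize_graph(nodes,
              tibble(from = sub$from, to = sub$to,
                     cost = pmax(ev$cost, 1e-6)))
}
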