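# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an integration result
#'
#' Combined score against -log10 integrated p, significant features
#' highlighted.
#'
#' @param object A `tromics_integration` table.
#' @param q_thresh Highlight threshold on `q_inte` (default 0.05).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tromics_integration <- function(object, q_thresh = 0.05, ...) {
  df <- tidy(object)
  df$significant <- df$q_inte <= q_thresh
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_meta,
                                   y = -log10(.data$p_inte),
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick"),
                                 name = paste0("q <= ", q_thresh)) +
    ggplot2::labs(x = "combined score (sum of |Z|)",
                  y = expression(-log[10] ~ p[inte]),
                  title = "Multi-omics integration") +
    ggplot2::theme_minimal()
}

#' Plot pathway impact evidence
#'
#' Two-way evidence plot: -log10 over-representation p against -log10
#' perturbation p, sized by global significance.
#'
#' @param object A `tromics_pathway_impact` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tromics_pathway_impact <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p_nde),
                                   y = -log10(.data$p_pert),
                                   colour = .data$significant)) +
    ggplot2::geom_point(ggplot2::aes(size = -log10(.data$p_g)), alpha = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = .data$pathway), vjust = -0.8,
                       size = 2.8, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = expression(-log[10] ~ P[NDE]),
                  y = expression(-log[10] ~ P[PERT]),
                  size = expression(-log[10] ~ P[G]),
                  title = "Pathway impact evidence") +
    ggplot2::theme_minimal()
}

# Deterministic force-directed layout for a small graph.
layout_tbl <- function(g, seed = 1L) {
  set.seed(seed)
  xy <- igraph::layout_with_fr(g)
  tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2])
}

#' Plot a Steiner module
#'
#' Module tree with node size proportional to prize.
#'
#' @param object A `tromics_module`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tromics_module <- function(object, seed = 1L, ...) {
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::labs(title = "Empty module") +
             ggplot2::theme_void())
  }
  g <- igraph::graph_from_data_frame(object$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = object$nodes$id)
  lay <- layout_tbl(g, seed)
  ed <- object$edges |>
    left_join(lay, by = c(from = "name")) |>
    left_join(lay, by = c(to = "name"), suffix = c("", "end"))
  nd <- left_join(tibble(name = object$nodes$id, prize = object$nodes$prize),
                  lay, by = "name")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey60") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$prize),
                        colour = "steelblue") +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$name),
                       vjust = -1.1, size = 3) +
    ggplot2::labs(title = sprintf("Disease module (lambda = %.3g, objective = %.3f)",
                                  object$lambda, object$objective),
                  size = "prize (-ln p)") +
    ggplot2::theme_void()
}

#' Plot the lambda calibration sweep
#'
#' @param object A `tromics_calibration`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tromics_calibration <- function(object, ...) {
  ggplot2::ggplot(object$sweep,
                  ggplot2::aes(x = .data$lambda, y = .data$mean_recovery)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$params$recovery_target,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$lambda_star,
                        linetype = "dotted", colour = "steelblue") +
    ggplot2::labs(x = expression(lambda), y = "mean essential-node recovery",
                  title = sprintf("lambda calibration (lambda* = %.2f)",
                                  object$lambda_star)) +
    ggplot2::theme_minimal()
}

#' Plot the combined miRNA-mRNA network
#'
#' Genes as squares, miRNAs as circles; module edges solid, miRNA edges
#' dashed.
#'
#' @param network An igraph from [build_bipartite()].
#' @param seed Layout seed.
#' @return A ggplot.
#' @export
plot_mirna_network <- function(network, seed = 1L) {
  lay <- layout_tbl(network, seed)
  ed <- igraph::as_data_frame(network, what = "edges") |>
    left_join(lay, by = c(from = "name")) |>
    left_join(lay, by = c(to = "name"), suffix = c("", "end"))
  nd <- igraph::as_data_frame(network, what = "vertices") |>
    left_join(lay, by = "name")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend,
                                       linetype = .data$kind),
                          colour = "grey55") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     shape = .data$type,
                                     colour = .data$pattern),
                        size = 3) +
    ggplot2::geom_text(data = nd,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$name),
                       vjust = -1.1, size = 2.8) +
    ggplot2::scale_shape_manual(values = c(gene = 15, mirna = 16)) +
    ggplot2::labs(title = "miRNA-mRNA regulatory network") +
    ggplot2::theme_void()
}
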