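# broom-style accessors for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @describeIn integrate_omics `tidy()` returns the integration table as a
#'   plain tibble.
#' @param x A `tromics_integration` object.
#' @param ... Unused.
#' @export
tidy.tromics_integration <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "tromics_integration")
  out
}

#' @describeIn integrate_omics `glance()` summarises one integration run.
#' @export
glance.tromics_integration <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_layers = length(attr(x, "layers")),
    method = attr(x, "method") %||% NA_character_,
    n_sig_q05 = sum(x$q_inte <= 0.05),
    min_p_inte = if (nrow(x) > 0) min(x$p_inte) else NA_real_
  )
}

#' @describeIn run_pathway_impact `tidy()` returns the pathway table as a
#'   plain tibble.
#' @param x A `tromics_pathway_impact` object.
#' @param ... Unused.
#' @export
tidy.tromics_pathway_impact <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "tromics_pathway_impact")
  out
}

#' @describeIn run_pathway_impact `glance()` summarises the pathway run.
#' @export
glance.tromics_pathway_impact <- function(x, ...) {
  tibble(
    n_pathways = nrow(x),
    n_significant = sum(x$significant),
    min_p_g = min(x$p_g),
    n_inversion_failed = sum(x$status == "inversion_failed")
  )
}

#' Tidy a Steiner module into its node table
#' @param x A `tromics_module`.
#' @param ... Unused.
#' @return Tibble of module nodes with prizes and annotations.
#' @export
tidy.tromics_module <- function(x, ...) as_tibble(x$nodes)

#' One-row summary of a Steiner module
#' @param x A `tromics_module`.
#' @param ... Unused.
#' @export
glance.tromics_module <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
    objective = x$objective, collected_prize = x$collected_prize,
    total_cost = sum(x$edges$cost), lambda = x$lambda, solver = x$solver
  )
}

#' Tidy a lambda calibration into its sweep table
#' @param x A `tromics_calibration`.
#' @param ... Unused.
#' @export
tidy.tromics_calibration <- function(x, ...) x$sweep

#' One-row summary of a lambda calibration
#' @param x A `tromics_calibration`.
#' @param ... Unused.
#' @export
glance.tromics_calibration <- function(x, ...) {
  tibble(
    lambda_star = x$lambda_star, reached = x$reached,
    recovery_at_star = x$sweep$mean_recovery[match(x$lambda_star, x$sweep$lambda)],
    recovery_target = x$params$recovery_target,
    n_sim = x$params$n_sim
  )
}

#' Tidy a results bundle into its per-gene pattern table
#' @param x A `tromics_results`.
#' @param ... Unused.
#' @export
tidy.tromics_results <- function(x, ...) as_tibble(x$patterns)

#' One-row summary of a pipeline run
#' @param x A `tromics_results`.
#' @param ... Unused.
#' @export
glance.tromics_results <- function(x, ...) {
  tibble(
    n_genes = x$manifest$n_genes,
    n_sig_genes = sum(x$integration_genes$q_inte <= 0.05),
    n_candidates = x$manifest$n_candidates,
    module_size = x$manifest$module_size,
    lambda = x$manifest$lambda,
    n_mirna_pairs = nrow(x$mirna_pairs),
    n_target_supported = sum(x$mirna_pairs$target_supported)
  )
}
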