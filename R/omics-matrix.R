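#' Construct a single-layer omics matrix
#'
#' Container for one omics layer in a two-group design: a feature-by-sample
#' numeric matrix of normalized, unitless intensities plus a binary phenotype
#' label per sample (e.g. `"high"` / `"low"` bone mineral density).
#'
#' @param values Numeric matrix, features in rows (unique rownames required),
#'   samples in columns (colnames required).
#' @param groups Character or factor of per-sample group labels, length
#'   `ncol(values)`, with exactly two distinct values and both groups
#'   non-empty. May be named by sample; names must then match `colnames(values)`.
#' @param high Label identifying the "high" phenotype arm; score signs are
#'   reported as high minus low.
#'
#' @return An object of class `omics_matrix`: a list with elements `values`,
#'   `groups` (factor with the high arm as first level) and `high`.
#' @examples
#' m <- matrix(rnorm(20), 4, 5, dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' om <- omics_matrix(m, c("high", "high", "low", "low", "low"))
#' @export
omics_matrix <- function(values, groups, high = "high") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix (features x samples).")
  }
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    abort("`values` must have unique rownames (feature IDs).")
  }
  if (is.null(colnames(values)) || anyDuplicated(colnames(values))) {
    abort("`values` must have unique colnames (sample IDs).")
  }
  groups <- setNames(as.character(groups), names(groups))
  if (length(groups) != ncol(values)) {
    abort("`groups` must have one label per sample (column).")
  }
  if (anyNA(groups)) abort("`groups` must not contain missing labels.")
  if (!is.null(names(groups))) {
    if (!setequal(names(groups), colnames(values))) {
      abort("names of `groups` must match the sample IDs of `values`.")
    }
    groups <- groups[colnames(values)]
  }
  lev <- unique(groups)
  if (length(lev) != 2L) abort("`groups` must contain exactly two distinct labels.")
  if (!high %in% lev) {
    abort(sprintf("`high` label '%s' not found among group labels (%s).",
                  high, paste(lev, collapse = ", ")))
  }
  if (min(table(groups)) < 1L) abort("both groups must be non-empty.")
  structure(
    list(
      values = values,
      groups = factor(groups, levels = c(high, setdiff(lev, high))),
      high = high
    ),
    class = "omics_matrix"
  )
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf(
    "<omics_matrix> %d features x %d samples (%s: %d, %s: %d)\n",
    nrow(x$values), ncol(x$values),
    levels(x$groups)[1], sum(x$groups == levels(x$groups)[1]),
    levels(x$groups)[2], sum(x$groups == levels(x$groups)[2])
  ))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Coerce an omics matrix to a long tibble
#'
#' @param x An [omics_matrix()].
#' @param ... Unused.
#' @return Tibble with columns `feature`, `sample`, `group`, `value`.
#' @export
as_tibble.omics_matrix <- function(x, ...) {
  tibble::tibble(
    feature = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    group = rep(as.character(x$groups), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

# 0/1 indicator of membership in the high arm, in column order.
high_indicator <- function(om) as.integer(om$groups == levels(om$groups)[1])
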