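# Internal helpers: argument checking and seed fan-out.

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lower) {
    abort(sprintf("`%s` must be an integer >= %d.", name, lower))
  }
  as.integer(x)
}

assert_seed <- function(x, name = "seed") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer.", name))
  }
  as.integer(x)
}

# Deterministic per-stage seed derivation from one global seed.  Stage
# offsets are fixed small integers so a stage re-run in isolation with the
# same global seed reproduces the pipeline's stream (kept below 2^31).
stage_seed <- function(seed, stage) {
  offsets <- c(
    dataset = 0L, expression = 11L, methylation = 12L, mirna = 13L,
    interactome = 21L, pathways = 22L, targets = 23L,
    integration = 31L, pathway_impact = 41L, module = 51L,
    calibration = 52L, mirna_net = 61L
  )
  if (!stage %in% names(offsets)) abort(paste0("unknown stage: ", stage))
  (as.integer(seed) %% 2000000000L) + offsets[[stage]]
}

`%||%` <- rlang::`%||%`
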