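#' Derive a reproducible sub-stream seed
#'
#' A single master seed drives a named random sub-stream per operation, so
#' that adding or reordering one stage of an analysis never perturbs the
#' draws of another. The derived seed is a deterministic hash of the master
#' seed and the stream name, kept inside the 32-bit integer range.
#'
#' @param seed integer master seed.
#' @param stream character stream name (e.g. `"cohort"`, `"consensus-run-3"`).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L)
  codes <- utf8ToInt(stream)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds halves to even; printed cohort tables use the
#' convention that halves round away from zero (e.g. 6.25 -> 6.3).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @keywords internal
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Permutation p-value with the add-one convention
#'
#' `p = (1 + #(null >= observed)) / (1 + pool size)`, the standard estimator
#' that can never return exactly zero.
#'
#' @param observed numeric vector of observed (absolute) statistics.
#' @param null_pool numeric vector, the pooled null statistics.
#' @return p-values in `[1/(1 + pool size), 1]`.
#' @export
permutation_pvalue <- function(observed, null_pool) {
  stopifnot(length(null_pool) > 0)
  s <- sort(null_pool)
  n_lt <- findInterval(observed, s, left.open = TRUE)
  (1 + length(s) - n_lt) / (1 + length(s))
}

# internal: stop() with a stage prefix, used by the pipeline
stage_stop <- function(stage, msg) {
  stop(sprintf("[stage %s] %s", stage, msg), call. = FALSE)
}
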