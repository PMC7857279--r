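#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a root seed
#'
#' All stochastic operations in the package draw their seed from a single root
#' seed through this function, so a pipeline run is reproducible end to end
#' while its stages remain decoupled.
#'
#' @param seed integer root seed.
#' @param offset integer stream offset (one per operation).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, offset = 0L) {
  s <- (as.numeric(seed) * 69069 + as.numeric(offset) * 362437) %% (2^31 - 1)
  as.integer(s)
}

is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & abs(x - round(x)) < 1e-8
}

#' Percentile confidence interval of bootstrap draws
#' @param draws numeric vector of bootstrap replicates (NAs dropped).
#' @param level confidence level in (0, 1).
#' @return length-2 numeric vector (lower, upper).
#' @export
percentile_ci <- function(draws, level = 0.95) {
  draws <- draws[is.finite(draws)]
  if (!length(draws)) return(c(NA_real_, NA_real_))
  a <- (1 - level) / 2
  unname(stats::quantile(draws, c(a, 1 - a), names = FALSE))
}
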