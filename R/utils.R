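#' Clip probabilities away from 0 and 1
#'
#' Keeps Bernoulli log-likelihoods finite when hazards saturate.
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping margin.
#' @return `p` clipped to `[eps, 1 - eps]`.
#' @export
clip_unit <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

#' @keywords internal
softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' @keywords internal
inv_softplus <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

#' Derive a reproducible per-unit substream seed
#'
#' Trials (and replicates) are generated from counter-based substreams of a
#' master seed so that unit `i` is identical regardless of how many units are
#' generated in one call. The mixing constants are fixed multipliers modulo
#' 2^31 - 1, keeping results valid 32-bit R integers.
#'
#' @param master master seed (integer).
#' @param i substream counter (integer >= 1).
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(master, i) {
  m <- 2147483647
  s <- (as.numeric(master) %% m) * 48271 %% m
  as.integer((s + as.numeric(i) * 9973 + 12345) %% m)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
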