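#' Configuration of the synthetic fluorescence generator
#'
#' Test-bed emulating frame-rate calcium traces driven by baseline stimulus
#' fluctuations: the stimulus (resampled to the frame grid) is convolved
#' with a stimulus kernel, movement with a movement kernel, the sum is
#' convolved with an exponential indicator kernel and Gaussian noise is
#' added. In two-channel mode both channels are multiplied by a shared
#' (hemodynamic-like) artifact trace, with the signal present in channel 1
#' only.
#'
#' @param stim_kernel response weights per frame lag (z-units per octave).
#' @param movement_kernel weights per frame lag for the movement trace.
#' @param indicator_decay indicator decay time constant, s (> 0).
#' @param noise_sd additive Gaussian noise SD, z-units.
#' @param frame_rate imaging frame rate, Hz.
#' @return a `vc_fluor_config` list.
#' @export
fluor_config <- function(stim_kernel = c(0, 0.5, 1, 0.7, 0.4, 0.2),
                         movement_kernel = numeric(0),
                         indicator_decay = 0.4,
                         noise_sd = 0.1,
                         frame_rate = 25) {
  stopifnot(indicator_decay > 0, noise_sd >= 0, frame_rate > 0)
  structure(as.list(environment()), class = "vc_fluor_config")
}

# causal convolution of x with kernel k (k[1] = lag 0)
#' @keywords internal
conv_causal <- function(x, k) {
  if (!length(k)) return(rep(0, length(x)))
  out <- stats::filter(c(rep(0, length(k) - 1), x), k,
                       method = "convolution", sides = 1)
  as.numeric(out[length(k) - 1 + seq_along(x)])
}

#' Generate synthetic fluorescence traces
#'
#' @param log2tf stimulus trace on the stimulus grid (octaves per 50 ms), or
#'   a `vc_stimulus`.
#' @param cfg a [fluor_config()].
#' @param task_cfg a [task_config()] (stimulus sample period).
#' @param movement optional movement trace on the frame grid.
#' @param seed optional integer seed.
#' @param channels 1 for a corrected trace; 2 for raw two-channel output.
#' @param artifact optional multiplicative artifact trace on the frame grid
#'   (two-channel mode); defaults to 1.
#' @return list with `frame_times` (s), `stim` (frame-resampled log2 TF),
#'   and either `trace` (1 channel) or `f470`/`f405` (2 channels).
#' @export
gen_synthetic_fluorescence <- function(log2tf, cfg = fluor_config(),
                                       task_cfg = task_config(),
                                       movement = NULL, seed = NULL,
                                       channels = 1, artifact = NULL) {
  if (inherits(log2tf, "vc_stimulus")) log2tf <- log2tf$log2tf
  if (!is.null(seed)) set.seed(seed)
  dt_s <- task_cfg$sample_period
  dt_f <- 1 / cfg$frame_rate
  total <- length(log2tf) * dt_s
  frame_starts <- seq(0, total - dt_f, by = dt_f)
  frames <- data.frame(start = frame_starts, end = frame_starts + dt_f)
  mon <- data.frame(onset = (seq_along(log2tf) - 1) * dt_s,
                    duration = dt_s, log2tf = log2tf)
  s_frame <- resample_stimulus(mon, frames)$value
  n <- length(s_frame)
  if (is.null(movement)) movement <- rep(0, n)
  stopifnot(length(movement) == n)
  drive <- conv_causal(s_frame, cfg$stim_kernel) +
    conv_causal(movement, cfg$movement_kernel)
  ind <- exp(-(0:ceiling(5 * cfg$indicator_decay / dt_f)) * dt_f /
               cfg$indicator_decay)
  ind <- ind / sum(ind)
  signal_tr <- conv_causal(drive, ind)
  if (channels == 1) {
    trace <- signal_tr + stats::rnorm(n, 0, cfg$noise_sd)
    return(list(frame_times = frame_starts, stim = s_frame, trace = trace))
  }
  if (is.null(artifact)) artifact <- rep(1, n)
  stopifnot(length(artifact) == n)
  f470 <- (1 + signal_tr + stats::rnorm(n, 0, cfg$noise_sd)) * artifact
  f405 <- (1 + stats::rnorm(n, 0, cfg$noise_sd)) * artifact
  list(frame_times = frame_starts, stim = s_frame, f470 = f470, f405 = f405)
}
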