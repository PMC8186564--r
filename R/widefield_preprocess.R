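# Widefield trace conditioning: channel-ratio hemodynamic correction,
# low-cut filtering/normalization, stimulus resampling to the frame grid,
# event alignment and threshold latencies.

#' Construct a frame series
#'
#' @param trace numeric vector (one ROI/pixel) of fluorescence values.
#' @param times strictly increasing frame times, s.
#' @return a `vc_frames` list.
#' @export
frame_series <- function(trace, times) {
  stopifnot(length(trace) == length(times), !is.unsorted(times, strictly = TRUE))
  structure(list(trace = as.numeric(trace), times = as.numeric(times)),
            class = "vc_frames")
}

#' Channel-ratio hemodynamic correction
#'
#' The calcium-insensitive 405-nm channel is linearly interpolated to the
#' 470-nm frame times (the average of the 405-nm frames immediately before
#' and after each 470-nm frame) and the 470/405 ratio is normalized by its
#' session mean. A fluctuation common multiplicatively to both channels is
#' removed exactly.
#'
#' @param f470 `vc_frames` of the calcium-sensitive channel.
#' @param f405 `vc_frames` of the hemodynamic reference channel.
#' @return corrected `vc_frames` at the 470-nm frame times.
#' @export
hemodynamic_correct <- function(f470, f405) {
  if (abs(length(f470$trace) - length(f405$trace)) > 1) {
    stop("channel lengths differ by more than one frame")
  }
  interp <- stats::approx(f405$times, f405$trace, xout = f470$times,
                          rule = 2)$y
  ratio <- f470$trace / interp
  frame_series(ratio / mean(ratio), f470$times)
}

#' Low-cut filter and session normalization
#'
#' Applies an order-2 Butterworth high-pass (forward-backward, so zero
#' phase) at the given cut-off, restores the DC offset, and normalizes by
#' the session standard deviation so the output trace has SD 1.
#'
#' @param trace numeric vector or `vc_frames`.
#' @param fs sampling rate, Hz (ignored when `trace` is a `vc_frames`).
#' @param cutoff high-pass cut-off, Hz.
#' @return normalized trace of the same class as the input; a zero-variance
#'   input is returned unscaled with a warning.
#' @export
preprocess_trace <- function(trace, fs = 25, cutoff = 0.00333) {
  is_fs <- inherits(trace, "vc_frames")
  x <- if (is_fs) trace$trace else as.numeric(trace)
  if (is_fs) fs <- 1 / stats::median(diff(trace$times))
  if (length(x) < 24) stop("trace shorter than the filter warm-up")
  dc <- mean(x)
  bf <- signal::butter(2, cutoff / (fs / 2), type = "high")
  y <- signal::filtfilt(bf, x - dc) + dc
  s <- stats::sd(y)
  if (s == 0) {
    warning("zero-variance trace; normalization skipped")
  } else {
    y <- y / s
  }
  if (is_fs) frame_series(y, trace$times) else y
}

#' Resample the monitor-frame stimulus to imaging frames
#'
#' Per imaging frame, the duration-weighted mean of the log2 TF values of
#' the monitor frames overlapping its exposure window.
#'
#' @param monitor_frames data frame with `onset`, `duration` (s) and
#'   `log2tf` columns.
#' @param frame_windows data frame with `start` and `end` columns (s).
#' @return data frame with `start`, `end`, `value` (octaves; NA where no
#'   overlap) and `valid`.
#' @export
resample_stimulus <- function(monitor_frames, frame_windows) {
  m_on <- monitor_frames$onset
  m_off <- m_on + monitor_frames$duration
  v <- monitor_frames$log2tf
  out <- vapply(seq_len(nrow(frame_windows)), function(i) {
    a <- frame_windows$start[i]; b <- frame_windows$end[i]
    p <- pmin(m_off, b) - pmax(m_on, a)
    keep <- p > 0
    if (!any(keep)) return(NA_real_)
    sum(p[keep] * v[keep]) / sum(p[keep])
  }, 0)
  data.frame(start = frame_windows$start, end = frame_windows$end,
             value = out, valid = !is.na(out))
}

#' Align a frame series to events
#'
#' Time 0 is the frame whose exposure interval contains the event (ties at
#' boundaries go to the earlier frame). Each aligned trace is baseline
#' corrected by its mean over `baseline_window` seconds before the event.
#' Optionally, frames at/after a per-event censor time are dropped and
#' events with less than `min_valid` seconds of valid post-event trace are
#' excluded.
#'
#' @param series a `vc_frames`.
#' @param events event times, s.
#' @param window c(before, after) in seconds around the event.
#' @param baseline_window pre-event window for baseline subtraction, s
#'   (480 ms for stimulus/change onsets, 2000 ms for licks).
#' @param censor optional per-event times after which frames are invalid.
#' @param min_valid minimum valid post-event duration, s (0 disables).
#' @param level confidence level of the across-event CI.
#' @return list: `lag` (s), `mean`, `lo`, `hi`, `n_events`, `n_skipped`,
#'   and the aligned `matrix` (events x lags).
#' @export
align_to_events <- function(series, events, window = c(-0.5, 2),
                            baseline_window = 0.48, censor = NULL,
                            min_valid = 0, level = 0.95) {
  dt <- stats::median(diff(series$times))
  k_lo <- round(window[1] / dt); k_hi <- round(window[2] / dt)
  lags <- (k_lo:k_hi) * dt
  n_fr <- length(series$trace)
  rows <- list(); skipped <- 0L
  for (e in seq_along(events)) {
    ev <- events[e]
    # frame containing the event; boundary ties go to the earlier frame
    i0 <- findInterval(ev, series$times, left.open = TRUE)
    if (i0 < 1 || ev > series$times[n_fr] + dt) {
      skipped <- skipped + 1L
      next
    }
    idx <- i0 + (k_lo:k_hi)
    vals <- ifelse(idx >= 1 & idx <= n_fr, series$trace[pmax(pmin(idx, n_fr), 1)],
                   NA_real_)
    if (!is.null(censor)) {
      tt <- series$times[pmax(pmin(idx, n_fr), 1)]
      vals[idx >= 1 & idx <= n_fr & tt >= censor[e]] <- NA_real_
    }
    if (min_valid > 0) {
      post <- vals[lags >= 0 & lags <= min_valid]
      if (anyNA(post)) { skipped <- skipped + 1L; next }
    }
    base_sel <- lags < 0 & lags >= -baseline_window
    base <- mean(vals[base_sel], na.rm = TRUE)
    if (!is.finite(base)) base <- 0
    rows[[length(rows) + 1]] <- vals - base
  }
  if (!length(rows)) stop("no alignable events")
  M <- do.call(rbind, rows)
  mu <- colMeans(M, na.rm = TRUE)
  n_eff <- colSums(!is.na(M))
  se <- apply(M, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(n_eff, 1))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(lag = lags, mean = mu, lo = mu - z * se, hi = mu + z * se,
       n_events = nrow(M), n_skipped = skipped, matrix = M)
}

#' Threshold-crossing latency of an aligned response
#'
#' First time the trace crosses `fraction` of its maximum, with linear
#' interpolation between samples.
#'
#' @param lag lag axis, s.
#' @param trace mean aligned trace.
#' @param fraction threshold fraction of the maximum (e.g. 0.1 or 0.5).
#' @return crossing time in seconds, or NA if the threshold is never
#'   crossed (or the trace is all zero).
#' @export
threshold_latency <- function(lag, trace, fraction = 0.5) {
  mx <- max(trace, na.rm = TRUE)
  if (!is.finite(mx) || mx <= 0) return(NA_real_)
  thr <- fraction * mx
  above <- which(trace >= thr)
  if (!length(above)) return(NA_real_)
  i <- above[1]
  if (i == 1) return(lag[1])
  # linear interpolation between the bracketing samples
  x0 <- lag[i - 1]; x1 <- lag[i]
  y0 <- trace[i - 1]; y1 <- trace[i]
  x0 + (thr - y0) / (y1 - y0) * (x1 - x0)
}
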