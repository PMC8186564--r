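# Lagged/interaction regressions of fluorescence on baseline stimulus
# fluctuations, multiexponential time-course fitting, binned fast/slow
# responses, and blocked-CV ridge deconvolution.

#' Lagged regression of fluorescence on baseline stimulus fluctuations
#'
#' For each lag t, the fluorescence shifted by t and corrected by its value
#' at the time of the stimulus sample (so the lag-0 slope is identically 0)
#' is regressed on the resampled log2 TF with an intercept:
#' `f(t) - f(0) = a_t + s b_t`. Only frame pairs whose stimulus frame and
#' response frame are both valid enter the fit. Normal-theory 95% CIs;
#' lags whose CI excludes 0 are flagged significant.
#'
#' @param trace fluorescence on the frame grid (z-units).
#' @param stim resampled stimulus values per frame (octaves).
#' @param valid logical mask per frame (baseline frames at least 1 s before
#'   early licks/wheel movements and before the change).
#' @param fs frame rate, Hz.
#' @param lags requested lags, s; mapped to the nearest integer frame
#'   offsets (duplicates dropped).
#' @param min_n minimum valid pairs per lag.
#' @param level confidence level.
#' @return data frame per lag: `lag` (realized, s), `intercept`, `slope`,
#'   `lo`, `hi`, `n`, `significant`.
#' @export
lagged_regression <- function(trace, stim, valid = NULL, fs = 25,
                              lags = seq(0, 2, by = 0.05), min_n = 10,
                              level = 0.95) {
  n <- length(trace)
  stopifnot(length(stim) == n)
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- valid & !is.na(stim) & !is.na(trace)
  offs <- unique(round(lags * fs))
  rows <- lapply(offs, function(k) {
    i <- which(valid)
    j <- i + k
    keep <- j >= 1 & j <= n
    i <- i[keep]; j <- j[keep]
    keep2 <- valid[j]
    i <- i[keep2]; j <- j[keep2]
    lag_s <- k / fs
    if (length(i) < min_n) {
      return(data.frame(lag = lag_s, intercept = NA_real_, slope = NA_real_,
                        lo = NA_real_, hi = NA_real_, n = length(i),
                        significant = NA))
    }
    y <- trace[j] - trace[i]
    x <- stim[i]
    if (k == 0 || stats::var(y) == 0) {
      return(data.frame(lag = lag_s, intercept = 0, slope = 0, lo = 0, hi = 0,
                        n = length(i), significant = FALSE))
    }
    fit <- stats::lm(y ~ x)
    ci <- stats::confint(fit, "x", level = level)
    data.frame(lag = lag_s, intercept = stats::coef(fit)[1],
               slope = stats::coef(fit)[2], lo = ci[1], hi = ci[2],
               n = length(i), significant = ci[1] > 0 | ci[2] < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lagged regression with an expectation-block interaction
#'
#' Adds a block indicator `e` (1 = early block, 0 = late block) and its
#' interaction with the stimulus: `f(t) - f(0) = a_t + s b_t + e c_t +
#' (e*s) d_t`. The interaction coefficient `d_t` estimates how temporal
#' expectation modulates the fluorescence/stimulus slope.
#'
#' @inheritParams lagged_regression
#' @param block character or factor per frame (`"early"`/`"late"`).
#' @return data frame per lag with `slope`, `block_term`, `interaction`,
#'   interaction CI (`d_lo`, `d_hi`) and `significant` (interaction CI
#'   excludes 0).
#' @export
interaction_regression <- function(trace, stim, block, valid = NULL, fs = 25,
                                   lags = seq(0, 2, by = 0.05), min_n = 10,
                                   level = 0.95) {
  n <- length(trace)
  e <- as.integer(block == "early")
  if (length(unique(e[!is.na(e)])) < 2) {
    stop("interaction undefined with a single block")
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- valid & !is.na(stim) & !is.na(trace)
  offs <- unique(round(lags * fs))
  rows <- lapply(offs, function(k) {
    i <- which(valid)
    j <- i + k
    keep <- j >= 1 & j <= n
    i <- i[keep]; j <- j[keep]
    keep2 <- valid[j]
    i <- i[keep2]; j <- j[keep2]
    lag_s <- k / fs
    if (length(i) < max(min_n, 4)) {
      return(data.frame(lag = lag_s, intercept = NA_real_, slope = NA_real_,
                        block_term = NA_real_, interaction = NA_real_,
                        d_lo = NA_real_, d_hi = NA_real_, n = length(i),
                        significant = NA))
    }
    y <- trace[j] - trace[i]
    x <- stim[i]; ei <- e[i]
    if (k == 0 || stats::var(y) == 0) {
      return(data.frame(lag = lag_s, intercept = 0, slope = 0, block_term = 0,
                        interaction = 0, d_lo = 0, d_hi = 0, n = length(i),
                        significant = FALSE))
    }
    fit <- stats::lm(y ~ x + ei + x:ei)
    cf <- stats::coef(fit)
    ci <- stats::confint(fit, "x:ei", level = level)
    data.frame(lag = lag_s, intercept = cf[1], slope = cf["x"],
               block_term = cf["ei"], interaction = cf["x:ei"],
               d_lo = ci[1], d_hi = ci[2], n = length(i),
               significant = ci[1] > 0 | ci[2] < 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Multiexponential fit of a lagged-regression time course
#'
#' Fits `b(t) = b_max (1 - exp(-t / tau_r))^z exp(-t / tau_d)` by bounded
#' nonlinear least squares with multiple starts. Latency is the first time
#' the fitted curve reaches 50% of its maximum absolute value; half-decay
#' is the time after the maximum at which the (extrapolated) fit falls
#' below 50% of the maximum, reported as NA ("not determined") if this
#' does not happen within `nd_window` seconds of the stimulus sample.
#'
#' @param lag lag axis, s.
#' @param b coefficients per lag (e.g. the `slope` column of
#'   [lagged_regression()]).
#' @param nd_window window within which the half-decay must occur, s.
#' @param grid_step evaluation step of the fitted curve, s.
#' @param n_starts number of random restarts.
#' @param seed integer seed for the restarts.
#' @return list with `b_max`, `z`, `tau_r`, `tau_d`, `latency`,
#'   `half_decay` (NA if not determined), `converged`, and the `fitted`
#'   values on `lag`.
#' @export
multiexp_fit <- function(lag, b, nd_window = 4, grid_step = 0.001,
                         n_starts = 8, seed = 1) {
  ok <- is.finite(b) & is.finite(lag)
  lag <- lag[ok]; b <- b[ok]
  stopifnot(length(lag) >= 5)
  set.seed(seed)
  sgn <- sign(b[which.max(abs(b))])
  if (sgn == 0) sgn <- 1
  amp0 <- max(abs(b))
  starts <- data.frame(
    b_max = sgn * amp0 * stats::runif(n_starts, 0.5, 2),
    z = stats::runif(n_starts, 0.5, 3),
    tau_r = stats::runif(n_starts, 0.05, 0.5),
    tau_d = stats::runif(n_starts, 0.2, 3)
  )
  starts[1, ] <- c(sgn * amp0, 1, 0.1, 1)
  best <- NULL; best_rss <- Inf
  for (s in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        b ~ b_max * (1 - exp(-lag / tau_r))^z * exp(-lag / tau_d),
        start = as.list(starts[s, ]),
        lower = c(b_max = -10 * amp0 - 1e-9, z = 0.1, tau_r = 1e-3,
                  tau_d = 1e-2),
        upper = c(b_max = 10 * amp0 + 1e-9, z = 10, tau_r = 10, tau_d = 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best)) {
    return(list(b_max = NA, z = NA, tau_r = NA, tau_d = NA, latency = NA,
                half_decay = NA, converged = FALSE, fitted = rep(NA, length(lag))))
  }
  p <- as.list(stats::coef(best))
  curve_fn <- function(t) {
    p$b_max * (1 - exp(-t / p$tau_r))^p$z * exp(-t / p$tau_d)
  }
  tt <- seq(0, nd_window, by = grid_step)
  ft <- curve_fn(tt)
  mx_abs <- max(abs(ft))
  latency <- if (mx_abs > 0) tt[which(abs(ft) >= 0.5 * mx_abs)[1]] else NA_real_
  i_max <- which.max(abs(ft))
  post <- which(seq_along(tt) > i_max & abs(ft) < 0.5 * mx_abs)
  # duration from the response maximum to the 50% crossing
  half_decay <- if (length(post)) tt[post[1]] - tt[i_max] else NA_real_
  list(b_max = p$b_max, z = p$z, tau_r = p$tau_r, tau_d = p$tau_d,
       latency = latency, half_decay = half_decay, converged = TRUE,
       fitted = curve_fn(lag))
}

#' Binned fast/slow stimulus responses
#'
#' Stimulus samples beyond +/- `threshold_sd` empirical SDs of the valid
#' resampled values define fast (pro-licking) and slow (anti-licking)
#' events; samples within +/- `reference_sd` SDs define the reference bin.
#' Event-aligned mean traces of the extreme bins are corrected by the
#' reference-bin trace; CIs use the normal approximation from standard
#' errors, and fast-vs-slow differences are flagged per time point by a
#' two-sample t test at `alpha`.
#'
#' @param trace fluorescence on the frame grid (z-units).
#' @param stim resampled stimulus values per frame (octaves).
#' @param valid logical mask per frame.
#' @param fs frame rate, Hz.
#' @param window c(before, after) in seconds around the stimulus sample.
#' @param threshold_sd extreme-bin threshold in empirical SDs.
#' @param reference_sd reference-bin half-width in empirical SDs.
#' @param alpha significance level of the t test.
#' @return list with `lag`, `fast`, `slow` (each: mean, lo, hi, n),
#'   `significant` (per lag), and the bin occupancies.
#' @export
binned_response <- function(trace, stim, valid = NULL, fs = 25,
                            window = c(-0.2, 2), threshold_sd = 1.5,
                            reference_sd = 0.5, alpha = 0.05) {
  n <- length(trace)
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- valid & !is.na(stim)
  mu <- mean(stim[valid]); sdv <- stats::sd(stim[valid])
  fast_i <- which(valid & stim > mu + threshold_sd * sdv)
  slow_i <- which(valid & stim < mu - threshold_sd * sdv)
  ref_i <- which(valid & abs(stim - mu) <= reference_sd * sdv)
  occ <- c(fast = length(fast_i), slow = length(slow_i), ref = length(ref_i))
  if (any(occ == 0)) {
    stop("empty stimulus bin; occupancies: ",
         paste(names(occ), occ, sep = "=", collapse = ", "))
  }
  k_lo <- round(window[1] * fs); k_hi <- round(window[2] * fs)
  lags <- (k_lo:k_hi) / fs
  snip <- function(idx) {
    M <- vapply(k_lo:k_hi, function(k) {
      j <- idx + k
      out <- rep(NA_real_, length(idx))
      okj <- j >= 1 & j <= n
      out[okj] <- trace[j[okj]]
      out
    }, numeric(length(idx)))
    if (is.null(dim(M))) M <- matrix(M, nrow = length(idx))
    M
  }
  Mf <- snip(fast_i); Ms <- snip(slow_i); Mr <- snip(ref_i)
  ref_mean <- colMeans(Mr, na.rm = TRUE)
  summarize <- function(M) {
    m <- colMeans(M, na.rm = TRUE) - ref_mean
    ne <- colSums(!is.na(M))
    se <- apply(M, 2, stats::sd, na.rm = TRUE) / sqrt(pmax(ne, 1))
    z <- stats::qnorm(0.975)
    list(mean = m, lo = m - z * se, hi = m + z * se, n = ne, se = se)
  }
  fast <- summarize(Mf); slow <- summarize(Ms)
  # per-timepoint Welch t test between fast and slow raw traces
  sig <- vapply(seq_along(lags), function(k) {
    a <- Mf[, k]; b <- Ms[, k]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) return(NA)
    stats::t.test(a, b)$p.value < alpha
  }, NA)
  list(lag = lags, fast = fast, slow = slow, significant = sig,
       occupancy = occ, stim_mean = mu, stim_sd = sdv)
}

#' Pearson correlation of two response time courses
#'
#' Resamples profile `b` onto profile `a`'s lag grid by linear
#' interpolation and returns the Pearson correlation over the window.
#'
#' @param lag_a,val_a first profile (lag axis in s, values).
#' @param lag_b,val_b second profile.
#' @param window correlation window, s.
#' @return Pearson r.
#' @export
compare_timecourses <- function(lag_a, val_a, lag_b, val_b,
                                window = c(0, 1.48)) {
  sel <- lag_a >= window[1] & lag_a <= window[2]
  if (!any(sel)) stop("window outside the first profile's lag grid")
  xa <- lag_a[sel]
  if (min(xa) < min(lag_b) - 1e-9 || max(xa) > max(lag_b) + 1e-9) {
    stop("window outside the second profile's lag grid")
  }
  vb <- stats::approx(lag_b, val_b, xout = xa)$y
  stats::cor(val_a[sel], vb)
}
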