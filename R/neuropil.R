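# Two-photon trace conditioning: rolling-percentile detrending and
# asymmetric Student-t (ASt) neuropil correction. The ASt error model uses
# nearly-Gaussian left tails (v1 = 30) and Cauchy-like right tails
# (v2 = 1), so large positive calcium transients are absorbed by the heavy
# right tail instead of inflating the contamination estimate.

#' Asymmetric Student-t density
#'
#' Piecewise Student-t with shared scale: left of the location the shape is
#' a t with `v1` degrees of freedom, right of it a t with `v2`; both pieces
#' equal 1 at the location before normalization, so the density is
#' continuous there, and the closed-form normalizer makes it integrate
#' to 1.
#'
#' @param x quantiles.
#' @param mu location.
#' @param sigma scale (> 0).
#' @param v1,v2 left/right tail degrees of freedom (> 0).
#' @param log return the log density.
#' @return density values.
#' @export
dast <- function(x, mu = 0, sigma = 1, v1 = 30, v2 = 1, log = FALSE) {
  stopifnot(sigma > 0, v1 > 0, v2 > 0)
  z <- (x - mu) / sigma
  v <- ifelse(z < 0, v1, v2)
  logg <- -(v + 1) / 2 * log1p(z^2 / v)
  # \int_{-inf}^0 (1+z^2/v)^{-(v+1)/2} dz = 1 / (2 c_v), the half mass of
  # an unnormalized t; c_v is the usual t normalizing constant
  cdof <- function(v) exp(lgamma((v + 1) / 2) - lgamma(v / 2)) / sqrt(v * pi)
  lognorm <- log(sigma) + log(0.5 / cdof(v1) + 0.5 / cdof(v2))
  out <- logg - lognorm
  if (log) out else exp(out)
}

# derivative of log dast wrt the residual r (at mu = 0)
#' @keywords internal
dast_score <- function(r, sigma, v1, v2) {
  z <- r / sigma
  v <- ifelse(z < 0, v1, v2)
  -(v + 1) * z / (v + z^2) / sigma
}

# second derivative of log dast wrt r
#' @keywords internal
dast_curv <- function(r, sigma, v1, v2) {
  z <- r / sigma
  v <- ifelse(z < 0, v1, v2)
  -(v + 1) * (v - z^2) / (v + z^2)^2 / sigma^2
}

#' Rolling-percentile detrending
#'
#' Subtracts the centered rolling 10th percentile in a 4000-frame
#' (~2 minute) window; edges use truncated windows. A window larger than
#' the trace degenerates to subtracting a single global percentile.
#'
#' @param trace numeric vector.
#' @param window window length in frames.
#' @param percentile percentile in \[0, 1\].
#' @return detrended trace.
#' @export
detrend_trace <- function(trace, window = 4000, percentile = 0.1) {
  n <- length(trace)
  if (n < 2) stop("trace shorter than 2 frames")
  if (window >= n) {
    return(trace - stats::quantile(trace, percentile, names = FALSE))
  }
  half <- floor(window / 2)
  base <- vapply(seq_len(n), function(i) {
    lo <- max(1, i - half)
    hi <- min(n, i + half)
    stats::quantile(trace[lo:hi], percentile, names = FALSE)
  }, 0)
  trace - base
}

#' Asymmetric Student-t neuropil correction
#'
#' Models the detrended ROI and surround traces as sharing a common
#' neuropil signal n_t: `roi_t = alpha * n_t + e1` and
#' `surround_t = n_t + e2`, with errors following asymmetric Student-t
#' distributions (shared left/right degrees of freedom, per-trace scales).
#' Estimation alternates closed-coordinate blocks: n_t by damped
#' vectorized Newton steps on the pointwise log-likelihood, then
#' (alpha, scales) by bounded quasi-Newton, until the log-likelihood gain
#' per frame falls below `tol`. The corrected trace is
#' `roi - alpha_hat * n_hat`.
#'
#' @param roi detrended ROI trace.
#' @param surround detrended surround (neuropil) trace, same length.
#' @param v1,v2 left/right tail degrees of freedom.
#' @param alpha_init,alpha_bounds initial value and bounds of the
#'   contamination coefficient.
#' @param tol convergence tolerance, log-likelihood gain per frame.
#' @param max_iter maximum outer iterations.
#' @return a `vc_neuropil_fit`: `alpha`, `neuropil` (n_hat), `corrected`,
#'   `sigma_roi`, `sigma_surround`, `loglik`, `iterations`, `converged`.
#' @export
ast_correct <- function(roi, surround, v1 = 30, v2 = 1, alpha_init = 0.7,
                        alpha_bounds = c(0, 2), tol = 1e-6, max_iter = 50) {
  stopifnot(length(roi) == length(surround))
  if (any(!is.finite(roi)) || any(!is.finite(surround))) {
    stop("non-finite values in input traces")
  }
  if (stats::sd(surround) == 0) stop("zero-variance surround trace")
  n_t <- surround
  alpha <- alpha_init
  s1 <- stats::mad(roi - alpha * n_t) + 1e-6
  s2 <- stats::mad(surround - n_t) + 1e-3
  T <- length(roi)
  ll_point <- function(n_t, alpha, s1, s2) {
    dast(roi - alpha * n_t, 0, s1, v1, v2, log = TRUE) +
      dast(surround - n_t, 0, s2, v1, v2, log = TRUE)
  }
  total_ll <- function(n_t, alpha, s1, s2) sum(ll_point(n_t, alpha, s1, s2))
  ll_old <- total_ll(n_t, alpha, s1, s2)
  iter <- 0L; converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    # --- update n_t: damped Newton, vectorized over frames -------------
    for (k in seq_len(25)) {
      r1 <- roi - alpha * n_t
      r2 <- surround - n_t
      g <- alpha * dast_score(r1, s1, v1, v2) + dast_score(r2, s2, v1, v2)
      h <- alpha^2 * dast_curv(r1, s1, v1, v2) + dast_curv(r2, s2, v1, v2)
      # keep steps well-defined where the curvature is non-negative
      h <- pmin(h, -1e-3 / max(s1, s2)^2)
      step <- -g / h
      cap <- 3 * max(s1, s2)
      step <- pmax(pmin(step, cap), -cap)
      old_pt <- ll_point(n_t, alpha, s1, s2)
      cand <- n_t + step
      new_pt <- ll_point(cand, alpha, s1, s2)
      worse <- new_pt < old_pt
      tries <- 0
      while (any(worse) && tries < 8) {
        step[worse] <- step[worse] / 2
        cand[worse] <- n_t[worse] + step[worse]
        new_pt[worse] <- ll_point(cand, alpha, s1, s2)[worse]
        worse <- new_pt < old_pt
        tries <- tries + 1
      }
      cand[worse] <- n_t[worse]
      moved <- mean(abs(cand - n_t))
      n_t <- cand
      if (moved < 1e-8 * max(s1, s2)) break
    }
    # --- update alpha and scales ---------------------------------------
    obj <- function(par) {
      a <- par[1]; ls1 <- par[2]; ls2 <- par[3]
      -total_ll(n_t, a, exp(ls1), exp(ls2))
    }
    opt <- stats::optim(c(alpha, log(s1), log(s2)), obj, method = "L-BFGS-B",
                        lower = c(alpha_bounds[1], log(1e-8), log(1e-8)),
                        upper = c(alpha_bounds[2], log(1e8), log(1e8)))
    alpha <- opt$par[1]; s1 <- exp(opt$par[2]); s2 <- exp(opt$par[3])
    ll_new <- -opt$value
    if (abs(ll_new - ll_old) < tol * T) { converged <- TRUE; ll_old <- ll_new; break }
    ll_old <- ll_new
  }
  structure(list(alpha = alpha, neuropil = n_t,
                 corrected = roi - alpha * n_t,
                 sigma_roi = s1, sigma_surround = s2,
                 loglik = ll_old, iterations = iter, converged = converged),
            class = "vc_neuropil_fit")
}
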