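# Kernel-side primitives of the lick-hazard GP: linear stimulus filters,
# monotone tanh time warping, and Matern 5/2 covariances with population
# and block-specific components.

#' Project stimulus history through the filter bank
#'
#' `phi = s' W`: each column of `W` is a stimulus filter over the `Q` most
#' recent 50-ms samples (most recent first); the projection gives the
#' low-dimensional filtered-stimulus coordinates seen by the GP.
#'
#' @param s stimulus history: a `Q`-vector or an `n x Q` matrix (rows =
#'   samples, columns = lags, most recent first), padded with the baseline
#'   mean before stimulus onset.
#' @param W `Q x D` filter matrix.
#' @return a `D`-vector or `n x D` matrix of filter outputs.
#' @export
project_filters <- function(s, W) {
  if (is.null(dim(s))) {
    if (length(s) != nrow(W)) stop("history length does not match filters")
    return(drop(crossprod(W, s)))
  }
  if (ncol(s) != nrow(W)) stop("history length does not match filters")
  s %*% W
}

#' Monotone tanh time warp
#'
#' `t_w = t + sum_k a_k tanh(b_k t + c_k)`. Non-negative `a` and `b`
#' guarantee strict monotonicity on `t >= 0`, keeping the warped axis
#' invertible so a stationary kernel on warped time can express
#' non-stationary timing behavior.
#'
#' @param t times, s (>= 0).
#' @param a,b,c warp coefficient vectors of equal length `J`; `a` and `b`
#'   must be non-negative.
#' @return warped times.
#' @export
warp_time <- function(t, a, b, c) {
  stopifnot(length(a) == length(b), length(b) == length(c))
  if (any(a < 0) || any(b < 0)) {
    stop("warp coefficients a and b must be non-negative")
  }
  out <- t
  for (k in seq_along(a)) out <- out + a[k] * tanh(b[k] * t + c[k])
  out
}

# Matern 5/2 profile and its derivative wrt the distance r
#' @keywords internal
matern52 <- function(r) {
  sr <- sqrt(5) * r
  (1 + sr + sr^2 / 3) * exp(-sr)
}

# d matern52 / d r  =  -(5/3) r (1 + sqrt(5) r) exp(-sqrt(5) r)
#' @keywords internal
matern52_dr <- function(r) {
  -(5 / 3) * r * (1 + sqrt(5) * r) * exp(-sqrt(5) * r)
}

# d matern52 / d r / r, with its r -> 0 limit -(5/3)
#' @keywords internal
matern52_dr_over_r <- function(r) {
  -(5 / 3) * (1 + sqrt(5) * r) * exp(-sqrt(5) * r)
}

#' Kernel hyperparameters of the hazard GP
#'
#' One population component plus one component per block. Each component
#' has a stimulus variance (Matern 5/2 over filter outputs, lengthscale
#' fixed to 1), a time variance and a time lengthscale (Matern 5/2 over
#' warped time). Block components only contribute when both inputs carry
#' the same block tag.
#'
#' @param sigma2_s,sigma2_t,ell_t vectors of length `1 + n_blocks`
#'   (population first).
#' @param blocks character vector of block labels.
#' @return a `vc_kernel_params` list.
#' @export
kernel_params <- function(sigma2_s = 1, sigma2_t = 1, ell_t = 1,
                          blocks = character(0)) {
  n_comp <- 1 + length(blocks)
  sigma2_s <- rep_len(sigma2_s, n_comp)
  sigma2_t <- rep_len(sigma2_t, n_comp)
  ell_t <- rep_len(ell_t, n_comp)
  stopifnot(all(sigma2_s >= 0), all(sigma2_t >= 0), all(ell_t > 0))
  structure(list(sigma2_s = sigma2_s, sigma2_t = sigma2_t, ell_t = ell_t,
                 blocks = blocks), class = "vc_kernel_params")
}

#' Evaluate the hazard-model kernel between two inputs
#'
#' `kappa = kappa_s + kappa_t`, where each part sums the population
#' component and, when the block tags match, the block-specific component.
#'
#' @param x,xp inputs: lists with `phi` (filter outputs), `t` (time, s)
#'   and `block` (label).
#' @param params a [kernel_params()].
#' @param warp optional list with `a`, `b`, `c` applied to the times.
#' @return scalar covariance.
#' @export
kernel_eval <- function(x, xp, params, warp = NULL) {
  comp_of <- function(bl) {
    if (is.null(bl) || !length(params$blocks)) return(integer(0))
    i <- match(bl, params$blocks)
    if (is.na(i)) stop("unknown block tag: ", bl)
    i + 1L
  }
  comps <- 1L
  if (!is.null(x$block) && !is.null(xp$block) &&
      identical(x$block, xp$block)) {
    comps <- c(comps, comp_of(x$block))
  } else {
    comp_of(x$block); comp_of(xp$block) # validate tags
  }
  r_s <- sqrt(sum((x$phi - xp$phi)^2))
  t1 <- x$t; t2 <- xp$t
  if (!is.null(warp)) {
    t1 <- warp_time(t1, warp$a, warp$b, warp$c)
    t2 <- warp_time(t2, warp$a, warp$b, warp$c)
  }
  out <- 0
  for (ci in comps) {
    out <- out + params$sigma2_s[ci] * matern52(r_s) +
      params$sigma2_t[ci] * matern52(abs(t1 - t2) / params$ell_t[ci])
  }
  out
}

# ---- vectorized internals used by training and prediction ---------------

# cross-distance matrix between phi rows (n x D) and (m x D)
#' @keywords internal
cross_dist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

# kernel matrices between (phiX, twX, bX) and (phiZ, twZ, bZ)
# kern: list(sigma2_s, sigma2_t, ell_t, blocks) as kernel_params
# returns K (and optionally the stimulus-only and time-only parts)
#' @keywords internal
kern_cross <- function(phiX, twX, bX, phiZ, twZ, bZ, kern, parts = FALSE) {
  Rs <- cross_dist(phiX, phiZ)
  Dt <- abs(outer(twX, twZ, "-"))
  Ks <- kern$sigma2_s[1] * matern52(Rs)
  Kt <- kern$sigma2_t[1] * matern52(Dt / kern$ell_t[1])
  for (bi in seq_along(kern$blocks)) {
    ci <- bi + 1L
    mask <- outer(bX == kern$blocks[bi], bZ == kern$blocks[bi]) # numeric 0/1
    if (!any(mask != 0)) next
    Ks <- Ks + kern$sigma2_s[ci] * matern52(Rs) * mask
    Kt <- Kt + kern$sigma2_t[ci] * matern52(Dt / kern$ell_t[ci]) * mask
  }
  if (parts) list(K = Ks + Kt, Ks = Ks, Kt = Kt, Rs = Rs, Dt = Dt)
  else list(K = Ks + Kt, Rs = Rs, Dt = Dt)
}

# prior variance kappa(x, x) per sample
#' @keywords internal
kern_diag <- function(bX, kern) {
  out <- rep(kern$sigma2_s[1] + kern$sigma2_t[1], length(bX))
  for (bi in seq_along(kern$blocks)) {
    ci <- bi + 1L
    sel <- bX == kern$blocks[bi]
    out[sel] <- out[sel] + kern$sigma2_s[ci] + kern$sigma2_t[ci]
  }
  out
}
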