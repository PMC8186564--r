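# Lagged ridge design construction and blocked cross-validated ridge fits
# separating stimulus/change-evoked fluorescence from movement confounds.

# lagged copies of x at integer frame offsets (positive = past)
#' @keywords internal
lag_block <- function(x, offsets) {
  n <- length(x)
  M <- vapply(offsets, function(k) {
    if (k >= 0) c(rep(0, k), x[seq_len(n - k)])
    else c(x[(1 - k):n], rep(0, -k))
  }, numeric(n))
  colnames(M) <- sprintf("lag%+d", offsets)
  M
}

#' Build a lagged ridge design matrix
#'
#' Assembles the design used to deconvolve fluorescence into stimulus,
#' movement and lick components: a constant column; stimulus history over
#' the past 2 s; movement predictors over the past 2 s and 0.52 s into the
#' future (lag 0 counted once, in the past block); lick onsets 0.68 s past
#' to 0.52 s future; and, in change mode, categorical change-onset
#' regressors per magnitude spanning 2 s. Every column except the constant
#' is rescaled by its standard deviation (recorded for later unscaling).
#' In change mode the response is corrected per trial by its value at
#' change onset.
#'
#' @param trace fluorescence response on the frame grid.
#' @param stim resampled stimulus per frame (baseline mode), or NULL.
#' @param movement named list of movement traces on the frame grid.
#' @param lick_frames integer frame indices of licks (optional).
#' @param change_onsets named list: per magnitude, integer frame indices of
#'   change onsets (change mode).
#' @param fs frame rate, Hz.
#' @param valid logical mask of rows to keep.
#' @param stim_span,move_past,move_future,lick_past,lick_future,change_span
#'   lag windows in seconds.
#' @param mode `"baseline"` or `"change"`.
#' @return a `vc_ridge_problem`: `X` (scaled), `y`, `scales`, `blocks`
#'   (column block labels), `valid_rows`.
#' @export
build_design <- function(trace, stim = NULL, movement = list(),
                         lick_frames = integer(0), change_onsets = list(),
                         fs = 25, valid = NULL,
                         stim_span = 2, move_past = 2, move_future = 0.52,
                         lick_past = 0.68, lick_future = 0.52,
                         change_span = 2,
                         mode = c("baseline", "change")) {
  mode <- match.arg(mode)
  n <- length(trace)
  if (mode == "change" && !length(movement)) {
    stop("change mode requires movement traces")
  }
  cols <- list(const = matrix(1, n, 1))
  blocks <- "const"
  if (!is.null(stim)) {
    s <- stim; s[is.na(s)] <- 0
    B <- lag_block(s, 0:round(stim_span * fs))
    cols$stim <- B
    blocks <- c(blocks, rep("stim", ncol(B)))
  }
  if (mode == "change") {
    for (nm in names(change_onsets)) {
      ev <- rep(0, n); ev[change_onsets[[nm]]] <- 1
      B <- lag_block(ev, 0:round(change_span * fs))
      cols[[paste0("C", nm)]] <- B
      blocks <- c(blocks, rep(paste0("C", nm), ncol(B)))
    }
  }
  for (nm in names(movement)) {
    B <- lag_block(movement[[nm]],
                   (-round(move_future * fs)):(round(move_past * fs)))
    cols[[paste0("M", nm)]] <- B
    blocks <- c(blocks, rep(paste0("M", nm), ncol(B)))
  }
  if (length(lick_frames)) {
    ev <- rep(0, n); ev[lick_frames] <- 1
    B <- lag_block(ev, (-round(lick_future * fs)):(round(lick_past * fs)))
    cols$L <- B
    blocks <- c(blocks, rep("L", ncol(B)))
  }
  X <- do.call(cbind, cols)
  y <- trace
  if (mode == "change") {
    # correct each trial by the fluorescence at its change onset
    all_on <- sort(unlist(change_onsets))
    if (length(all_on)) {
      bounds <- c(all_on, n + 1L)
      for (k in seq_along(all_on)) {
        idx <- all_on[k]:(bounds[k + 1] - 1L)
        y[idx] <- y[idx] - trace[all_on[k]]
      }
    }
  }
  if (is.null(valid)) valid <- rep(TRUE, n)
  valid <- valid & !is.na(y)
  X <- X[valid, , drop = FALSE]
  y <- y[valid]
  scales <- apply(X, 2, stats::sd)
  scales[1] <- 1 # constant column unscaled
  scales[scales == 0] <- 1
  X <- sweep(X, 2, scales, "/")
  structure(list(X = X, y = y, scales = scales, blocks = blocks,
                 valid_rows = which(valid), mode = mode),
            class = "vc_ridge_problem")
}

#' Blocked cross-validated ridge regression
#'
#' Closed-form ridge solutions over a penalty grid (36 values log-spaced
#' between 1e-2 and 1e5 by default), with the first diagonal element of
#' the penalty zeroed so the intercept is never regularized. The valid
#' sample sequence is divided into 5 equal contiguous folds; the penalty
#' minimizing mean held-out squared error is refit on all data. Reported
#' coefficients are divided by the column scale factors.
#'
#' @param problem a [build_design()] result.
#' @param lambda penalty grid.
#' @param n_folds number of contiguous folds.
#' @return a `vc_ridge_fit`: `coef` (unscaled, named by block),
#'   `blocks`, `lambda`, `lambda_grid`, `cv_mse` (grid x 1 mean held-out
#'   MSE), `intercept`.
#' @export
ridge_fit_cv <- function(problem,
                         lambda = 10^seq(-2, 5, length.out = 36),
                         n_folds = 5) {
  X <- problem$X; y <- problem$y
  n <- nrow(X); p <- ncol(X)
  I0 <- diag(p); I0[1, 1] <- 0 # do not regularize the intercept
  fold_id <- rep(seq_len(n_folds), each = ceiling(n / n_folds))[seq_len(n)]
  mse <- matrix(NA_real_, length(lambda), n_folds)
  for (f in seq_len(n_folds)) {
    tr <- fold_id != f
    Xt <- X[tr, , drop = FALSE]; yt <- y[tr]
    Xv <- X[!tr, , drop = FALSE]; yv <- y[!tr]
    XtX <- crossprod(Xt); Xty <- crossprod(Xt, yt)
    for (l in seq_along(lambda)) {
      b <- tryCatch(solve(XtX + lambda[l] * I0, Xty),
                    error = function(e) NULL)
      if (is.null(b)) next
      mse[l, f] <- mean((Xv %*% b - yv)^2)
    }
  }
  cv_mse <- rowMeans(mse)
  l_star <- which.min(cv_mse)
  XtX <- crossprod(X); Xty <- crossprod(X, y)
  b <- solve(XtX + lambda[l_star] * I0, Xty)
  coef <- drop(b) / problem$scales
  names(coef) <- colnames(X)
  structure(list(coef = coef, blocks = problem$blocks,
                 lambda = lambda[l_star], lambda_grid = lambda,
                 cv_mse = cv_mse, intercept = coef[1]),
            class = "vc_ridge_fit")
}

#' Extract a coefficient block from a ridge fit
#'
#' @param fit a [ridge_fit_cv()] result.
#' @param block block label (e.g. `"stim"`, `"C2"`, `"Mbody"`, `"L"`).
#' @param minus_block optional block subtracted coefficient-wise (e.g. the
#'   no-change block `"C1"`, reporting change coefficients corrected by
#'   the 1-Hz trials).
#' @return named numeric vector of unscaled coefficients.
#' @export
ridge_block <- function(fit, block, minus_block = NULL) {
  out <- fit$coef[fit$blocks == block]
  if (!is.null(minus_block)) {
    out <- out - fit$coef[fit$blocks == minus_block]
  }
  out
}
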