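# Lagged/interaction regression, multiexponential fits, binned responses
# and ridge deconvolution on planted-model fixtures.

# shared fixture: fluorescence = known kernel * stimulus at SNR ~ 5
make_planted <- function(n_samples = 20000, fs = 20, snr = 5, seed = 101,
                         gain_block = NULL) {
  set.seed(seed)
  stim <- rnorm(n_samples, 0, 0.25)
  kern_lags <- 0:(2 * fs)
  kern <- 1.5 * (1 - exp(-kern_lags / (0.15 * fs)))^1 * exp(-kern_lags / (0.6 * fs))
  kern[1] <- 0
  block <- rep(c("early", "late"), each = n_samples / 2)
  g <- if (is.null(gain_block)) rep(1, n_samples) else
    ifelse(block == "early", gain_block[1], gain_block[2])
  drive <- vischange:::conv_causal(stim * g, kern)
  noise_sd <- sd(drive) / snr
  trace <- drive + rnorm(n_samples, 0, noise_sd)
  list(stim = stim, trace = trace, kern = kern, fs = fs, block = block,
       lag_s = kern_lags / fs)
}

test_that("lagged regression recovers a planted kernel and zeroes lag 0", {
  fx <- make_planted()
  prof <- lagged_regression(fx$trace, fx$stim, fs = fx$fs,
                            lags = seq(0, 2, by = 0.05))
  expect_equal(prof$slope[prof$lag == 0], 0)
  expect_equal(prof$lo[prof$lag == 0], 0)
  # slope profile ~ kernel (both on the frame grid)
  est <- prof$slope[match(round(fx$lag_s, 10), round(prof$lag, 10))]
  rmse <- sqrt(mean((est - fx$kern)^2, na.rm = TRUE))
  expect_lt(rmse, 0.10 * max(abs(fx$kern)))
  # the kernel peak region is flagged significant
  pk <- which.max(fx$kern)
  expect_true(prof$significant[pk])
})

test_that("null stimulus-independent fluorescence yields ~95% covering CIs", {
  set.seed(55)
  n <- 20000; fs <- 20
  stim <- rnorm(n, 0, 0.25)
  trace <- as.numeric(arima.sim(list(ar = 0.8), n)) * 0.3
  prof <- lagged_regression(trace, stim, fs = fs, lags = seq(0, 2, 0.05))
  nz <- prof[prof$lag > 0, ]
  frac_cover <- mean(nz$lo <= 0 & 0 <= nz$hi)
  expect_gt(frac_cover, 0.85)
})

test_that("masked pairs are excluded and sparse lags are masked", {
  fx <- make_planted(n_samples = 2000)
  valid <- rep(TRUE, 2000)
  valid[500:2000] <- FALSE
  prof <- lagged_regression(fx$trace, fx$stim, valid = valid, fs = fx$fs,
                            lags = c(0, 0.5))
  expect_true(all(prof$n <= 500))
  barely <- lagged_regression(fx$trace, fx$stim,
                              valid = c(rep(TRUE, 5), rep(FALSE, 1995)),
                              fs = fx$fs, lags = 0.5)
  expect_true(is.na(barely$slope))
})

test_that("interaction regression detects a planted block gain difference", {
  # identical gains: interaction coefficients cover zero almost everywhere
  fx0 <- make_planted(seed = 61)
  p0 <- interaction_regression(fx0$trace, fx0$stim, fx0$block, fs = fx0$fs,
                               lags = seq(0, 2, 0.05))
  nz <- p0[p0$lag > 0, ]
  expect_gt(mean(nz$d_lo <= 0 & 0 <= nz$d_hi), 0.85)

  # planted gain ratio 1.5: interaction at the kernel peak matches the
  # slope difference implied by the generator
  fx1 <- make_planted(seed = 62, gain_block = c(1.5, 1))
  p1 <- interaction_regression(fx1$trace, fx1$stim, fx1$block, fs = fx1$fs,
                               lags = seq(0, 2, 0.05))
  pk <- which.max(fx1$kern)
  truth <- 0.5 * fx1$kern[pk] # early gain 1.5 minus late gain 1
  row <- p1[match(round(fx1$lag_s[pk], 10), round(p1$lag, 10)), ]
  expect_true(row$d_lo <= truth && truth <= row$d_hi)
  expect_true(row$significant)

  expect_error(interaction_regression(fx1$trace, fx1$stim,
                                      rep("early", 20000), fs = 20),
               "single block")
})

test_that("multiexponential fit recovers noiseless parameters within 1%", {
  lag <- seq(0, 2, by = 0.05)
  truth <- list(b_max = 1, z = 1, tau_r = 0.1, tau_d = 1)
  b <- truth$b_max * (1 - exp(-lag / truth$tau_r))^truth$z *
    exp(-lag / truth$tau_d)
  fit <- multiexp_fit(lag, b)
  expect_lt(abs(fit$b_max - 1), 0.01)
  expect_lt(abs(fit$z - 1), 0.01)
  expect_lt(abs(fit$tau_r - 0.1), 0.001)
  expect_lt(abs(fit$tau_d - 1), 0.01)

  # latency and half-decay against a 1-ms dense-grid scan of the true curve
  grid <- seq(0, 4, by = 1e-3)
  truef <- (1 - exp(-grid / 0.1)) * exp(-grid)
  mx <- max(abs(truef))
  lat_oracle <- grid[which(abs(truef) >= 0.5 * mx)[1]]
  i_max <- which.max(abs(truef))
  hd_oracle <- grid[which(seq_along(grid) > i_max &
                            abs(truef) < 0.5 * mx)[1]] - grid[i_max]
  expect_lt(abs(fit$latency - lat_oracle), 2e-3)
  expect_lt(abs(fit$half_decay - hd_oracle), 2e-3)

  # pure rise: no decay within the 4-s window -> not determined
  b_rise <- (1 - exp(-lag / 0.3))
  fit_rise <- multiexp_fit(lag, b_rise)
  expect_true(is.na(fit_rise$half_decay))

  # sign symmetry via the maximum-absolute-value rule
  fit_neg <- multiexp_fit(lag, -b)
  expect_lt(abs(fit_neg$latency - lat_oracle), 2e-3)
  expect_lt(abs(fit_neg$b_max + 1), 0.05)
})

test_that("binned responses separate linear and rectified systems", {
  # linear system: fast and slow deviations are symmetric
  fx <- make_planted(seed = 71)
  br <- binned_response(fx$trace, fx$stim, fs = fx$fs, window = c(-0.2, 2))
  pk <- which.min(abs(br$lag - fx$lag_s[which.max(fx$kern)]))
  sym_err <- abs(br$fast$mean[pk] + br$slow$mean[pk])
  expect_lt(sym_err, 3 * (br$fast$hi[pk] - br$fast$mean[pk]))

  # Gaussian occupancies: ~6.7% per tail, ~38.3% middle
  expect_lt(abs(br$occupancy["fast"] / 20000 - 0.0668), 0.01)
  expect_lt(abs(br$occupancy["slow"] / 20000 - 0.0668), 0.01)
  expect_lt(abs(br$occupancy["ref"] / 20000 - 0.3829), 0.015)

  # rectified system: response only to fast samples
  set.seed(72)
  stim <- rnorm(20000, 0, 0.25)
  kern <- fx$kern
  drive <- vischange:::conv_causal(pmax(stim - 1.5 * 0.25, 0), kern) * 4
  trace <- drive + rnorm(20000, 0, sd(drive[drive != 0]) / 3 + 0.05)
  brr <- binned_response(trace, stim, fs = fx$fs, window = c(-0.2, 2))
  pk2 <- which.min(abs(brr$lag - fx$lag_s[which.max(kern)]))
  expect_true(brr$significant[pk2])
  expect_gt(brr$fast$mean[pk2], 0)
  expect_true(brr$slow$lo[pk2] <= 0 & 0 <= brr$slow$hi[pk2])

  expect_error(binned_response(fx$trace, rep(0, 20000), fs = fx$fs),
               "empty")
})

test_that("ridge matches OLS at tiny penalty and shrinks at huge penalty", {
  set.seed(81)
  n <- 600
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1.5 + 2 * x1 - x2 + rnorm(n, 0, 0.3)
  X <- cbind(const = 1, x1 = x1, x2 = x2)
  prob <- structure(list(X = X, y = y, scales = c(1, 1, 1),
                         blocks = c("const", "x1", "x2"),
                         valid_rows = 1:n, mode = "baseline"),
                    class = "vc_ridge_problem")
  fit <- ridge_fit_cv(prob, lambda = c(1e-8, 1e8), n_folds = 5)
  if (fit$lambda == 1e-8) {
    expect_equal(unname(fit$coef), unname(coef(lm(y ~ x1 + x2))),
                 tolerance = 1e-6)
  }
  # heavy shrinkage limit on pure noise
  y0 <- rnorm(n, 3, 1)
  prob0 <- prob; prob0$y <- y0
  fit0 <- ridge_fit_cv(prob0, lambda = 1e8, n_folds = 5)
  expect_lt(max(abs(fit0$coef[-1])), 1e-3)
  expect_equal(unname(fit0$coef[1]), mean(y0), tolerance = 1e-2)
})

test_that("intercept is unpenalized: shifting the response moves only it", {
  fx <- make_planted(n_samples = 4000)
  prob <- build_design(fx$trace, stim = fx$stim, fs = fx$fs)
  lam <- 10^seq(-2, 5, length.out = 36)
  f1 <- ridge_fit_cv(prob, lambda = lam)
  prob_k <- prob; prob_k$y <- prob$y + 7
  f2 <- ridge_fit_cv(prob_k, lambda = f1$lambda) # same penalty
  expect_equal(unname(f2$coef[1] - f1$coef[1]), 7, tolerance = 1e-6)
  expect_equal(unname(f2$coef[-1]), unname(f1$coef[-1]), tolerance = 1e-6)
  # the reported penalty attains the grid minimum
  expect_equal(f1$cv_mse[which(lam == f1$lambda)], min(f1$cv_mse))
})

test_that("ridge recovers planted stimulus coefficients under a movement confound", {
  set.seed(91)
  n <- 20000; fs <- 20
  stim <- rnorm(n, 0, 0.25)
  movement <- as.numeric(arima.sim(list(ar = 0.9), n)) * 0.2 +
    0.3 * vischange:::conv_causal(stim, rep(1 / 5, 5)) # stimulus-correlated
  kern_lags <- 0:(2 * fs)
  kern <- 1.2 * (1 - exp(-kern_lags / 3))^1 * exp(-kern_lags / 12)
  kern[1] <- 0
  mker <- 0.8 * exp(-(0:10) / 4)
  drive <- vischange:::conv_causal(stim, kern) +
    vischange:::conv_causal(movement, mker)
  trace <- drive + rnorm(n, 0, sd(drive) / 5)
  prob <- build_design(trace, stim = stim, movement = list(body = movement),
                       fs = fs)
  fit <- ridge_fit_cv(prob)
  b_stim <- ridge_block(fit, "stim")
  pk <- which.max(kern)
  expect_lt(abs(b_stim[pk] - kern[pk]), 0.15 * kern[pk])
  rmse <- sqrt(mean((b_stim - kern)^2))
  expect_lt(rmse, 0.15 * max(kern))

  # residual re-analysis: movement-only model, then lagged regression of
  # residuals on the stimulus recovers the same kernel shape
  prob_m <- build_design(trace, stim = NULL, movement = list(body = movement),
                         fs = fs)
  fit_m <- ridge_fit_cv(prob_m)
  resid <- prob_m$y - drop(prob_m$X %*% (fit_m$coef * prob_m$scales))
  prof <- lagged_regression(resid, stim, fs = fs, lags = seq(0, 2, 0.05))
  est <- prof$slope[match(round(kern_lags / fs, 10), round(prof$lag, 10))]
  r <- cor(est, kern, use = "complete.obs")
  expect_gt(r, 0.9)
})

test_that("design matrix columns follow the stated windows", {
  # 3-frame toy, hand enumeration of column counts
  fs <- 25
  tr <- rnorm(100)
  prob <- build_design(tr, stim = rnorm(100),
                       movement = list(body = rnorm(100)),
                       lick_frames = c(10, 50), fs = fs)
  blocks <- table(prob$blocks)
  expect_equal(unname(blocks["const"]), 1L)
  expect_equal(unname(blocks["stim"]), 2L * fs + 1L)       # 0..2 s
  expect_equal(unname(blocks["Mbody"]), 13L + 50L + 1L)    # -0.52..2 s
  expect_equal(unname(blocks["L"]), 13L + 17L + 1L)        # -0.52..0.68 s
  # constant column present and unscaled
  expect_equal(unname(prob$scales[1]), 1)
  expect_true(all(prob$X[, 1] == 1))

  # change mode: categorical blocks per magnitude; empty events all zero
  prob_c <- build_design(tr, movement = list(body = rnorm(100)),
                         change_onsets = list(`1` = integer(0), `2` = c(20)),
                         fs = fs, mode = "change")
  expect_true(all(prob_c$X[, prob_c$blocks == "C1"] == 0))
  expect_equal(sum(prob_c$X[, prob_c$blocks == "C2"] != 0), 2L * fs + 1L)

  expect_error(build_design(tr, mode = "change"), "movement")
})

test_that("time-course comparison behaves under resampling", {
  lag_f <- seq(0, 2, by = 0.01)
  curve <- (1 - exp(-lag_f / 0.2)) * exp(-lag_f / 0.8)
  expect_equal(compare_timecourses(lag_f, curve, lag_f, curve), 1)
  expect_equal(compare_timecourses(lag_f, curve, lag_f, -curve), -1)
  lag_c <- seq(0, 2, by = 0.08)
  coarse <- (1 - exp(-lag_c / 0.2)) * exp(-lag_c / 0.8)
  expect_gt(compare_timecourses(lag_f, curve, lag_c, coarse), 0.99)
  expect_error(compare_timecourses(lag_f, curve, lag_f, curve,
                                   window = c(5, 6)), "window")
})
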