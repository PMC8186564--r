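# Prediction from the fitted hazard GP: per-sample latent posterior and
# hazard, stimulus/time decomposition of the log-odds, trial outcome
# probabilities, predictive log-likelihood, and behavior replicates.

#' Predict the momentary lick hazard for trials
#'
#' Uses the sparse predictive equations with the filter bank fixed at its
#' posterior mean. The latent mean decomposes exactly into
#' `m0 + mu_s + mu_t` (constant mean plus stimulus- and time-dependent
#' log-odds). The hazard is the Monte Carlo expectation of the logistic
#' latent over `mc` posterior draws (drawing inducing values, conditional
#' means, and independent per-sample conditional noise); trial outcome
#' probabilities average exact enumeration of the first-lick distribution
#' over the same draws.
#'
#' @param model a fitted `vc_gp_model`.
#' @param trials list of trials (or one trial).
#' @param mc Monte Carlo draws.
#' @param seed integer seed.
#' @return list with `samples` (data frame: trial, t, latent mean/var,
#'   `mu_s`, `mu_t`, hazard) and `outcomes` (per trial: probability of
#'   early, refractory, hit, miss).
#' @export
predict_hazard <- function(model, trials, mc = model$cfg$mc_eval, seed = 1) {
  if (inherits(trials, "vc_trial")) trials <- list(trials)
  data <- discretize_trials(trials, model$task_cfg, model$cfg$Q)
  if (max(data$t) > max(model$Z_t) + 2) {
    warning("trial extends beyond the trained time range; extrapolating")
  }
  pr <- gp_latent_raw(model$par, model_static(model, data), data$S, data$t,
                      data$block, parts = TRUE)
  v_cond <- pmax(pr$var - rowSums(pr$AL^2), 1e-12) # given u, diag only
  set.seed(seed)
  N <- length(pr$mean)
  M <- length(model$par$mu_u)
  L <- lower_from_raw(model$par$L_raw)
  hsum <- numeric(N)
  cfg_t <- model$task_cfg
  dt <- cfg_t$sample_period
  out_lab <- c("early", "refractory", "hit", "miss")
  out_acc <- matrix(0, data$n_trials, 4, dimnames = list(NULL, out_lab))
  trial_rows <- split(seq_len(N), data$trial)
  change_s <- vapply(trials, function(tr) {
    cs <- tr$stimulus$change_sample
    if (is.na(cs)) Inf else as.numeric(cs)
  }, 0)
  for (r in seq_len(mc)) {
    eps_u <- stats::rnorm(M)
    f <- pr$mean + drop(pr$AL %*% eps_u) +
      sqrt(v_cond) * stats::rnorm(N)
    h <- clip_unit(stats::plogis(f))
    hsum <- hsum + h
    for (tr_i in seq_along(trial_rows)) {
      rows <- trial_rows[[tr_i]]
      ht <- h[rows]
      surv <- cumprod(1 - ht)
      p_first <- ht * c(1, utils::head(surv, -1))
      # classify each first-lick sample relative to the change
      k <- seq_along(rows)
      lick_t <- k * dt
      change_t <- (change_s[tr_i] - 1) * dt
      lab <- ifelse(lick_t < change_t, "early",
              ifelse(lick_t - change_t <= cfg_t$refractory, "refractory",
               ifelse(lick_t - change_t <= cfg_t$miss_deadline, "hit",
                      "miss")))
      for (lb in out_lab) {
        out_acc[tr_i, lb] <- out_acc[tr_i, lb] + sum(p_first[lab == lb])
      }
      out_acc[tr_i, "miss"] <- out_acc[tr_i, "miss"] + surv[length(surv)]
    }
  }
  hazard <- hsum / mc
  samples <- data.frame(trial = data$trial, t = data$t,
                        latent_mean = pr$mean, latent_var = pr$var,
                        m0 = model$par$m0, mu_s = pr$mean_s,
                        mu_t = pr$mean_t, hazard = hazard)
  list(samples = samples, outcomes = out_acc / mc)
}

#' Closed-form trial log-likelihood of a hazard sequence
#'
#' `log p(y)` for a trial under given per-sample hazards: the product of
#' conditional Bernoulli terms, i.e. survival through every sample except
#' a terminal lick.
#'
#' @param hazard per-sample hazard.
#' @param lick_sample index of the lick sample, or NA for a no-lick trial.
#' @return log-likelihood.
#' @export
hazard_trial_loglik <- function(hazard, lick_sample = NA) {
  h <- clip_unit(hazard)
  if (is.na(lick_sample)) return(sum(log1p(-h)))
  stopifnot(lick_sample >= 1, lick_sample <= length(h))
  sum(log1p(-h[seq_len(lick_sample - 1)])) + log(h[lick_sample])
}

#' Average predictive log-likelihood of trials
#'
#' Estimates `log p(y | X)` per trial as the log of the Monte Carlo mean
#' of the trial likelihood over posterior draws of the latent function,
#' averaged across trials.
#'
#' @param model a fitted `vc_gp_model`.
#' @param trials list of trials.
#' @param mc Monte Carlo draws.
#' @param seed integer seed.
#' @return mean per-trial predictive log-likelihood (nats).
#' @export
predictive_loglik <- function(model, trials, mc = 100, seed = 1) {
  data <- discretize_trials(trials, model$task_cfg, model$cfg$Q)
  pr <- gp_latent_raw(model$par, model_static(model, data), data$S, data$t,
                      data$block)
  v_cond <- pmax(pr$var - rowSums(pr$AL^2), 1e-12)
  set.seed(seed)
  N <- length(pr$mean)
  M <- length(model$par$mu_u)
  trial_rows <- split(seq_len(N), data$trial)
  ll_draws <- matrix(0, data$n_trials, mc)
  for (r in seq_len(mc)) {
    f <- pr$mean + drop(pr$AL %*% stats::rnorm(M)) +
      sqrt(v_cond) * stats::rnorm(N)
    h <- clip_unit(stats::plogis(f))
    lls <- ifelse(data$y == 1, log(h), log1p(-h))
    ll_draws[, r] <- vapply(trial_rows, function(rows) sum(lls[rows]), 0)
  }
  # log-mean-exp across draws, per trial
  mx <- apply(ll_draws, 1, max)
  mean(mx + log(rowMeans(exp(ll_draws - mx))))
}

#' Sample behavior replicates from the fitted model
#'
#' For each replicate, licks are drawn per trial from the predictive
#' hazard (a fresh posterior draw per trial) and outcomes classified with
#' the task rules; psychometric and chronometric summaries and the early
#' lick-time density are computed per replicate, and 2.5/50/97.5%
#' quantile bands across replicates are returned.
#'
#' @param model a fitted `vc_gp_model`.
#' @param trials list of trials to replicate.
#' @param n_rep number of replicates.
#' @param seed integer seed.
#' @param lick_breaks histogram breaks (s) for the early lick-time
#'   density.
#' @param censor_incomplete treat a no-lick replicate of a trial whose
#'   recorded trace ends before the miss deadline (because the subject
#'   licked first) as unclassifiable rather than a miss. Full-length
#'   trials are unaffected.
#' @return list with `psychometric` (per magnitude: median and band of
#'   the replicate hit rate), `chronometric` (median RT bands),
#'   `lick_density` (per bin bands), and the per-replicate `hit_rates`
#'   matrix.
#' @export
sample_replicates <- function(model, trials, n_rep = model$cfg$n_replicates,
                              seed = 1, lick_breaks = seq(0, 16, 0.5),
                              censor_incomplete = TRUE) {
  data <- discretize_trials(trials, model$task_cfg, model$cfg$Q)
  pr <- gp_latent_raw(model$par, model_static(model, data), data$S, data$t,
                      data$block)
  v_cond <- pmax(pr$var - rowSums(pr$AL^2), 1e-12)
  sd_cond <- sqrt(v_cond)
  cfg_t <- model$task_cfg
  dt <- cfg_t$sample_period
  N <- length(pr$mean)
  M <- length(model$par$mu_u)
  trial_rows <- split(seq_len(N), data$trial)
  mags <- vapply(trials, `[[`, 0, "change_magnitude")
  change_t <- vapply(trials, `[[`, 0, "change_time")
  umags <- sort(unique(mags))
  hit_rates <- matrix(NA_real_, n_rep, length(umags),
                      dimnames = list(NULL, umags))
  med_rt <- matrix(NA_real_, n_rep, length(umags),
                   dimnames = list(NULL, umags))
  dens <- matrix(0, n_rep, length(lick_breaks) - 1)
  set.seed(seed)
  for (r in seq_len(n_rep)) {
    f <- pr$mean + drop(pr$AL %*% stats::rnorm(M)) +
      sd_cond * stats::rnorm(N)
    h <- clip_unit(stats::plogis(f))
    u <- stats::runif(N)
    lick_time <- rep(NA_real_, length(trials))
    outc <- character(length(trials))
    rt <- rep(NA_real_, length(trials))
    for (tr_i in seq_along(trial_rows)) {
      rows <- trial_rows[[tr_i]]
      first <- which(u[rows] < h[rows])
      licks <- if (length(first)) first[1] * dt else numeric(0)
      if (!length(licks) && censor_incomplete &&
          length(rows) * dt < change_t[tr_i] + cfg_t$miss_deadline - dt) {
        outc[tr_i] <- "censored"
        next
      }
      cl <- classify_outcome(licks, change_t[tr_i], cfg_t)
      outc[tr_i] <- cl$outcome
      rt[tr_i] <- cl$reaction_time
      if (length(licks) && licks < change_t[tr_i]) lick_time[tr_i] <- licks
    }
    for (mi in seq_along(umags)) {
      sel <- mags == umags[mi] & outc %in% c("hit", "miss")
      if (any(sel)) hit_rates[r, mi] <- mean(outc[sel] == "hit")
      hit_sel <- mags == umags[mi] & outc == "hit"
      if (any(hit_sel)) med_rt[r, mi] <- stats::median(rt[hit_sel])
    }
    lt <- lick_time[!is.na(lick_time)]
    if (length(lt)) {
      dens[r, ] <- graphics::hist(lt, breaks = lick_breaks,
                                  plot = FALSE)$density
    }
  }
  band <- function(Mx) {
    apply(Mx, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
          na.rm = TRUE)
  }
  list(psychometric = band(hit_rates), chronometric = band(med_rt),
       lick_density = band(dens), lick_breaks = lick_breaks,
       hit_rates = hit_rates, median_rts = med_rt)
}
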