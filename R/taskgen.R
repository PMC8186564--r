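#' Configuration of the change-detection task generator
#'
#' Collects the generative constants of the task: the stimulus is a drifting
#' grating whose log2 temporal frequency (TF) is redrawn every 50 ms from a
#' normal distribution in octaves (so TF itself is lognormal with geometric
#' mean 1 Hz), 70% of trials carry this noise, and after a block-dependent
#' delay the mean TF steps up to the change magnitude. Change times are an
#' offset (3 s in early blocks, 10.5 s in late blocks for 90% of trials,
#' swapped for the remaining 10%) plus an exponential draw with mean 4 s
#' truncated at 5 s. Licks within the first 150 ms of a change are refractory
#' and trials with no qualifying lick within 2.15 s of the change are misses.
#'
#' @param sample_period stimulus update period, seconds.
#' @param baseline_log2tf_mean baseline mean of log2 TF, octaves.
#' @param noise_sd SD of log2 TF fluctuations, octaves.
#' @param noise_trial_fraction fraction of trials with TF noise.
#' @param change_magnitudes change magnitudes in Hz; 1 means no change.
#' @param block_offsets named vector of change-time offsets (seconds) for
#'   the `early` and `late` blocks.
#' @param change_exp_mean mean of the exponential change-time component, s.
#' @param change_trunc truncation point of the exponential component, s.
#' @param majority_fraction probability a trial uses its block's primary
#'   offset rather than the opposite block's offset.
#' @param prestim_min minimum pre-stimulus delay, s.
#' @param prestim_exp_mean mean of the exponential part of the delay, s.
#' @param refractory refractory period after the change, s.
#' @param miss_deadline response deadline after the change, s.
#' @param wheel_abort_mm wheel displacement (mm per sample) aborting a trial.
#' @param simulate_wheel logical; simulate wheel movement (off by default,
#'   emulating a stationary mouse).
#' @return a `vc_task_config` list.
#' @export
task_config <- function(sample_period = 0.05,
                        baseline_log2tf_mean = 0,
                        noise_sd = 0.25,
                        noise_trial_fraction = 0.7,
                        change_magnitudes = c(1, 1.25, 1.35, 1.5, 2, 4),
                        block_offsets = c(early = 3, late = 10.5),
                        change_exp_mean = 4,
                        change_trunc = 5,
                        majority_fraction = 0.9,
                        prestim_min = 3,
                        prestim_exp_mean = 0.5,
                        refractory = 0.15,
                        miss_deadline = 2.15,
                        wheel_abort_mm = 2.5,
                        simulate_wheel = FALSE) {
  stopifnot(
    sample_period > 0, noise_sd >= 0,
    noise_trial_fraction >= 0, noise_trial_fraction <= 1,
    all(change_magnitudes > 0),
    all(c("early", "late") %in% names(block_offsets)),
    change_exp_mean > 0, change_trunc > 0,
    majority_fraction >= 0, majority_fraction <= 1,
    prestim_min > 0, prestim_exp_mean > 0,
    refractory > 0, miss_deadline > refractory,
    wheel_abort_mm > 0
  )
  structure(as.list(environment()), class = "vc_task_config")
}

#' Generate a baseline stimulus trace
#'
#' On noisy trials each 50-ms sample of log2 TF is an independent normal
#' draw around the baseline mean; on no-noise trials the trace is constant.
#'
#' @param n_samples number of stimulus samples (>= 1).
#' @param cfg a [task_config()].
#' @param seed optional integer seed.
#' @param noisy logical; draw noise (TRUE) or hold TF constant.
#' @return a `vc_stimulus` list with fields `log2tf`, `change_sample`
#'   (NA for a pure baseline trace), `change_log2tf`, `noisy`.
#' @export
gen_baseline_stimulus <- function(n_samples, cfg = task_config(), seed = NULL,
                                  noisy = TRUE) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 1) {
    stop("n_samples must be a positive count")
  }
  n_samples <- as.integer(n_samples)
  if (!is.null(seed)) set.seed(seed)
  log2tf <- if (noisy && cfg$noise_sd > 0) {
    stats::rnorm(n_samples, cfg$baseline_log2tf_mean, cfg$noise_sd)
  } else {
    rep(cfg$baseline_log2tf_mean, n_samples)
  }
  structure(list(log2tf = log2tf, change_sample = NA_integer_,
                 change_log2tf = NA_real_, noisy = noisy),
            class = "vc_stimulus")
}

#' Draw stimulus change times
#'
#' With probability `majority_fraction` the offset of the trial's own block
#' is used, otherwise the opposite block's offset; a truncated-exponential
#' component (rejection sampling, so no atom at the truncation point) is
#' added. Early-block draws therefore fall in \[3, 8\] s about 90% of the
#' time and in \[10.5, 15.5\] s otherwise.
#'
#' @param block `"early"` or `"late"`.
#' @param cfg a [task_config()].
#' @param seed optional integer seed.
#' @param n number of draws.
#' @return change times in seconds after stimulus onset.
#' @export
gen_change_time <- function(block, cfg = task_config(), seed = NULL, n = 1) {
  block <- match.arg(block, c("early", "late"))
  if (!is.null(seed)) set.seed(seed)
  other <- setdiff(c("early", "late"), block)
  primary <- unname(cfg$block_offsets[block])
  alt <- unname(cfg$block_offsets[other])
  offs <- ifelse(stats::runif(n) < cfg$majority_fraction, primary, alt)
  offs + rtrunc_exp(n, cfg$change_exp_mean, cfg$change_trunc)
}

# truncated exponential by rejection (redraw, not cap)
#' @keywords internal
rtrunc_exp <- function(n, mean, trunc) {
  out <- stats::rexp(n, rate = 1 / mean)
  bad <- which(out > trunc)
  while (length(bad)) {
    out[bad] <- stats::rexp(length(bad), rate = 1 / mean)
    bad <- bad[out[bad] > trunc]
  }
  out
}

#' Define a synthetic lick agent
#'
#' The agent licks with a per-sample hazard equal to the logistic function of
#' an additive log-odds: a bias, stimulus-filter outputs (each filter is a
#' vector of weights per octave over recent stimulus history, most recent
#' sample first), and a time gain. This mirrors the additivity assumed by the
#' hazard model and serves as ground truth in recovery tests.
#'
#' @param filters numeric matrix, history length x K (weights per octave);
#'   row `q` applies to the stimulus sample `q - 1` steps in the past.
#' @param filter_gains numeric vector of K gains.
#' @param bias log-odds offset.
#' @param time_gain function of trial time (s) returning log-odds, or NULL.
#' @return a `vc_agent` list.
#' @export
synthetic_agent <- function(filters, filter_gains = rep(1, ncol(filters)),
                            bias = -4, time_gain = NULL) {
  filters <- as.matrix(filters)
  stopifnot(length(filter_gains) == ncol(filters), is.finite(bias))
  if (is.null(time_gain)) time_gain <- function(t) rep(0, length(t))
  structure(list(filters = filters, filter_gains = filter_gains,
                 bias = bias, time_gain = time_gain),
            class = "vc_agent")
}

#' Per-sample lick hazard of a synthetic agent
#'
#' Stimulus history is padded with the baseline mean before stimulus onset.
#' The hazard is clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @param agent a [synthetic_agent()].
#' @param log2tf stimulus trace (octaves per sample) or a `vc_stimulus`.
#' @param cfg a [task_config()] (supplies the sample period and baseline mean).
#' @param max_history longest supported filter, samples (2.5 s by default).
#' @return hazard per sample, same length as the stimulus.
#' @export
agent_hazard <- function(agent, log2tf, cfg = task_config(),
                         max_history = 50L) {
  if (inherits(log2tf, "vc_stimulus")) log2tf <- log2tf$log2tf
  n <- length(log2tf)
  Lf <- nrow(agent$filters)
  if (Lf > max_history) stop("filter longer than allowed history")
  padded <- c(rep(cfg$baseline_log2tf_mean, Lf - 1), log2tf)
  # history matrix: row i = samples i, i-1, ..., i-Lf+1
  filt_out <- matrix(0, n, ncol(agent$filters))
  for (k in seq_len(ncol(agent$filters))) {
    w <- agent$filters[, k]
    # convolution: sum_q w[q] * s[i - q + 1]
    filt_out[, k] <- stats::filter(padded, w, method = "convolution",
                                   sides = 1)[Lf - 1 + seq_len(n)]
  }
  t_i <- (seq_len(n) - 1) * cfg$sample_period
  eta <- agent$bias + drop(filt_out %*% agent$filter_gains) +
    agent$time_gain(t_i)
  clip_unit(stats::plogis(eta))
}

#' Classify the outcome of a trial
#'
#' Events are resolved in temporal order: a wheel abort before any lick or
#' change aborts the trial; a lick before the change is an early lick; the
#' first post-change lick within the refractory period (150 ms) is
#' refractory; a first lick inside the response window (0.15, 2.15\] s after
#' the change is a hit with reaction time lick - change; otherwise the trial
#' is a miss at the deadline.
#'
#' @param licks lick times (s, relative to stimulus onset), sorted ascending.
#' @param change_time change time (s, relative to stimulus onset).
#' @param cfg a [task_config()].
#' @param wheel optional per-sample wheel displacement (mm per sample).
#' @return list with `outcome` (one of `hit`, `miss`, `early`, `abort`,
#'   `refractory`) and `reaction_time` (s; NA unless a hit).
#' @export
classify_outcome <- function(licks, change_time, cfg = task_config(),
                             wheel = NULL) {
  if (length(licks) && is.unsorted(licks)) {
    stop("lick times must be sorted ascending")
  }
  if (!is.finite(change_time) || change_time < 0) {
    stop("change_time must be a non-negative number")
  }
  first_lick <- if (length(licks)) licks[1] else Inf
  abort_time <- Inf
  if (!is.null(wheel) && length(wheel)) {
    hit_idx <- which(abs(wheel) > cfg$wheel_abort_mm)
    if (length(hit_idx)) abort_time <- (hit_idx[1] - 1) * cfg$sample_period
  }
  if (abort_time < min(first_lick, change_time)) {
    return(list(outcome = "abort", reaction_time = NA_real_))
  }
  if (first_lick < change_time) {
    return(list(outcome = "early", reaction_time = NA_real_))
  }
  post <- licks[licks >= change_time]
  if (length(post)) {
    dt <- post[1] - change_time
    if (dt <= cfg$refractory) {
      return(list(outcome = "refractory", reaction_time = NA_real_))
    }
    if (dt <= cfg$miss_deadline) {
      return(list(outcome = "hit", reaction_time = dt))
    }
  }
  list(outcome = "miss", reaction_time = NA_real_)
}

#' Generate a synthetic session of the change-detection task
#'
#' Each trial draws a pre-stimulus delay (3 s + exponential with mean
#' 0.5 s), a noisy/no-noise label, a change magnitude, and a block-dependent
#' change time snapped up to the 50-ms stimulus grid. If an agent is given,
#' licks are sampled per 50-ms Bernoulli hazard and the trial ends at the
#' first terminating event; without an agent no licks occur and noisy-change
#' trials end as misses. Trial `i` is reproducible independent of
#' `n_trials` via counter-based substreams of `seed`.
#'
#' @param n_trials number of trials (>= 1).
#' @param block_schedule character vector of block labels, recycled.
#' @param agent a [synthetic_agent()] or NULL (passive observer).
#' @param cfg a [task_config()].
#' @param seed master seed.
#' @param magnitude_probs sampling weights over `cfg$change_magnitudes`
#'   (uniform by default).
#' @return list of `vc_trial` objects with fields `stimulus`, `block`,
#'   `prestim_delay`, `change_time`, `change_magnitude`, `lick_times`,
#'   `wheel`, `outcome`, `reaction_time`.
#' @export
gen_session <- function(n_trials, block_schedule = "early", agent = NULL,
                        cfg = task_config(), seed = 1,
                        magnitude_probs = NULL) {
  stopifnot(n_trials >= 1)
  blocks <- rep_len(block_schedule, n_trials)
  dt <- cfg$sample_period
  probs <- magnitude_probs %||%
    rep(1 / length(cfg$change_magnitudes), length(cfg$change_magnitudes))
  lapply(seq_len(n_trials), function(i) {
    set.seed(substream_seed(seed, i))
    prestim <- cfg$prestim_min + stats::rexp(1, 1 / cfg$prestim_exp_mean)
    noisy <- stats::runif(1) < cfg$noise_trial_fraction
    mag <- cfg$change_magnitudes[sample.int(length(cfg$change_magnitudes),
                                            1, prob = probs)]
    raw_ct <- gen_change_time(blocks[i], cfg)
    change_sample <- as.integer(ceiling(raw_ct / dt)) + 1L
    change_time <- (change_sample - 1L) * dt
    n_total <- change_sample - 1L + as.integer(ceiling(cfg$miss_deadline / dt))
    sd_use <- if (noisy) cfg$noise_sd else 0
    log2tf <- c(
      stats::rnorm(change_sample - 1L, cfg$baseline_log2tf_mean, sd_use),
      stats::rnorm(n_total - change_sample + 1L,
                   cfg$baseline_log2tf_mean + log2(mag), sd_use)
    )
    wheel <- if (cfg$simulate_wheel) {
      stats::rnorm(n_total, 0, cfg$wheel_abort_mm / 4)
    } else {
      rep(0, n_total)
    }
    licks <- numeric(0)
    if (!is.null(agent)) {
      hz <- agent_hazard(agent, log2tf, cfg)
      u <- stats::runif(n_total)
      hit_idx <- which(u < hz)
      if (length(hit_idx)) licks <- hit_idx[1] * dt
    }
    out <- classify_outcome(licks, change_time, cfg, wheel)
    # trial ends at the first terminating event
    end_time <- switch(out$outcome,
      hit = ,
      early = ,
      refractory = licks[1],
      abort = change_time, # conservative: keep pre-change trace
      miss = change_time + cfg$miss_deadline
    )
    keep <- min(n_total, as.integer(ceiling(end_time / dt)))
    stim <- structure(list(
      log2tf = log2tf[seq_len(keep)],
      change_sample = if (change_sample <= keep) change_sample else NA_integer_,
      change_log2tf = cfg$baseline_log2tf_mean + log2(mag),
      noisy = noisy
    ), class = "vc_stimulus")
    structure(list(
      stimulus = stim, block = blocks[i], prestim_delay = prestim,
      change_time = change_time, change_magnitude = mag,
      lick_times = licks, wheel = wheel[seq_len(keep)],
      outcome = out$outcome, reaction_time = out$reaction_time
    ), class = "vc_trial")
  })
}

#' Summarize a session as a data frame
#'
#' @param trials list of trials from [gen_session()].
#' @return one row per trial: block, change time/magnitude, noise flag,
#'   outcome, reaction time, first lick time, number of samples.
#' @export
session_table <- function(trials) {
  data.frame(
    trial = seq_along(trials),
    block = vapply(trials, `[[`, "", "block"),
    prestim_delay = vapply(trials, `[[`, 0, "prestim_delay"),
    change_time = vapply(trials, `[[`, 0, "change_time"),
    change_magnitude = vapply(trials, `[[`, 0, "change_magnitude"),
    noisy = vapply(trials, function(tr) tr$stimulus$noisy, NA),
    outcome = vapply(trials, `[[`, "", "outcome"),
    reaction_time = vapply(trials, `[[`, 0, "reaction_time"),
    first_lick = vapply(trials, function(tr) {
      if (length(tr$lick_times)) tr$lick_times[1] else NA_real_
    }, 0),
    n_samples = vapply(trials, function(tr) length(tr$stimulus$log2tf), 0L),
    stringsAsFactors = FALSE
  )
}

#' Write / read trials as delimited text
#'
#' One row per trial; lick times are stored as a semicolon-separated list.
#' Stimulus traces are written alongside as a long-format table keyed by
#' trial and sample.
#'
#' @param trials list of trials.
#' @param dir output directory (created if needed).
#' @return `write_trials` returns `dir` invisibly; `read_trials` the trial
#'   table plus stimulus matrix list.
#' @export
write_trials <- function(trials, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- session_table(trials)
  tab$lick_times <- vapply(trials, function(tr) {
    paste(format(tr$lick_times, trim = TRUE), collapse = ";")
  }, "")
  utils::write.table(tab, file.path(dir, "trials.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  stim <- do.call(rbind, lapply(seq_along(trials), function(i) {
    s <- trials[[i]]$stimulus
    data.frame(trial = i, sample = seq_along(s$log2tf), log2tf = s$log2tf,
               change_sample = s$change_sample)
  }))
  utils::write.table(stim, file.path(dir, "stimulus.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @rdname write_trials
#' @export
read_trials <- function(dir) {
  tab <- utils::read.delim(file.path(dir, "trials.tsv"))
  stim <- utils::read.delim(file.path(dir, "stimulus.tsv"))
  list(trials = tab, stimulus = split(stim$log2tf, stim$trial))
}
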