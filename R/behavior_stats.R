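# Descriptive behavioral statistics: psychometric/chronometric curves,
# discrete hazard rates, lick-triggered averages and stratified splits.

# exact (Clopper-Pearson) binomial CI
#' @keywords internal
binom_ci <- function(x, n, level = 0.95) {
  a <- (1 - level) / 2
  lo <- ifelse(x == 0, 0, stats::qbeta(a, x, n - x + 1))
  hi <- ifelse(x == n, 1, stats::qbeta(1 - a, x + 1, n - x))
  cbind(lo = lo, hi = hi)
}

#' Psychometric curve: hit rate per change magnitude
#'
#' Early, abort and refractory trials are excluded from the denominators;
#' the hit rate per magnitude is hits / (hits + misses) with an exact
#' Clopper-Pearson 95% binomial confidence interval.
#'
#' @param trials list of trials from [gen_session()].
#' @param level confidence level.
#' @return data frame per magnitude: `change_magnitude`, `n_trials`,
#'   `n_hits`, `hit_rate`, `lo`, `hi`.
#' @export
psychometric <- function(trials, level = 0.95) {
  tab <- session_table(trials)
  ok <- tab$outcome %in% c("hit", "miss")
  mags <- sort(unique(tab$change_magnitude))
  rows <- lapply(mags, function(m) {
    sel <- ok & tab$change_magnitude == m
    n <- sum(sel)
    if (n == 0) {
      warning("no eligible trials at magnitude ", m, "; omitted")
      return(NULL)
    }
    x <- sum(tab$outcome[sel] == "hit")
    ci <- binom_ci(x, n, level)
    data.frame(change_magnitude = m, n_trials = n, n_hits = x,
               hit_rate = x / n, lo = ci[1], hi = ci[2])
  })
  do.call(rbind, rows)
}

#' Chronometric curve: median reaction time per change magnitude
#'
#' Hits only. Confidence intervals are the 0.025 and 0.975 quantiles of
#' 2000 bootstrap medians (resampling with replacement), seeded.
#'
#' @param trials list of trials.
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @return data frame per magnitude: `change_magnitude`, `n_hits`,
#'   `median_rt`, `lo`, `hi`, `ci_defined`.
#' @export
chronometric <- function(trials, n_boot = 2000, seed = 1) {
  tab <- session_table(trials)
  hits <- tab[tab$outcome == "hit", ]
  set.seed(seed)
  rows <- lapply(sort(unique(hits$change_magnitude)), function(m) {
    rt <- hits$reaction_time[hits$change_magnitude == m]
    n <- length(rt)
    if (n < 2) {
      return(data.frame(change_magnitude = m, n_hits = n,
                        median_rt = if (n) stats::median(rt) else NA_real_,
                        lo = NA_real_, hi = NA_real_, ci_defined = FALSE))
    }
    boots <- vapply(seq_len(n_boot), function(b) {
      stats::median(rt[sample.int(n, n, replace = TRUE)])
    }, 0)
    q <- stats::quantile(boots, c(0.025, 0.975), names = FALSE)
    data.frame(change_magnitude = m, n_hits = n, median_rt = stats::median(rt),
               lo = q[1], hi = q[2], ci_defined = TRUE)
  })
  do.call(rbind, rows)
}

#' Discrete hazard rate of early licks or stimulus changes
#'
#' Per time bin, the hazard is the number of events in the bin divided by
#' the number of trials still at risk at the bin start (trials where no
#' early lick or change has yet happened and that were not aborted before
#' the bin start), with an exact binomial CI.
#'
#' @param trials list of trials.
#' @param event `"early_lick"` or `"change"`.
#' @param bin bin width, s.
#' @param t_max last bin edge, s (defaults to cover all events).
#' @param level confidence level.
#' @return data frame per bin: `t_lo`, `t_hi`, `events`, `at_risk`,
#'   `hazard`, `lo`, `hi`.
#' @export
hazard_rate <- function(trials, event = c("early_lick", "change"), bin = 1,
                        t_max = NULL, level = 0.95) {
  event <- match.arg(event)
  tab <- session_table(trials)
  # per-trial censoring structure
  early_t <- ifelse(tab$outcome == "early", tab$first_lick, Inf)
  change_t <- ifelse(tab$outcome %in% c("early", "abort"), Inf,
                     tab$change_time)
  abort_t <- ifelse(tab$outcome == "abort", tab$change_time, Inf)
  # a trial leaves the risk set at the first of these
  exit_t <- pmin(early_t, change_t, abort_t)
  ev_t <- switch(event, early_lick = early_t, change = change_t)
  if (is.null(t_max)) {
    fin <- ev_t[is.finite(ev_t)]
    t_max <- if (length(fin)) ceiling(max(fin) / bin) * bin else bin
  }
  edges <- seq(0, t_max, by = bin)
  rows <- lapply(seq_len(length(edges) - 1), function(k) {
    lo <- edges[k]; hi <- edges[k + 1]
    at_risk <- sum(exit_t >= lo)
    events <- sum(ev_t >= lo & ev_t < hi)
    if (at_risk == 0) {
      return(data.frame(t_lo = lo, t_hi = hi, events = 0L, at_risk = 0L,
                        hazard = NA_real_, lo = NA_real_, hi = NA_real_))
    }
    ci <- binom_ci(events, at_risk, level)
    data.frame(t_lo = lo, t_hi = hi, events = events, at_risk = at_risk,
               hazard = events / at_risk, lo = ci[1], hi = ci[2])
  })
  do.call(rbind, rows)
}

#' Lick-triggered average stimulus
#'
#' Averages the log2 TF samples preceding each early lick during the
#' baseline period (a reverse-correlation estimate of the stimulus features
#' driving licks). Histories shorter than `max_lag` are padded with the
#' baseline mean. Confidence intervals are percentile bootstrap over licks.
#'
#' @param trials list of trials.
#' @param max_lag history length, s.
#' @param n_boot bootstrap resamples.
#' @param seed integer seed.
#' @param cfg a [task_config()].
#' @param pad pad short histories with the baseline mean (TRUE) or drop
#'   them (FALSE).
#' @return list with `lag` (s before lick, increasing), `mean`, `lo`, `hi`,
#'   `n_licks`.
#' @export
lick_triggered_average <- function(trials, max_lag = 2.5, n_boot = 2000,
                                   seed = 1, cfg = task_config(), pad = TRUE) {
  dt <- cfg$sample_period
  Q <- round(max_lag / dt)
  wins <- list()
  for (tr in trials) {
    if (tr$outcome != "early") next
    # a lick is assigned to the sample containing it; the epsilon guards
    # against floating-point jitter at sample boundaries
    lick_sample <- ceiling(tr$lick_times[1] / dt - 1e-9)
    idx <- lick_sample - seq_len(Q) # samples at lags dt..max_lag
    s <- tr$stimulus$log2tf
    if (!pad && any(idx < 1)) next
    vals <- ifelse(idx >= 1, s[pmax(idx, 1)], cfg$baseline_log2tf_mean)
    wins[[length(wins) + 1]] <- vals
  }
  if (!length(wins)) stop("no early licks available for the LTA")
  W <- do.call(rbind, wins)
  m <- colMeans(W)
  set.seed(seed)
  n <- nrow(W)
  boots <- matrix(0, n_boot, Q)
  for (b in seq_len(n_boot)) {
    boots[b, ] <- colMeans(W[sample.int(n, n, replace = TRUE), , drop = FALSE])
  }
  qs <- apply(boots, 2, stats::quantile, probs = c(0.025, 0.975))
  list(lag = dt * seq_len(Q), mean = m, lo = qs[1, ], hi = qs[2, ],
       n_licks = n)
}

#' Stratified train/validation/test split
#'
#' Within each stratum (block x change magnitude by default) the training
#' set takes `round(f1 * N)` trials and the remainder is split equally
#' between validation and test, with an odd remainder going to validation.
#' Strata smaller than 3 trials are assigned wholly to training with a
#' warning. For 14,944 trials in one stratum this yields the
#' (8,966, 2,989, 2,989) partition.
#'
#' @param trials list of trials.
#' @param fractions length-3 fractions summing to 1.
#' @param stratify_by columns of [session_table()] to stratify on.
#' @param seed integer seed for the random assignment within strata.
#' @return list of index vectors `train`, `validation`, `test` (disjoint,
#'   exhaustive).
#' @export
split_dataset <- function(trials, fractions = c(0.6, 0.2, 0.2),
                          stratify_by = c("block", "change_magnitude"),
                          seed = 1) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-8)
  tab <- session_table(trials)
  key <- if (is.null(stratify_by)) {
    factor(rep("all", nrow(tab)))
  } else {
    interaction(tab[stratify_by], drop = TRUE)
  }
  set.seed(seed)
  train <- integer(0); val <- integer(0); test <- integer(0)
  for (lev in levels(key)) {
    idx <- which(key == lev)
    ns <- length(idx)
    if (ns < 3 && fractions[1] < 1) {
      warning("stratum ", lev, " has fewer than 3 trials; assigned to training")
      train <- c(train, idx)
      next
    }
    idx <- idx[sample.int(ns)]
    n_tr <- round(fractions[1] * ns)
    rem <- ns - n_tr
    if (fractions[2] + fractions[3] > 0) {
      n_val <- ceiling(rem * fractions[2] / (fractions[2] + fractions[3]))
    } else {
      n_val <- 0
      n_tr <- ns
      rem <- 0
    }
    train <- c(train, idx[seq_len(n_tr)])
    if (rem > 0) {
      val <- c(val, idx[n_tr + seq_len(n_val)])
      if (rem - n_val > 0) test <- c(test, idx[(n_tr + n_val) + seq_len(rem - n_val)])
    }
  }
  list(train = sort(train), validation = sort(val), test = sort(test))
}
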