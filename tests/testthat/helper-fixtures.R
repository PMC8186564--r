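# Fixture builders shared across test files. Everything is generated in
# code at test time; no stored data.

# lightweight trial stubs for statistics that only need the summary fields
make_stub_trials <- function(n, block = "early", magnitude = 2,
                             outcome = "hit", rt = 0.4, change_time = 4,
                             first_lick = NA_real_, noisy = TRUE) {
  lapply(seq_len(n), function(i) {
    licks <- if (!is.na(first_lick)) first_lick else
      if (outcome == "hit") change_time + rt else numeric(0)
    structure(list(
      stimulus = structure(list(log2tf = numeric(0), change_sample = NA,
                                change_log2tf = NA, noisy = noisy),
                           class = "vc_stimulus"),
      block = block, prestim_delay = 3.2, change_time = change_time,
      change_magnitude = magnitude, lick_times = licks,
      wheel = numeric(0), outcome = outcome,
      reaction_time = if (outcome == "hit") rt else NA_real_
    ), class = "vc_trial")
  })
}

# boxcar filter over lags 0.25-1 s on the 50-ms grid (rows = lags 0, 0.05, ...)
boxcar_filter <- function(lo = 0.25, hi = 1, dt = 0.05, length_out = 20,
                          value = 1) {
  lags <- (seq_len(length_out) - 1) * dt
  matrix(value * as.numeric(lags >= lo & lags < hi), ncol = 1)
}

boxcar_agent <- function(gain = 4, bias = -3.5) {
  synthetic_agent(boxcar_filter(), filter_gains = gain, bias = bias)
}

# shared synthetic contamination fixture
make_neuropil_fixture <- function(T = 4000, alpha = 0.7, seed = 8,
                                  n_trans = 25, trans_amp = 3) {
  set.seed(seed)
  n_t <- as.numeric(arima.sim(list(ar = 0.9), T)) * 0.5
  trans <- rep(0, T)
  at <- sort(sample(50:(T - 50), n_trans))
  for (sp in at) trans[sp:(sp + 10)] <- trans[sp:(sp + 10)] +
    trans_amp * exp(-(0:10) / 4)
  roi <- alpha * n_t + trans + rnorm(T, 0, 0.08)
  surround <- n_t + rnorm(T, 0, 0.08)
  list(roi = roi, surround = surround, n = n_t, transients = trans,
       spikes = at)
}
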