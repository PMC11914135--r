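# Shared fixtures, all generated in code at test time.

# Perfectly separable dataset: targets carry a fixed template, non-targets
# are exactly zero. No noise anywhere.
separable_dataset <- function(n_target = 12, n_nontarget = 48,
                              n_channels = 4, n_samples = 30) {
  template <- sin(seq(0, pi, length.out = n_samples))
  trials <- array(0, c(n_target + n_nontarget, n_channels, n_samples))
  for (i in seq_len(n_target)) {
    trials[i, , ] <- matrix(template, n_channels, n_samples, byrow = TRUE) *
      seq(0.5, 1.5, length.out = n_channels)
  }
  labels <- c(rep(1L, n_target), rep(0L, n_nontarget))
  bciparity:::.new_trial_dataset(
    trials, labels, trial_window_s = n_samples / 150, effective_fs = 150,
    provenance = "CF", band = c(1, 20),
    channel_names = paste0("ch", seq_len(n_channels)))
}

# Gaussian-noise dataset with no class signal (null data)
null_dataset <- function(n = 200, n_channels = 4, n_samples = 30,
                         seed = 99) {
  set.seed(seed)
  trials <- array(rnorm(n * n_channels * n_samples),
                  c(n, n_channels, n_samples))
  labels <- c(rep(1L, round(n / 11)), rep(0L, n - round(n / 11)))
  bciparity:::.new_trial_dataset(
    trials, labels, trial_window_s = n_samples / 150, effective_fs = 150,
    provenance = "CF", band = c(1, 20),
    channel_names = paste0("ch", seq_len(n_channels)))
}

# Small calibration session with tunable noise/signal; cached per parameter
# combination because synthesis + filtering dominate test runtime.
.session_cache <- new.env(parent = emptyenv())
cached_session <- function(n_inquiries = 20, p300_amp_uV = 5,
                           background_sd_uV = 3, seed = 42, rate = 5,
                           alpha_amp_uV = 5, line_amp_uV = 2,
                           blink_rate_per_s = 0.1,
                           latency_jitter_sd_s = 0.02) {
  key <- paste(n_inquiries, p300_amp_uV, background_sd_uV, seed, rate,
               alpha_amp_uV, line_amp_uV, blink_rate_per_s,
               latency_jitter_sd_s, sep = "|")
  if (!is.null(.session_cache[[key]])) return(.session_cache[[key]])
  sched <- build_calibration_schedule(n_inquiries = n_inquiries, rate = rate,
                                      seed = seed)
  params <- synthesis_params(
    p300_amp_uV = p300_amp_uV, background_sd_uV = background_sd_uV,
    alpha_amp_uV = alpha_amp_uV, line_amp_uV = line_amp_uV,
    blink_rate_per_s = blink_rate_per_s,
    latency_jitter_sd_s = latency_jitter_sd_s, seed = seed + 1)
  .session_cache[[key]] <- synthesize_session(sched, params)
  .session_cache[[key]]
}

# session that is a pure stationary sinusoid (alpha only), for filter-parity
# oracles
sinusoid_session <- function(n_inquiries = 12, freq = 10, amp = 20,
                             seed = 5) {
  sched <- build_calibration_schedule(n_inquiries = n_inquiries, seed = seed)
  params <- synthesis_params(
    p300_amp_uV = 0, n200_amp_uV = 0, background_sd_uV = 0,
    alpha_amp_uV = amp, alpha_freq_Hz = freq, line_amp_uV = 0,
    blink_rate_per_s = 0, latency_jitter_sd_s = 0, seed = seed)
  synthesize_session(sched, params)
}

# filtered trial dataset with realistic structure, shared across model tests
.trialset_cache <- new.env(parent = emptyenv())
cached_trialset <- function() {
  if (is.null(.trialset_cache$ds)) {
    raw <- cached_session(n_inquiries = 20, p300_amp_uV = 5,
                          background_sd_uV = 3)
    .trialset_cache$ds <- online_pipeline(raw)
  }
  .trialset_cache$ds
}

# AUC helper used by a few oracles
simple_auc <- function(scores, labels) {
  s1 <- scores[labels == 1]; s0 <- scores[labels == 0]
  mean(outer(s1, s0, ">")) + 0.5 * mean(outer(s1, s0, "=="))
}
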