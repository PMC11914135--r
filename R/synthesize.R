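#' Default 19-channel 10-20 montage
#'
#' The deduplicated standard 10-20 scalp set used throughout the package.
#'
#' @return Character vector of 19 channel labels.
#' @export
default_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T3", "C3", "Cz", "C4", "T4",
    "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

# per-component channel weight maps; Pz carries the full P300 so that a
# noise-free synthesis reproduces the template exactly at Pz
.erp_channel_weights <- function(channel_names) {
  w <- function(pairs) {
    v <- stats::setNames(numeric(length(channel_names)), channel_names)
    keep <- intersect(names(pairs), channel_names)
    v[keep] <- pairs[keep]
    v
  }
  list(
    n200 = w(c(O1 = 1, O2 = 1, P3 = 0.5, P4 = 0.5)),
    p300 = w(c(Pz = 1, Cz = 0.8, P3 = 0.6, P4 = 0.6)),
    blink = w(c(Fp1 = 1, Fp2 = 1, F3 = 0.3, Fz = 0.3, F4 = 0.3))
  )
}

#' Synthesis parameters for the EEG generator
#'
#' Bundles and validates every knob of [synthesize_session()]. Defaults
#' emulate an adult scalp EEG recorded with a dry-electrode cap in an office
#' environment: AR(1) background noise, a 10 Hz alpha rhythm, 60 Hz mains
#' interference, sporadic blinks, and N200/P300 deflections after attended
#' (target) stimuli.
#'
#' @param fs Sampling rate in Hz (default 300).
#' @param channel_names Channel labels (default [default_channels()]).
#' @param n200_amp_uV,n200_latency_s,n200_width_s N200 Gaussian component:
#'   amplitude (negative, default -2), post-stimulus latency (default 0.20 s)
#'   and Gaussian sd (default 0.025 s), weighted toward O1/O2/P3/P4.
#' @param p300_amp_uV,p300_latency_s,p300_width_s P300 Gaussian component:
#'   amplitude (default +5), latency (default 0.35 s), sd (default 0.06 s),
#'   weighted toward Pz/Cz/P3/P4 with unit weight at Pz.
#' @param latency_jitter_sd_s Per-trial Gaussian latency jitter applied to
#'   both components (default 0.02 s).
#' @param background_sd_uV Stationary (marginal) standard deviation of the
#'   per-channel AR(1) background (default 10); innovations are scaled by
#'   `sqrt(1 - ar_coefficient^2)` so this is the amplitude scale of the
#'   rendered background signal.
#' @param ar_coefficient AR(1) coefficient (default 0.95).
#' @param alpha_amp_uV,alpha_freq_Hz Alpha sinusoid amplitude (default 5) and
#'   frequency (default 10 Hz), random phase per channel.
#' @param line_amp_uV,line_freq_Hz Power-line sinusoid amplitude (default 2)
#'   and frequency (default 60 Hz), common phase across channels.
#' @param blink_rate_per_s Poisson rate of blink events (default 0.1).
#' @param blink_amp_uV Blink amplitude on Fp1/Fp2 (default 100; scaled 0.3 on
#'   F3/Fz/F4, 0 elsewhere).
#' @param blink_duration_s Blink half-sine duration (default 0.4 s).
#' @param seed Integer master seed for the generator.
#' @return A validated `synthesis_params` list.
#' @export
synthesis_params <- function(fs = 300,
                             channel_names = default_channels(),
                             n200_amp_uV = -2, n200_latency_s = 0.20,
                             n200_width_s = 0.025,
                             p300_amp_uV = 5, p300_latency_s = 0.35,
                             p300_width_s = 0.06,
                             latency_jitter_sd_s = 0.02,
                             background_sd_uV = 10, ar_coefficient = 0.95,
                             alpha_amp_uV = 5, alpha_freq_Hz = 10,
                             line_amp_uV = 2, line_freq_Hz = 60,
                             blink_rate_per_s = 0.1, blink_amp_uV = 100,
                             blink_duration_s = 0.4,
                             seed = 1L) {
  if (anyDuplicated(channel_names)) stop("duplicate channel names")
  if (fs <= 2 * alpha_freq_Hz || fs <= 2 * line_freq_Hz) {
    stop("fs must exceed twice the alpha and line frequencies")
  }
  nonneg <- c(
    abs_n200 = abs(n200_amp_uV), p300 = p300_amp_uV,
    jitter = latency_jitter_sd_s, bg = background_sd_uV,
    alpha = alpha_amp_uV, line = line_amp_uV,
    blink_rate = blink_rate_per_s, blink_amp = blink_amp_uV,
    blink_dur = blink_duration_s
  )
  if (any(nonneg < 0)) stop("amplitude and rate parameters must be >= 0")
  structure(
    list(
      fs = fs, channel_names = channel_names,
      erp = list(
        n200_amp_uV = n200_amp_uV, n200_latency_s = n200_latency_s,
        n200_width_s = n200_width_s,
        p300_amp_uV = p300_amp_uV, p300_latency_s = p300_latency_s,
        p300_width_s = p300_width_s,
        latency_jitter_sd_s = latency_jitter_sd_s
      ),
      noise = list(
        background_sd_uV = background_sd_uV, ar_coefficient = ar_coefficient,
        alpha_amp_uV = alpha_amp_uV, alpha_freq_Hz = alpha_freq_Hz
      ),
      artifacts = list(
        line_amp_uV = line_amp_uV, line_freq_Hz = line_freq_Hz,
        blink_rate_per_s = blink_rate_per_s, blink_amp_uV = blink_amp_uV,
        blink_duration_s = blink_duration_s
      ),
      seed = as.integer(seed)
    ),
    class = "synthesis_params"
  )
}

#' The noiseless ERP template at a given channel
#'
#' Sum of the N200 and P300 Gaussian components, weighted for `channel`, on a
#' post-stimulus time grid. This is what the average target epoch converges
#' to as noise vanishes.
#'
#' @param params A `synthesis_params`.
#' @param channel Channel label.
#' @param t Post-stimulus times (s).
#' @return Numeric vector of template amplitudes (uV).
#' @export
erp_template <- function(params, channel, t) {
  w <- .erp_channel_weights(params$channel_names)
  e <- params$erp
  w$n200[channel] * e$n200_amp_uV *
    exp(-(t - e$n200_latency_s)^2 / (2 * e$n200_width_s^2)) +
    w$p300[channel] * e$p300_amp_uV *
      exp(-(t - e$p300_latency_s)^2 / (2 * e$p300_width_s^2))
}

#' Synthesize a continuous multichannel EEG session
#'
#' Renders a `stim_schedule` into a continuous channels-by-samples recording:
#' per-channel AR(1) background noise, an alpha sinusoid with random
#' per-channel phase, a common-phase power-line sinusoid, frontally weighted
#' half-sine blink pulses at Poisson times, and - after every target stimulus
#' onset - the N200/P300 Gaussian deflections with seeded per-trial latency
#' jitter. Bit-identical output for identical seed and parameters.
#'
#' @param schedule A `stim_schedule`.
#' @param params A `synthesis_params`.
#' @param tail_s Seconds of recording kept after the last stimulus onset
#'   (default 1.5; must cover the analysis window).
#' @return A `raw_session`: list with `data` (channels x samples matrix, uV),
#'   `fs`, `channel_names`, `schedule`, `seed_used`.
#' @export
synthesize_session <- function(schedule, params = synthesis_params(),
                               tail_s = 1.5) {
  stopifnot(inherits(schedule, "stim_schedule"),
            inherits(params, "synthesis_params"))
  fs <- params$fs
  ch <- params$channel_names
  n_ch <- length(ch)
  onsets <- trial_onsets(schedule)
  duration <- if (length(onsets)) max(onsets) + tail_s else 1.0
  n_s <- as.integer(ceiling(duration * fs))
  tgrid <- (seq_len(n_s) - 1) / fs
  x <- matrix(0, n_ch, n_s, dimnames = list(ch, NULL))
  w <- .erp_channel_weights(ch)
  base_seed <- params$seed

  # background AR(1), independent per channel
  if (params$noise$background_sd_uV > 0) {
    set.seed(base_seed + 1L)
    innov_sd <- params$noise$background_sd_uV *
      sqrt(1 - params$noise$ar_coefficient^2)
    for (c in seq_len(n_ch)) {
      innov <- stats::rnorm(n_s, sd = innov_sd)
      x[c, ] <- x[c, ] + as.numeric(
        stats::filter(innov, params$noise$ar_coefficient, method = "recursive")
      )
    }
  }

  # alpha rhythm, per-channel phase
  if (params$noise$alpha_amp_uV > 0) {
    set.seed(base_seed + 2L)
    phases <- stats::runif(n_ch, 0, 2 * pi)
    for (c in seq_len(n_ch)) {
      x[c, ] <- x[c, ] + params$noise$alpha_amp_uV *
        sin(2 * pi * params$noise$alpha_freq_Hz * tgrid + phases[c])
    }
  }

  # power-line interference, common phase
  if (params$artifacts$line_amp_uV > 0) {
    set.seed(base_seed + 3L)
    phase <- stats::runif(1, 0, 2 * pi)
    line <- params$artifacts$line_amp_uV *
      sin(2 * pi * params$artifacts$line_freq_Hz * tgrid + phase)
    x <- x + matrix(line, n_ch, n_s, byrow = TRUE)
  }

  # blinks: half-sine pulses at Poisson times, frontal weighting
  if (params$artifacts$blink_rate_per_s > 0 &&
      params$artifacts$blink_amp_uV > 0) {
    set.seed(base_seed + 4L)
    n_blinks <- stats::rpois(1, params$artifacts$blink_rate_per_s * duration)
    blink_t <- sort(stats::runif(n_blinks, 0, duration))
    blen <- max(1L, round(params$artifacts$blink_duration_s * fs))
    pulse <- sin(pi * (seq_len(blen) - 1) / (blen - 1)) *
      params$artifacts$blink_amp_uV
    for (bt in blink_t) {
      i0 <- round(bt * fs) + 1L
      idx <- i0:min(i0 + blen - 1L, n_s)
      if (length(idx) == 0 || idx[1] > n_s) next
      x[, idx] <- x[, idx] + outer(w$blink, pulse[seq_along(idx)])
    }
  }

  # ERP deflections on target stimuli, jittered latency per trial
  e <- params$erp
  has_erp <- e$n200_amp_uV != 0 || e$p300_amp_uV != 0
  if (has_erp) {
    set.seed(base_seed + 5L)
    for (q in schedule$inquiries) {
      if (is.na(q$target_position)) next
      onset <- q$stimulus_onsets[q$target_position + 1L]
      jit <- if (e$latency_jitter_sd_s > 0) {
        stats::rnorm(1, sd = e$latency_jitter_sd_s)
      } else 0
      span_s <- e$p300_latency_s + 5 * e$p300_width_s + abs(jit) + 0.1
      i0 <- round(onset * fs) + 1L
      i1 <- min(i0 + as.integer(ceiling(span_s * fs)), n_s)
      if (i1 > n_s || i0 > n_s) {
        stop("scheduled target ERP extends past the allocated duration")
      }
      trel <- (seq(i0, i1) - i0) / fs
      n200 <- e$n200_amp_uV *
        exp(-(trel - (e$n200_latency_s + jit))^2 / (2 * e$n200_width_s^2))
      p300 <- e$p300_amp_uV *
        exp(-(trel - (e$p300_latency_s + jit))^2 / (2 * e$p300_width_s^2))
      x[, i0:i1] <- x[, i0:i1] + outer(w$n200, n200) + outer(w$p300, p300)
    }
  }

  structure(
    list(data = x, fs = fs, channel_names = ch, schedule = schedule,
         seed_used = base_seed),
    class = "raw_session"
  )
}

#' @export
print.raw_session <- function(x, ...) {
  cat(sprintf("<raw_session: %d channels x %d samples @ %g Hz (%.1f s)>\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Extract unfiltered stimulus-locked trials from a raw session
#'
#' Cuts one epoch of `trial_window_s` seconds after every scheduled stimulus
#' onset, without any filtering or downsampling. Used for ERP averaging and
#' for verifying the generator.
#'
#' @param raw A `raw_session`.
#' @param trial_window_s Epoch length in seconds (default 0.5).
#' @return List with `trials` (n x channels x samples array), `labels`, `fs`.
#' @export
extract_trials <- function(raw, trial_window_s = 0.5) {
  stopifnot(inherits(raw, "raw_session"))
  fs <- raw$fs
  onsets <- trial_onsets(raw$schedule)
  labels <- trial_labels(raw$schedule)
  wlen <- as.integer(floor(trial_window_s * fs))
  n_ch <- nrow(raw$data)
  out <- array(0, c(length(onsets), n_ch, wlen),
               dimnames = list(NULL, raw$channel_names, NULL))
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * fs) + 1L
    if (i0 + wlen - 1L > ncol(raw$data)) {
      stop(sprintf("stimulus %d at %.3f s extends past the record", i,
                   onsets[i]))
    }
    out[i, , ] <- raw$data[, i0:(i0 + wlen - 1L)]
  }
  list(trials = out, labels = labels, fs = fs)
}
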