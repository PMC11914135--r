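#' @keywords internal
.new_trial_dataset <- function(trials, labels, trial_window_s, effective_fs,
                               provenance, band, channel_names) {
  structure(
    list(trials = trials, labels = as.integer(labels),
         trial_window_s = trial_window_s, effective_fs = effective_fs,
         provenance = provenance, band = band,
         channel_names = channel_names),
    class = "trial_dataset"
  )
}

#' @export
print.trial_dataset <- function(x, ...) {
  d <- dim(x$trials)
  cat(sprintf(
    "<trial_dataset [%s]: %d trials x %d channels x %d samples @ %g Hz, %d targets>\n",
    x$provenance, d[1], d[2], d[3], x$effective_fs, sum(x$labels)))
  invisible(x)
}

# samples kept per trial after decimation; integer by construction for the
# default 0.5 s window at 300 Hz / factor 2
.trial_samples <- function(trial_window_s, fs, factor) {
  as.integer(floor(trial_window_s * fs) / factor)
}

#' Conventional (filter-then-epoch) pre-processing
#'
#' Applies the filter chain once to the entire continuous recording, then
#' extracts one trial per scheduled stimulus from the filtered, downsampled
#' record. This is the standard offline EEG workflow, which breaks online
#' parity: every trial has seen filter context from the whole session.
#'
#' @param raw A `raw_session`.
#' @param spec A [filter_spec()].
#' @param trial_window_s Post-stimulus trial window in seconds (default 0.5).
#' @return A `trial_dataset` with `provenance = "CF"`.
#' @export
conventional_pipeline <- function(raw, spec = filter_spec(),
                                  trial_window_s = 0.5) {
  stopifnot(inherits(raw, "raw_session"))
  fs <- raw$fs
  filters <- design_filter_chain(spec, fs)
  onsets <- trial_onsets(raw$schedule)
  labels <- trial_labels(raw$schedule)
  onset_samples <- round(onsets * fs)            # 0-based
  wlen_raw <- as.integer(floor(trial_window_s * fs))
  bad <- which(onset_samples + wlen_raw > ncol(raw$data))
  if (length(bad)) {
    stop(sprintf("stimuli beyond the record: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  filtered <- apply_filter_chain(raw$data, filters)
  factor <- spec$downsample_factor
  wlen <- .trial_samples(trial_window_s, fs, factor)
  n_ch <- nrow(filtered)
  trials <- array(0, c(length(onsets), n_ch, wlen),
                  dimnames = list(NULL, raw$channel_names, NULL))
  for (i in seq_along(onsets)) {
    j0 <- onset_samples[i] %/% factor + 1L       # back to 1-based
    trials[i, , ] <- filtered[, j0:(j0 + wlen - 1L)]
  }
  .new_trial_dataset(trials, labels, trial_window_s, fs / factor, "CF",
                     c(spec$band_low, spec$band_high), raw$channel_names)
}

#' Online-parity (epoch-then-filter) pre-processing
#'
#' Cuts each inquiry out of the raw record with `buffer_s` seconds of context
#' on both ends, filters every buffered inquiry epoch independently with zero
#' initial conditions (exactly as inquiries arrive during closed-loop use),
#' discards the buffers, and extracts trials. Epoch starts are aligned to the
#' decimation grid so trial tensors are sample-aligned with the conventional
#' pipeline's.
#'
#' @param raw A `raw_session`.
#' @param spec A [filter_spec()].
#' @param trial_window_s Post-stimulus trial window in seconds (default 0.5).
#' @param buffer_s Buffer on each end of the inquiry epoch (default 1.0).
#' @return A `trial_dataset` with `provenance = "OF"`, shape-identical to the
#'   conventional output for the same session.
#' @export
online_pipeline <- function(raw, spec = filter_spec(), trial_window_s = 0.5,
                            buffer_s = 1.0) {
  stopifnot(inherits(raw, "raw_session"), buffer_s >= 0)
  fs <- raw$fs
  filters <- design_filter_chain(spec, fs)
  factor <- spec$downsample_factor
  wlen_raw <- as.integer(floor(trial_window_s * fs))
  wlen <- .trial_samples(trial_window_s, fs, factor)
  buf <- round(buffer_s * fs)
  n_ch <- nrow(raw$data)
  n_trials <- n_stimuli(raw$schedule)
  trials <- array(0, c(n_trials, n_ch, wlen),
                  dimnames = list(NULL, raw$channel_names, NULL))
  labels <- trial_labels(raw$schedule)

  k <- 0L
  for (q in raw$schedule$inquiries) {
    onset_samples <- round(q$stimulus_onsets * fs)   # 0-based
    e0 <- onset_samples[1] - buf
    e0 <- (e0 %/% factor) * factor                   # align to decimation grid
    e1 <- onset_samples[length(onset_samples)] + wlen_raw + buf
    if (e0 < 0 || e1 > ncol(raw$data)) {
      stop(sprintf(
        "buffered inquiry epoch [%d, %d] outside the record (0..%d)",
        e0, e1, ncol(raw$data)))
    }
    seg <- raw$data[, (e0 + 1L):e1, drop = FALSE]
    filtered <- apply_filter_chain(seg, filters)
    for (s in seq_along(onset_samples)) {
      k <- k + 1L
      j0 <- (onset_samples[s] - e0) %/% factor + 1L
      trials[k, , ] <- filtered[, j0:(j0 + wlen - 1L)]
    }
  }

  .new_trial_dataset(trials, labels, trial_window_s, fs / factor, "OF",
                     c(spec$band_low, spec$band_high), raw$channel_names)
}
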