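#' RSVP symbol alphabet
#'
#' The 28 symbols used by the RSVP speller: the 26 uppercase letters plus
#' `"_"` (space) and `"<"` (backspace).
#'
#' @return Character vector of length 28.
#' @export
rsvp_alphabet <- function() {
  c(LETTERS, "_", "<")
}

#' Build an RSVP calibration stimulus schedule
#'
#' Generates the stimulus/trigger schedule of an RSVP calibration session:
#' `n_inquiries` inquiries of `stims_per_inquiry` rapidly presented symbols.
#' Each inquiry is preceded by a target prompt (`prompt_s`) and a fixation
#' cross (`fixation_s`); inquiries are separated by a blank-screen gap
#' (`gap_s`). A fraction `no_target_fraction` of inquiries contains no target
#' symbol; every other inquiry contains the prompted target exactly once, at a
#' position drawn uniformly over the `stims_per_inquiry` slots.
#'
#' @param n_inquiries Number of inquiries (default 110).
#' @param stims_per_inquiry Symbols per inquiry (default 10).
#' @param no_target_fraction Fraction of inquiries without a target
#'   (default 0.10); `n_inquiries * no_target_fraction` is rounded to the
#'   nearest integer.
#' @param rate Presentation rate in Hz (default 5): consecutive stimulus
#'   onsets within an inquiry differ by exactly `1/rate` seconds.
#' @param prompt_s Prompt duration in seconds (default 1.0).
#' @param fixation_s Fixation duration in seconds (default 0.5).
#' @param gap_s Blank-screen gap between inquiries in seconds (default 2.0).
#' @param seed Integer seed; the schedule is deterministic given the seed.
#'
#' @return A `stim_schedule` object: a list with `inquiries` (each holding
#'   `stimulus_labels`, `target_label`, `target_position` (0-based, `NA` when
#'   target-free), `prompt_onset`, `fixation_onset`, `stimulus_onsets`),
#'   `presentation_rate`, `inter_inquiry_gap` and `kind = "calibration"`.
#' @examples
#' sched <- build_calibration_schedule(seed = 7)
#' n_stimuli(sched)          # 1100
#' sum(trial_labels(sched))  # 99 target trials
#' @export
build_calibration_schedule <- function(n_inquiries = 110,
                                       stims_per_inquiry = 10,
                                       no_target_fraction = 0.10,
                                       rate = 5,
                                       prompt_s = 1.0,
                                       fixation_s = 0.5,
                                       gap_s = 2.0,
                                       seed = 1L) {
  if (n_inquiries < 0 || stims_per_inquiry < 0) {
    stop("inquiry and stimulus counts must be non-negative")
  }
  if (rate <= 0) stop("presentation rate must be > 0")
  if (no_target_fraction < 0 || no_target_fraction > 1) {
    stop("no_target_fraction must lie in [0, 1]")
  }
  set.seed(seed)
  alphabet <- rsvp_alphabet()
  n_free <- as.integer(round(n_inquiries * no_target_fraction))
  free_idx <- if (n_inquiries > 0 && n_free > 0) {
    sort(sample.int(n_inquiries, n_free))
  } else integer(0)

  inquiries <- vector("list", n_inquiries)
  t0 <- 0
  for (i in seq_len(n_inquiries)) {
    prompt_onset <- t0
    fixation_onset <- prompt_onset + prompt_s
    first_stim <- fixation_onset + fixation_s
    onsets <- first_stim + (seq_len(stims_per_inquiry) - 1) / rate
    target_label <- sample(alphabet, 1)
    if (i %in% free_idx) {
      labels <- sample(setdiff(alphabet, target_label), stims_per_inquiry)
      target_position <- NA_integer_
    } else {
      target_position <- sample.int(stims_per_inquiry, 1) - 1L
      labels <- sample(setdiff(alphabet, target_label), stims_per_inquiry)
      labels[target_position + 1L] <- target_label
    }
    inquiries[[i]] <- list(
      stimulus_labels = labels,
      target_label = target_label,
      target_position = target_position,
      prompt_onset = prompt_onset,
      fixation_onset = fixation_onset,
      stimulus_onsets = onsets
    )
    t0 <- onsets[stims_per_inquiry] + 1 / rate + gap_s
  }

  structure(
    list(
      inquiries = inquiries,
      presentation_rate = rate,
      inter_inquiry_gap = gap_s,
      prompt_s = prompt_s,
      fixation_s = fixation_s,
      stims_per_inquiry = stims_per_inquiry,
      kind = "calibration",
      seed = seed
    ),
    class = "stim_schedule"
  )
}

#' Build a copy-phrase (online typing) stimulus schedule
#'
#' Schedules the No-Preview copy-phrase task: the user spells `target_word`
#' (which must occur in `phrase`), one letter at a time, with
#' `n_inquiries_per_letter` inquiries per letter. Each inquiry presents 10
#' distinct symbols drawn from the alphabet, always including the current
#' target letter, at a position uniform over the 10 slots. Only the first
#' inquiry carries a prompt; subsequent inquiries run fixation-to-fixation as
#' during closed-loop use.
#'
#' @param phrase Full phrase providing task context.
#' @param target_word Word to spell; must be a substring of `phrase`.
#' @param n_inquiries_per_letter Inquiries scheduled per letter (default 5).
#' @param rate Presentation rate in Hz (default 5).
#' @param seed Integer seed.
#' @param stims_per_inquiry Symbols per inquiry (default 10).
#' @param prompt_s,fixation_s,gap_s Timing parameters as in
#'   [build_calibration_schedule()].
#' @return A `stim_schedule` with `kind = "copy_phrase"`; every inquiry has
#'   exactly one target trial.
#' @export
build_copy_phrase_schedule <- function(phrase,
                                       target_word,
                                       n_inquiries_per_letter = 5,
                                       rate = 5,
                                       seed = 1L,
                                       stims_per_inquiry = 10,
                                       prompt_s = 1.0,
                                       fixation_s = 0.5,
                                       gap_s = 2.0) {
  if (!nzchar(phrase) || !nzchar(target_word)) {
    stop("phrase and target_word must be non-empty")
  }
  if (n_inquiries_per_letter <= 0 || rate <= 0) {
    stop("counts and rate must be positive")
  }
  if (!grepl(toupper(target_word), toupper(phrase), fixed = TRUE)) {
    stop("target_word must occur within phrase")
  }
  set.seed(seed)
  alphabet <- rsvp_alphabet()
  letters_to_spell <- strsplit(toupper(target_word), "")[[1]]
  letters_to_spell[letters_to_spell == " "] <- "_"

  inquiries <- list()
  t0 <- 0
  first <- TRUE
  for (letter in letters_to_spell) {
    for (k in seq_len(n_inquiries_per_letter)) {
      prompt_onset <- if (first) t0 else NA_real_
      fixation_onset <- if (first) t0 + prompt_s else t0
      first <- FALSE
      first_stim <- fixation_onset + fixation_s
      onsets <- first_stim + (seq_len(stims_per_inquiry) - 1) / rate
      target_position <- sample.int(stims_per_inquiry, 1) - 1L
      labels <- sample(setdiff(alphabet, letter), stims_per_inquiry)
      labels[target_position + 1L] <- letter
      inquiries[[length(inquiries) + 1L]] <- list(
        stimulus_labels = labels,
        target_label = letter,
        target_position = target_position,
        prompt_onset = prompt_onset,
        fixation_onset = fixation_onset,
        stimulus_onsets = onsets
      )
      t0 <- onsets[stims_per_inquiry] + 1 / rate + gap_s
    }
  }

  structure(
    list(
      inquiries = inquiries,
      presentation_rate = rate,
      inter_inquiry_gap = gap_s,
      prompt_s = prompt_s,
      fixation_s = fixation_s,
      stims_per_inquiry = stims_per_inquiry,
      kind = "copy_phrase",
      phrase = phrase,
      target_word = target_word,
      seed = seed
    ),
    class = "stim_schedule"
  )
}

#' @export
print.stim_schedule <- function(x, ...) {
  cat(sprintf(
    "<stim_schedule: %s, %d inquiries x %d stimuli @ %g Hz, %d target trials>\n",
    x$kind, length(x$inquiries), x$stims_per_inquiry,
    x$presentation_rate, sum(trial_labels(x))
  ))
  invisible(x)
}

#' Total stimulus (trial) count of a schedule
#' @param schedule A `stim_schedule`.
#' @return Integer count of scheduled stimuli.
#' @export
n_stimuli <- function(schedule) {
  sum(vapply(schedule$inquiries, function(q) length(q$stimulus_onsets), 1L))
}

#' All stimulus onsets of a schedule, in presentation order
#' @param schedule A `stim_schedule`.
#' @return Numeric vector of onset times (s), strictly increasing.
#' @export
trial_onsets <- function(schedule) {
  unlist(lapply(schedule$inquiries, function(q) q$stimulus_onsets),
         use.names = FALSE)
}

#' Binary target labels for every scheduled stimulus
#' @param schedule A `stim_schedule`.
#' @return Integer vector (1 = target, 0 = non-target), one per stimulus.
#' @export
trial_labels <- function(schedule) {
  unlist(lapply(schedule$inquiries, function(q) {
    lab <- integer(length(q$stimulus_onsets))
    if (!is.na(q$target_position)) lab[q$target_position + 1L] <- 1L
    lab
  }), use.names = FALSE)
}

#' Number of target-free inquiries in a schedule
#' @param schedule A `stim_schedule`.
#' @return Integer count of inquiries with no target.
#' @export
n_target_free <- function(schedule) {
  sum(vapply(schedule$inquiries, function(q) is.na(q$target_position), NA))
}
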