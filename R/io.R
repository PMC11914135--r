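# Session and model serialization. Sessions go to a directory of plain-text
# files (data.csv, triggers.json, meta.json) so recordings can be inspected
# or diffed; the layout is byte-stable for a fixed seed.

#' Write a raw session to a directory
#'
#' Writes `data.csv` (one header row of channel names, one row per sample,
#' uV), `triggers.json` (entries `{label, type, onset_s}` with types
#' `prompt`, `fixation`, `target`, `nontarget`) and `meta.json` (fs, seed,
#' channel names, schedule summary).
#'
#' @param session A `raw_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "raw_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dt <- data.table::as.data.table(t(session$data))
  data.table::setnames(dt, session$channel_names)
  data.table::fwrite(dt, file.path(dir, "data.csv"))

  triggers <- list()
  for (q in session$schedule$inquiries) {
    if (!is.na(q$prompt_onset)) {
      triggers[[length(triggers) + 1L]] <-
        list(label = q$target_label, type = "prompt", onset_s = q$prompt_onset)
    }
    triggers[[length(triggers) + 1L]] <-
      list(label = "+", type = "fixation", onset_s = q$fixation_onset)
    for (s in seq_along(q$stimulus_onsets)) {
      type <- if (!is.na(q$target_position) && s == q$target_position + 1L) {
        "target"
      } else "nontarget"
      triggers[[length(triggers) + 1L]] <-
        list(label = q$stimulus_labels[s], type = type,
             onset_s = q$stimulus_onsets[s])
    }
  }
  jsonlite::write_json(triggers, file.path(dir, "triggers.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(fs = session$fs, seed = session$seed_used,
         channel_names = session$channel_names,
         n_inquiries = length(session$schedule$inquiries),
         kind = session$schedule$kind,
         presentation_rate = session$schedule$presentation_rate,
         inter_inquiry_gap = session$schedule$inter_inquiry_gap),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a raw session written by [write_session()]
#'
#' @param dir Directory holding `data.csv`, `triggers.json`, `meta.json`.
#' @return A `raw_session`. The schedule is reconstructed from the trigger
#'   list (labels, target positions, onsets).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  dt <- data.table::fread(file.path(dir, "data.csv"))
  data <- t(as.matrix(dt))
  rownames(data) <- meta$channel_names
  trig <- jsonlite::read_json(file.path(dir, "triggers.json"),
                              simplifyVector = TRUE)
  # rebuild inquiries: a fixation starts each inquiry
  fix_idx <- which(trig$type == "fixation")
  bounds <- c(fix_idx, nrow(trig) + 1L)
  inquiries <- vector("list", length(fix_idx))
  for (i in seq_along(fix_idx)) {
    rows <- trig[seq(bounds[i], bounds[i + 1] - 1L), ]
    stims <- rows[rows$type %in% c("target", "nontarget"), ]
    prompt_row <- if (bounds[i] > 1 && trig$type[bounds[i] - 1L] == "prompt") {
      trig[bounds[i] - 1L, ]
    } else NULL
    tpos <- which(stims$type == "target")
    inquiries[[i]] <- list(
      stimulus_labels = stims$label,
      target_label = if (length(tpos)) stims$label[tpos] else
        (if (!is.null(prompt_row)) prompt_row$label else NA_character_),
      target_position = if (length(tpos)) tpos - 1L else NA_integer_,
      prompt_onset = if (!is.null(prompt_row)) prompt_row$onset_s else NA_real_,
      fixation_onset = rows$onset_s[rows$type == "fixation"][1],
      stimulus_onsets = stims$onset_s
    )
  }
  schedule <- structure(
    list(inquiries = inquiries,
         presentation_rate = meta$presentation_rate,
         inter_inquiry_gap = meta$inter_inquiry_gap,
         stims_per_inquiry = length(inquiries[[1]]$stimulus_onsets),
         kind = meta$kind, seed = meta$seed),
    class = "stim_schedule"
  )
  structure(
    list(data = data, fs = meta$fs, channel_names = meta$channel_names,
         schedule = schedule, seed_used = meta$seed),
    class = "raw_session"
  )
}

#' Save a trained model with a JSON manifest
#'
#' Writes the model object to `<path>.rds` and a human-readable manifest
#' (kind, trial shape, band, provenance, likelihood convention) to
#' `<path>.json`, so saved models can be reloaded for online simulation.
#'
#' @param model A `trained_model`.
#' @param path Output path without extension.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, paste0(path, ".rds"))
  jsonlite::write_json(
    list(kind = model$kind,
         channels = model$channel_names,
         trial_shape = model$trial_shape,
         band = model$band,
         provenance = model$provenance,
         likelihood_convention = "target/nontarget likelihood ratio; > 1 favors target",
         seed = model$seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path Path without extension.
#' @return A `trained_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(paste0(path, ".rds"))
  stopifnot(inherits(model, "trained_model"))
  model
}
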