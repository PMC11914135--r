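#' Configuration of the full filtering-comparison experiment
#'
#' One object driving the multi-subject study replica: synthetic subject
#' generation, conventional vs online-parity pre-processing, classifier
#' cross-validation, the filter-band sweep, paired permutation statistics,
#' and the online copy-phrase simulation. Subject heterogeneity is emulated
#' by drawing each subject's P300 amplitude uniformly from
#' `p300_amp_range_uV` and background-noise sd from `noise_sd_range_uV`
#' using sub-seeds derived from `master_seed`.
#'
#' @param n_subjects Synthetic subjects (default 30).
#' @param master_seed Master seed; every stage derives its own sub-seed from
#'   it by fixed integer offsets.
#' @param n_inquiries Calibration inquiries per subject (default 110).
#' @param p300_amp_range_uV,noise_sd_range_uV Uniform ranges for per-subject
#'   P300 amplitude (default 2-8 uV) and AR(1) innovation sd (default
#'   5-15 uV).
#' @param spec Default [filter_spec()].
#' @param bands Band list for the sweep (default the four standard bands).
#' @param models Model kinds to compare (default PRK, LR, RLDA).
#' @param hp A [model_hyperparams()].
#' @param trial_window_s,buffer_s Epoching parameters (defaults 0.5 s, 1 s).
#' @param n_permutations,alpha Permutation-test settings (defaults 50000,
#'   0.05).
#' @param n_simulation_subjects Subjects carried into the online simulation
#'   (default 25): the highest-calibration-MCC subset, mirroring exclusion
#'   of low-accuracy calibrations.
#' @param sim_phrase,sim_target_word,sim_inquiries_per_letter Copy-phrase
#'   simulation task (defaults: 4 x 5-letter words worth of inquiries via
#'   `sim_inquiries_per_letter = 5` over a 5-letter word, repeated
#'   `sim_n_phrases` times).
#' @param sim_n_phrases Number of copy phrases per subject (default 4).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(n_subjects = 30,
                              master_seed = 1L,
                              n_inquiries = 110,
                              p300_amp_range_uV = c(2, 8),
                              noise_sd_range_uV = c(5, 15),
                              spec = filter_spec(),
                              bands = list(c(1, 10), c(0.2, 20),
                                           c(1, 20), c(0.1, 50)),
                              models = c("PRK", "LR", "RLDA"),
                              hp = model_hyperparams(),
                              trial_window_s = 0.5,
                              buffer_s = 1.0,
                              n_permutations = 50000,
                              alpha = 0.05,
                              n_simulation_subjects = 25,
                              sim_phrase = "I want to go to the store",
                              sim_target_word = "store",
                              sim_inquiries_per_letter = 5,
                              sim_n_phrases = 4) {
  stopifnot(n_subjects >= 2, length(bands) >= 1)
  structure(
    list(n_subjects = as.integer(n_subjects),
         master_seed = as.integer(master_seed),
         n_inquiries = as.integer(n_inquiries),
         p300_amp_range_uV = p300_amp_range_uV,
         noise_sd_range_uV = noise_sd_range_uV,
         spec = spec, bands = bands, models = models, hp = hp,
         trial_window_s = trial_window_s, buffer_s = buffer_s,
         n_permutations = n_permutations, alpha = alpha,
         n_simulation_subjects = as.integer(n_simulation_subjects),
         sim_phrase = sim_phrase, sim_target_word = sim_target_word,
         sim_inquiries_per_letter = sim_inquiries_per_letter,
         sim_n_phrases = sim_n_phrases),
    class = "experiment_config"
  )
}

# per-subject sub-seeds and drawn synthesis parameters
.subject_setup <- function(cfg, i) {
  seed <- cfg$master_seed + 1000L * i
  set.seed(seed)
  amp <- stats::runif(1, cfg$p300_amp_range_uV[1], cfg$p300_amp_range_uV[2])
  noise_sd <- stats::runif(1, cfg$noise_sd_range_uV[1],
                           cfg$noise_sd_range_uV[2])
  list(seed = seed, p300_amp_uV = amp, background_sd_uV = noise_sd,
       params = synthesis_params(p300_amp_uV = amp,
                                 background_sd_uV = noise_sd,
                                 seed = seed + 1L))
}

.subject_calibration <- function(cfg, i) {
  su <- .subject_setup(cfg, i)
  sched <- build_calibration_schedule(n_inquiries = cfg$n_inquiries,
                                      seed = su$seed + 2L)
  list(setup = su, raw = synthesize_session(sched, su$params))
}

#' Run the conventional-vs-online filtering comparison
#'
#' For each synthetic subject: generate a calibration session, run both
#' pre-processing pipelines at the default band, cross-validate every model
#' kind on each, and record fold-mean BA and MCC. Afterwards, a paired
#' sign-flip permutation t-test compares OF against CF per model and metric.
#' Fully deterministic given `cfg$master_seed`.
#'
#' @param cfg An [experiment_config()].
#' @param progress Emit per-stage log lines to stderr (default TRUE).
#' @return A `study_report`: `metrics` (subject x model x condition rows),
#'   `tests` (one row per model x metric), and the config.
#' @export
run_filter_comparison <- function(cfg, progress = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"))
  rows <- list()
  for (i in seq_len(cfg$n_subjects)) {
    t0 <- proc.time()[3]
    cal <- .subject_calibration(cfg, i)
    datasets <- list(
      CF = conventional_pipeline(cal$raw, cfg$spec, cfg$trial_window_s),
      OF = online_pipeline(cal$raw, cfg$spec, cfg$trial_window_s,
                           cfg$buffer_s)
    )
    for (cond in names(datasets)) {
      for (m in cfg$models) {
        res <- tryCatch(
          cross_validate(m, datasets[[cond]], cfg$hp,
                         seed = cal$setup$seed + 3L),
          error = function(e) {
            stop(sprintf("subject %d, %s/%s failed: %s", i, cond, m,
                         conditionMessage(e)))
          })
        rows[[length(rows) + 1L]] <- data.frame(
          subject = i, model = m, condition = cond,
          band = paste(cfg$spec$band_low, cfg$spec$band_high, sep = "-"),
          ba = res$ba, mcc = res$mcc,
          p300_amp_uV = cal$setup$p300_amp_uV,
          noise_sd_uV = cal$setup$background_sd_uV,
          seed = cal$setup$seed
        )
      }
    }
    if (progress) {
      message(sprintf("[compare] subject %d/%d done in %.1f s", i,
                      cfg$n_subjects, proc.time()[3] - t0))
    }
  }
  metrics <- do.call(rbind, rows)

  tests <- list()
  for (m in cfg$models) {
    for (metric in c("ba", "mcc")) {
      of <- metrics[metrics$model == m & metrics$condition == "OF", metric]
      cf <- metrics[metrics$model == m & metrics$condition == "CF", metric]
      tt <- paired_permutation_test(of, cf, cfg$n_permutations, cfg$alpha,
                                    df = cfg$n_subjects - 1,
                                    seed = cfg$master_seed + 17L)
      tests[[length(tests) + 1L]] <- data.frame(
        model = m, metric = toupper(metric),
        of_mean = mean(of), of_sd = stats::sd(of),
        cf_mean = mean(cf), cf_sd = stats::sd(cf),
        mean_diff = tt$mean_diff, t = tt$t_observed, p = tt$p_value,
        threshold = tt$threshold
      )
    }
  }

  structure(list(metrics = metrics, tests = do.call(rbind, tests),
                 config = cfg),
            class = "study_report")
}

#' Run the filter-band sweep
#'
#' Cross-validates the PRK model per subject under each band in
#' `cfg$bands`, for both pre-processing conditions, and tabulates per-cell
#' mean MCC with standard errors. Bands invalid for the sampling rate are
#' skipped with a warning and an `NA` cell.
#'
#' @param cfg An [experiment_config()].
#' @param progress Emit log lines (default TRUE).
#' @return Data frame with one row per band x condition: `mean_mcc`,
#'   `se_mcc`, `n`.
#' @export
run_band_sweep <- function(cfg, progress = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"), length(cfg$bands) >= 1)
  cells <- list()
  per_subject <- list()
  for (i in seq_len(cfg$n_subjects)) {
    cal <- .subject_calibration(cfg, i)
    for (b in cfg$bands) {
      spec_b <- filter_spec(band_low = b[1], band_high = b[2],
                            notch_freq = cfg$spec$notch_freq,
                            notch_q = cfg$spec$notch_q,
                            butter_order = cfg$spec$butter_order,
                            downsample_factor = cfg$spec$downsample_factor)
      ok <- tryCatch({
        design_filter_chain(spec_b, cal$raw$fs); TRUE
      }, error = function(e) {
        warning(sprintf("band %g-%g invalid at fs %g: %s", b[1], b[2],
                        cal$raw$fs, conditionMessage(e)))
        FALSE
      })
      if (!ok) next
      for (cond in c("CF", "OF")) {
        ds <- if (cond == "CF") {
          conventional_pipeline(cal$raw, spec_b, cfg$trial_window_s)
        } else {
          online_pipeline(cal$raw, spec_b, cfg$trial_window_s, cfg$buffer_s)
        }
        res <- cross_validate("PRK", ds, cfg$hp, seed = cal$setup$seed + 3L)
        per_subject[[length(per_subject) + 1L]] <- data.frame(
          subject = i, band = paste(b[1], b[2], sep = "-"),
          condition = cond, mcc = res$mcc, ba = res$ba
        )
      }
    }
    if (progress) {
      message(sprintf("[bandsweep] subject %d/%d done", i, cfg$n_subjects))
    }
  }
  ps <- do.call(rbind, per_subject)
  for (bn in unique(ps$band)) {
    for (cond in c("CF", "OF")) {
      v <- ps$mcc[ps$band == bn & ps$condition == cond]
      cells[[length(cells) + 1L]] <- data.frame(
        band = bn, condition = cond, mean_mcc = mean(v),
        se_mcc = stats::sd(v) / sqrt(length(v)), n = length(v)
      )
    }
  }
  out <- do.call(rbind, cells)
  attr(out, "per_subject") <- ps
  out
}

#' Run the online copy-phrase simulation study
#'
#' Selects the `n_simulation_subjects` subjects with the highest OF
#' calibration MCC (PRK) from a comparison report, retrains per-subject PRK
#' models on CF- and OF-processed calibration data, generates each subject's
#' copy-phrase sessions, and replays them through the online pipeline with
#' both saved models. Reports per-subject BA/MCC and the paired permutation
#' test between OF-trained and CF-trained models.
#'
#' @param cfg An [experiment_config()].
#' @param report A `study_report` from [run_filter_comparison()].
#' @param progress Emit log lines (default TRUE).
#' @return List with `per_subject` data frame, `test` (paired permutation
#'   test on MCC), and averaged confusion counts per condition.
#' @export
run_online_simulation <- function(cfg, report, progress = TRUE) {
  stopifnot(inherits(cfg, "experiment_config"),
            inherits(report, "study_report"))
  prk_of <- report$metrics[report$metrics$model == "PRK" &
                             report$metrics$condition == "OF", ]
  keep <- prk_of$subject[order(-prk_of$mcc)]
  keep <- sort(utils::head(keep, min(cfg$n_simulation_subjects, length(keep))))

  rows <- list()
  for (i in keep) {
    cal <- .subject_calibration(cfg, i)
    cf_ds <- conventional_pipeline(cal$raw, cfg$spec, cfg$trial_window_s)
    of_ds <- online_pipeline(cal$raw, cfg$spec, cfg$trial_window_s,
                             cfg$buffer_s)
    models <- list(CF = fit_prk(cf_ds, cfg$hp, cal$setup$seed + 3L),
                   OF = fit_prk(of_ds, cfg$hp, cal$setup$seed + 3L))
    for (ph in seq_len(cfg$sim_n_phrases)) {
      sched <- build_copy_phrase_schedule(
        cfg$sim_phrase, cfg$sim_target_word,
        n_inquiries_per_letter = cfg$sim_inquiries_per_letter,
        seed = cal$setup$seed + 100L + ph)
      params_ph <- cal$setup$params
      params_ph$seed <- cal$setup$seed + 200L + ph
      sess <- synthesize_session(sched, params_ph)
      for (cond in c("CF", "OF")) {
        sim <- simulate_copy_phrase(models[[cond]], sess, cfg$spec,
                                    scoring_rule(), cfg$trial_window_s,
                                    cfg$buffer_s)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = i, phrase = ph, trained_on = cond,
          ba = sim$ba, mcc = sim$mcc,
          tp = sim$confusion$TP, fn = sim$confusion$FN,
          fp = sim$confusion$FP, tn = sim$confusion$TN
        )
      }
    }
    if (progress) message(sprintf("[simulate] subject %d done", i))
  }
  per_subject <- do.call(rbind, rows)
  agg <- stats::aggregate(cbind(ba, mcc, tp, fn, fp, tn) ~ subject + trained_on,
                          per_subject, mean)
  of <- agg[agg$trained_on == "OF", ]
  cf <- agg[agg$trained_on == "CF", ]
  of <- of[order(of$subject), ]; cf <- cf[order(cf$subject), ]
  test <- paired_permutation_test(of$mcc, cf$mcc, cfg$n_permutations,
                                  cfg$alpha, df = nrow(of) - 1,
                                  seed = cfg$master_seed + 19L)
  list(per_subject = per_subject, by_subject = agg, test = test,
       mean_confusion = stats::aggregate(
         cbind(tp, fn, fp, tn) ~ trained_on, agg, mean),
       subjects = keep)
}

#' Write a study report to disk
#'
#' Emits tidy CSVs (`metrics.csv`, `tests.csv`, and `bandsweep.csv` /
#' `simulation.csv` when present), a JSON `manifest.json` (seeds and
#' configuration), and a plain-text `summary.txt` with per-model means, SDs
#' and p-values per condition. Output is byte-identical when re-written from
#' the same report.
#'
#' @param report A `study_report`, optionally with `$bandsweep` and
#'   `$simulation` components attached.
#' @param outdir Output directory.
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(report$metrics, file.path(outdir, "metrics.csv"))
  data.table::fwrite(report$tests, file.path(outdir, "tests.csv"))
  if (!is.null(report$bandsweep)) {
    data.table::fwrite(report$bandsweep, file.path(outdir, "bandsweep.csv"))
  }
  if (!is.null(report$simulation)) {
    data.table::fwrite(report$simulation$per_subject,
                       file.path(outdir, "simulation.csv"))
  }
  cfg <- report$config
  jsonlite::write_json(
    list(master_seed = cfg$master_seed, n_subjects = cfg$n_subjects,
         n_inquiries = cfg$n_inquiries, models = cfg$models,
         band = c(cfg$spec$band_low, cfg$spec$band_high),
         bands = cfg$bands, trial_window_s = cfg$trial_window_s,
         buffer_s = cfg$buffer_s, n_permutations = cfg$n_permutations,
         alpha = cfg$alpha, package_version = "0.1.0"),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)

  con <- file(file.path(outdir, "summary.txt"), "w")
  on.exit(close(con))
  writeLines("Filter application model performance (synthetic cohort)", con)
  writeLines(sprintf("n_subjects = %d, band = %g-%g Hz",
                     cfg$n_subjects, cfg$spec$band_low, cfg$spec$band_high),
             con)
  for (metric in c("MCC", "BA")) {
    writeLines(sprintf("\n%s", metric), con)
    for (m in unique(report$tests$model)) {
      r <- report$tests[report$tests$model == m &
                          report$tests$metric == metric, ]
      writeLines(sprintf(
        "  %-5s OF M (SD) %.3f (%.3f)   CF M (SD) %.3f (%.3f)   p = %.4g",
        m, r$of_mean, r$of_sd, r$cf_mean, r$cf_sd, r$p), con)
    }
  }
  invisible(outdir)
}
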