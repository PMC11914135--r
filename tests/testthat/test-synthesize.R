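test_that("all-zero parameters give an all-zero recording", {
  sched <- build_calibration_schedule(n_inquiries = 3, seed = 1)
  p <- synthesis_params(p300_amp_uV = 0, n200_amp_uV = 0,
                        background_sd_uV = 0, alpha_amp_uV = 0,
                        line_amp_uV = 0, blink_rate_per_s = 0, seed = 1)
  raw <- synthesize_session(sched, p)
  expect_true(all(raw$data == 0))
  expect_equal(nrow(raw$data), 19)
  expect_equal(ncol(raw$data),
               as.integer(ceiling((max(trial_onsets(sched)) + 1.5) * 300)))
})

test_that("noise-free target epochs reproduce the ERP template exactly", {
  # 1 Hz presentation so 0.5 s windows cannot overlap a neighbouring ERP
  sched <- build_calibration_schedule(n_inquiries = 10, rate = 1, seed = 2)
  p <- synthesis_params(background_sd_uV = 0, alpha_amp_uV = 0,
                        line_amp_uV = 0, blink_rate_per_s = 0,
                        latency_jitter_sd_s = 0, seed = 1)
  raw <- synthesize_session(sched, p, tail_s = 2)
  ex <- extract_trials(raw, 0.5)
  tpl <- erp_template(p, "Pz", (0:149) / 300)
  avg <- colMeans(ex$trials[ex$labels == 1, "Pz", ])
  expect_lt(max(abs(avg - tpl)), 1e-9)
  expect_true(all(ex$trials[ex$labels == 0, , ] == 0))
})

test_that("line-noise-only signal peaks at the 60 Hz periodogram bin", {
  sched <- build_calibration_schedule(n_inquiries = 3, seed = 1)
  p <- synthesis_params(p300_amp_uV = 0, n200_amp_uV = 0,
                        background_sd_uV = 0, alpha_amp_uV = 0,
                        line_amp_uV = 3, blink_rate_per_s = 0, seed = 9)
  raw <- synthesize_session(sched, p)
  x <- raw$data["Cz", ]
  spec <- Mod(stats::fft(x))^2
  freqs <- (seq_along(x) - 1) * 300 / length(x)
  half <- freqs <= 150
  peak_freq <- freqs[half][which.max(spec[half])]
  expect_lt(abs(peak_freq - 60), 300 / length(x) + 1e-9)
})

test_that("synthesis is bit-deterministic and linear in ERP amplitude", {
  sched <- build_calibration_schedule(n_inquiries = 5, seed = 4)
  p <- synthesis_params(seed = 12)
  expect_identical(synthesize_session(sched, p)$data,
                   synthesize_session(sched, p)$data)

  base <- synthesis_params(p300_amp_uV = 3, n200_amp_uV = 0,
                           background_sd_uV = 0, alpha_amp_uV = 0,
                           line_amp_uV = 0, blink_rate_per_s = 0,
                           latency_jitter_sd_s = 0, seed = 1)
  dbl <- synthesis_params(p300_amp_uV = 6, n200_amp_uV = 0,
                          background_sd_uV = 0, alpha_amp_uV = 0,
                          line_amp_uV = 0, blink_rate_per_s = 0,
                          latency_jitter_sd_s = 0, seed = 1)
  r1 <- synthesize_session(sched, base)
  r2 <- synthesize_session(sched, dbl)
  expect_equal(r2$data, 2 * r1$data, tolerance = 1e-12)

  # one ERP insertion per inquiry that has a target
  n_with_target <- sum(!vapply(sched$inquiries,
                               function(q) is.na(q$target_position), NA))
  touched <- which(colSums(abs(r1$data)) > 0)
  onsets <- trial_onsets(sched)[trial_labels(sched) == 1]
  expect_equal(length(onsets), n_with_target)
  # every nonzero sample lies within an ERP span after some target onset
  spans <- unlist(lapply(onsets, function(o) {
    (round(o * 300) + 1):(round((o + 0.8) * 300) + 1)
  }))
  expect_true(all(touched %in% spans))
})

test_that("invalid synthesis parameters are rejected", {
  expect_error(synthesis_params(background_sd_uV = -1), ">= 0")
  expect_error(synthesis_params(fs = 100, line_freq_Hz = 60), "twice")
  expect_error(synthesis_params(channel_names = c("Cz", "Cz")), "duplicate")
})

test_that("session round-trips through the CSV/JSON directory format", {
  raw <- cached_session(n_inquiries = 3, background_sd_uV = 3,
                        blink_rate_per_s = 0)
  dir <- file.path(tempdir(), "sess_io")
  write_session(raw, dir)
  back <- read_session(dir)
  expect_equal(back$fs, raw$fs)
  expect_equal(back$channel_names, raw$channel_names)
  expect_equal(unname(back$data), unname(raw$data), tolerance = 1e-10)
  expect_equal(trial_onsets(back$schedule), trial_onsets(raw$schedule))
  expect_equal(trial_labels(back$schedule), trial_labels(raw$schedule))

  # byte-stable rewrite
  before <- tools::md5sum(list.files(dir, full.names = TRUE))
  write_session(raw, dir)
  after <- tools::md5sum(list.files(dir, full.names = TRUE))
  expect_identical(before, after)
  unlink(dir, recursive = TRUE)
})
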