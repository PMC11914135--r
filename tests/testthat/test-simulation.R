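test_that("likelihood scoring follows the online criteria exactly", {
  # boundary: exactly 1.0 is negative
  cm <- score_likelihoods(rep(1.0, 10), rep(c(1L, 0L), 5))
  expect_equal(c(cm$TP, cm$FP), c(0, 0))
  expect_equal(c(cm$FN, cm$TN), c(5, 5))

  cm2 <- score_likelihoods(c(2.0, 0.5, 1.5, 0.9), c(1L, 1L, 0L, 0L))
  expect_equal(c(cm2$TP, cm2$FN, cm2$FP, cm2$TN), c(1, 1, 1, 1))

  expect_error(score_likelihoods(1:3, c(0L, 1L)), "equal length")
})

test_that("scoring matches an independent recount on random inputs", {
  set.seed(41)
  lik <- exp(rnorm(1000))
  labels <- rbinom(1000, 1, 0.1)
  cm <- score_likelihoods(lik, labels)
  expect_equal(cm$TP, sum(labels == 1 & lik > 1))
  expect_equal(cm$FN, sum(labels == 1 & lik <= 1))
  expect_equal(cm$FP, sum(labels == 0 & lik > 1))
  expect_equal(cm$TN, sum(labels == 0 & lik <= 1))
  expect_equal(cm$TP + cm$FN, sum(labels))
  expect_equal(cm$FP + cm$TN, sum(labels == 0))
})

test_that("raising the threshold never increases TP or FP", {
  set.seed(6)
  lik <- exp(rnorm(500)); labels <- rbinom(500, 1, 0.1)
  prev <- score_likelihoods(lik, labels, scoring_rule(0.5))
  for (thr in c(1.0, 1.5, 3.0)) {
    cur <- score_likelihoods(lik, labels, scoring_rule(thr))
    expect_lte(cur$TP, prev$TP)
    expect_lte(cur$FP, prev$FP)
    prev <- cur
  }
})

test_that("a separably trained model transfers perfectly to a clean session", {
  # 1 Hz presentation keeps epochs free of neighbouring-trial ERP overlap
  cal_sched <- build_calibration_schedule(n_inquiries = 12, rate = 1,
                                          seed = 2)
  clean <- synthesis_params(background_sd_uV = 0, alpha_amp_uV = 0,
                            line_amp_uV = 0, blink_rate_per_s = 0,
                            latency_jitter_sd_s = 0, seed = 3)
  cal <- synthesize_session(cal_sched, clean, tail_s = 2)
  model <- fit_prk(online_pipeline(cal))

  cp_sched <- build_copy_phrase_schedule("go to it", "it", 3, rate = 1,
                                         seed = 4)
  sess <- synthesize_session(cp_sched, clean, tail_s = 2)
  sim <- simulate_copy_phrase(model, sess)
  expect_equal(sim$ba, 1.0)
  expect_equal(sim$mcc, 1.0)
  # count conservation: every inquiry contains its target
  n_inq <- length(cp_sched$inquiries)
  expect_equal(sim$confusion$TP + sim$confusion$FN, n_inq)
  expect_equal(sim$confusion$FP + sim$confusion$TN, n_inq * 9)
  # records allow re-scoring under other rules without re-simulation
  expect_equal(nrow(sim$records), n_inq * 10)
  expect_equal(sum(sim$records$label), n_inq)
})

test_that("a model trained on signal-free data simulates at chance", {
  cal <- cached_session(n_inquiries = 15, p300_amp_uV = 0,
                        background_sd_uV = 3, seed = 60,
                        latency_jitter_sd_s = 0)
  params0 <- synthesis_params(p300_amp_uV = 0, n200_amp_uV = 0,
                              background_sd_uV = 3, seed = 61)
  model <- fit_prk(online_pipeline(cal))
  mccs <- vapply(1:10, function(s) {
    sched <- build_copy_phrase_schedule("abcde", "abc", 3, seed = 70 + s)
    p <- params0
    p$seed <- 80L + s
    sim <- simulate_copy_phrase(model, synthesize_session(sched, p))
    sim$mcc
  }, 1)
  expect_true(all(mccs >= -0.2 & mccs <= 0.2))
})

test_that("simulation insists on a matching montage and OF processing", {
  ds <- separable_dataset()
  model <- fit_prk(ds)   # 4-channel toy montage
  sess <- cached_session(n_inquiries = 3)
  expect_error(simulate_copy_phrase(model, sess), "montage")
})
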