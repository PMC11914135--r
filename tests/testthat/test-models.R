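test_that("all three models separate noiseless separable classes perfectly", {
  ds <- separable_dataset()
  for (kind in c("PRK", "LR", "RLDA")) {
    m <- bciparity:::.fit_model(kind, ds, model_hyperparams(), 1)
    lik <- predict_likelihoods(m, ds)
    expect_true(all(is.finite(lik)) && all(lik > 0))
    cm <- confusion_counts(ds$labels, as.integer(lik > 1))
    expect_equal(balanced_accuracy(cm), 1.0, info = kind)
    # target-like trial above 1, nontarget-like below 1
    expect_gt(lik[1], 1)
    expect_lt(lik[length(lik)], 1)
  }
})

test_that("label-permuted data scores at chance under cross-validation", {
  ds <- null_dataset(n = 330, seed = 7)
  res <- cross_validate("PRK", ds, model_hyperparams(), seed = 21)
  expect_gte(res$mcc, -0.15)
  expect_lte(res$mcc, 0.15)
})

test_that("RDA with lambda=1, gamma=1 reduces to a distance-to-mean rule", {
  set.seed(4)
  feats <- matrix(rnorm(200 * 6), 200, 6)
  labels <- rep(c(1L, 0L), each = 100)
  feats[labels == 1, 1] <- feats[labels == 1, 1] + 2
  rda <- bciparity:::.fit_rda(feats, labels, lambda = 1, gamma = 1)
  # both covariances are the same scaled identity
  expect_equal(rda$R1, rda$R0, tolerance = 1e-12)
  expect_equal(rda$R1, diag(diag(rda$R1)), tolerance = 1e-12)
  sigma2 <- diag(rda$R1)[1]^2
  score <- bciparity:::.rda_score(rda, feats)
  closed <- (colSums((t(feats) - rda$mu0)^2) -
               colSums((t(feats) - rda$mu1)^2)) / (2 * sigma2)
  expect_equal(score, closed, tolerance = 1e-8)
})

test_that("PRK class-conditional KDEs integrate to one", {
  ds <- cached_trialset()
  m <- fit_prk(ds)
  for (cls in c("target", "nontarget")) {
    k <- m$kde[[cls]]
    grid <- seq(min(k$centers) - 6 * k$h, max(k$centers) + 6 * k$h,
                length.out = 4000)
    dens <- bciparity:::.kde_eval(grid, k$centers, k$h)
    integral <- sum(dens) * diff(grid[1:2])
    expect_equal(integral, 1, tolerance = 0.01)
  }
})

test_that("PRK feature count equals the sum of per-channel components", {
  ds <- cached_trialset()
  m <- fit_prk(ds)
  per_channel <- vapply(m$channels, function(ch) ncol(ch$rotation), 1L)
  expect_equal(m$n_features, sum(per_channel))
  # dropping one channel removes exactly its block
  keep <- 2:dim(ds$trials)[2]
  ds2 <- bciparity:::.new_trial_dataset(
    ds$trials[, keep, , drop = FALSE], ds$labels, ds$trial_window_s,
    ds$effective_fs, ds$provenance, ds$band, ds$channel_names[keep])
  m2 <- fit_prk(ds2)
  expect_equal(length(m2$channels), length(m$channels) - 1L)
})

test_that("logistic model handles degenerate and rescaled inputs", {
  # all-zero trials: intercept-only fit predicts the class prior
  n <- 60
  zero <- bciparity:::.new_trial_dataset(
    array(0, c(n, 2, 10)), rep(c(1L, 0L), c(12, 48)), 10 / 150, 150, "CF",
    c(1, 20), c("a", "b"))
  m <- fit_logistic(zero)
  lik <- predict_likelihoods(m, zero)
  prior_odds <- 12 / 48
  expect_equal(lik, rep(prior_odds, n), tolerance = 1e-6)

  # doubling features pre-standardization leaves predictions unchanged
  ds <- cached_trialset()
  m1 <- fit_logistic(ds)
  ds2 <- ds
  ds2$trials <- ds$trials * 2
  m2 <- fit_logistic(ds2)
  expect_equal(predict_likelihoods(m2, ds2), predict_likelihoods(m1, ds),
               tolerance = 1e-6)
})

test_that("SPD geometry primitives satisfy their closed forms", {
  M <- matrix(c(2, 0.5, 0.5, 1), 2)
  expect_equal(spd_mean(list(M, M)), M, tolerance = 1e-10)
  a <- c(1, 4); b <- c(9, 16)
  G <- spd_mean(list(diag(a), diag(b)))
  expect_equal(G, diag(sqrt(a * b)), tolerance = 1e-8)
  # tangent map of the reference at itself is the zero vector
  Z <- tangent_space(list(M), M)
  expect_equal(as.numeric(Z), rep(0, 3), tolerance = 1e-10)
  # dimension d(d+1)/2
  C4 <- diag(4) + 0.1
  expect_equal(ncol(tangent_space(list(C4), diag(4))), 10)
})

test_that("cross-validation is deterministic and exact on separable data", {
  ds <- separable_dataset(n_target = 20, n_nontarget = 80)
  r1 <- cross_validate("PRK", ds, seed = 5)
  r2 <- cross_validate("PRK", ds, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$ba, 1.0)
  expect_equal(r1$mcc, 1.0)
})

test_that("thresholding likelihoods at 1.0 reproduces in-fold classifications", {
  ds <- cached_trialset()
  hp <- model_hyperparams(cv_folds = 5)
  res <- cross_validate("RLDA", ds, hp, seed = 9)
  folds <- bciparity:::.stratified_folds(ds$labels, 5, seed = 9)
  f <- 1L
  tr <- bciparity:::.subset_trials(ds, which(folds != f))
  te <- bciparity:::.subset_trials(ds, which(folds == f))
  m <- fit_rlda(tr, hp, 9)
  pred <- as.integer(predict_likelihoods(m, te) > 1.0)
  cm <- confusion_counts(te$labels, pred)
  expect_equal(balanced_accuracy(cm), res$fold_ba[f])
  expect_equal(matthews_cc(cm), res$fold_mcc[f])
})

test_that("model fitting rejects invalid inputs", {
  ds <- separable_dataset()
  one_class <- ds
  one_class$labels <- rep(0L, length(ds$labels))
  expect_error(fit_prk(one_class), "both")
  expect_error(fit_logistic(one_class), "both")
  expect_error(fit_rlda(one_class), "both")

  m <- fit_prk(ds)
  wrong <- separable_dataset(n_channels = 3)
  expect_error(predict_likelihoods(m, wrong), "shape")
})

test_that("model save/load round-trips through the archive format", {
  ds <- separable_dataset()
  m <- fit_prk(ds)
  path <- file.path(tempdir(), "models", "prk_test")
  save_model(m, path)
  back <- load_model(path)
  expect_identical(predict_likelihoods(back, ds), predict_likelihoods(m, ds))
  manifest <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(manifest$kind, "PRK")
  unlink(dirname(path), recursive = TRUE)
})
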