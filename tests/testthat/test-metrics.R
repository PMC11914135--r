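test_that("balanced accuracy follows its defining arithmetic", {
  expect_equal(balanced_accuracy(confusion_matrix(100, 1000, 0, 0)), 1.0)
  expect_equal(balanced_accuracy(confusion_matrix(80, 600, 400, 20)), 0.7)
  expect_equal(balanced_accuracy(confusion_matrix(50, 500, 500, 50)), 0.5)
  expect_error(balanced_accuracy(confusion_matrix(0, 10, 5, 0)), "undefined")
})

test_that("MCC matches its formula, conventions and symmetries", {
  expect_equal(matthews_cc(confusion_matrix(99, 1001, 0, 0)), 1.0)
  # classifier emitting a single class: chance convention
  expect_equal(matthews_cc(confusion_matrix(0, 900, 0, 100)), 0)
  expect_equal(matthews_cc(confusion_matrix(tp = 90, tn = 900, fp = 100,
                                            fn = 10)),
               80000 / sqrt(190 * 100 * 1000 * 910))
  # swapping predicted labels negates MCC
  cm <- confusion_matrix(tp = 70, tn = 800, fp = 200, fn = 30)
  flipped <- confusion_matrix(tp = 200, tn = 30, fp = 70, fn = 800)
  expect_equal(matthews_cc(flipped), -matthews_cc(cm))
})

test_that("BA and MCC agree with brute-force recounts on random predictions", {
  set.seed(31)
  for (rep in 1:20) {
    n <- 1000
    labels <- rbinom(n, 1, 0.1)
    if (sum(labels) == 0 || sum(labels) == n) next
    preds <- rbinom(n, 1, runif(1, 0.05, 0.5))
    cm <- confusion_counts(labels, preds)
    # independent recount, element by element
    tp <- 0; tn <- 0; fp <- 0; fn <- 0
    for (i in seq_len(n)) {
      if (labels[i] == 1 && preds[i] == 1) tp <- tp + 1
      else if (labels[i] == 0 && preds[i] == 0) tn <- tn + 1
      else if (labels[i] == 0 && preds[i] == 1) fp <- fp + 1
      else fn <- fn + 1
    }
    expect_equal(c(cm$TP, cm$TN, cm$FP, cm$FN), c(tp, tn, fp, fn))
    tpr <- tp / (tp + fn); tnr <- tn / (tn + fp)
    expect_equal(balanced_accuracy(cm), (tpr + tnr) / 2)
    den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    expect_equal(matthews_cc(cm),
                 if (den == 0) 0 else (tp * tn - fp * fn) / den)
  }
})

test_that("permutation p-value matches exhaustive enumeration at n = 4", {
  d <- c(1, 2, 3, 4)
  b <- rep(0, 4)
  # exact null: all 2^4 sign assignments
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), 4)))
  tstat <- function(x) mean(x) / (sd(x) / 2)
  t_exact <- apply(signs * rep(d, each = 16), 1, tstat)
  t_obs <- tstat(d)
  p_exact <- mean(abs(t_exact) >= abs(t_obs) - 1e-12)
  res <- paired_permutation_test(d, b, n_permutations = 50000, seed = 2)
  expect_equal(res$t_observed, t_obs)
  expect_lt(abs(res$p_value - p_exact), 0.02)
})

test_that("permutation test reports the t-quantile threshold and handles ties", {
  a <- rnorm(30); res <- paired_permutation_test(a, a, seed = 1)
  expect_equal(res$t_observed, 0)
  expect_equal(res$p_value, 1.0)
  res30 <- paired_permutation_test(rnorm(30, 1), rnorm(30), df = 29, seed = 3)
  expect_equal(res30$threshold, qt(0.975, df = 29))
  expect_error(paired_permutation_test(1:3, 1:4), "equal length")
  expect_error(paired_permutation_test(c(1, NA), c(0, 0)), "missing")
})

test_that("swapping the paired vectors negates t and preserves p", {
  set.seed(17)
  a <- rnorm(20, 0.3); b <- rnorm(20)
  r1 <- paired_permutation_test(a, b, n_permutations = 5000, seed = 8)
  r2 <- paired_permutation_test(b, a, n_permutations = 5000, seed = 8)
  expect_equal(r1$t_observed, -r2$t_observed)
  expect_equal(r1$p_value, r2$p_value)
})

test_that("the permutation test is calibrated under the null", {
  set.seed(12)
  pvals <- replicate(200, {
    a <- rnorm(30); b <- rnorm(30)
    paired_permutation_test(a, b, n_permutations = 2000,
                            seed = sample.int(1e6, 1))$p_value
  })
  expect_gte(mean(pvals < 0.05), 0.02)
  expect_lte(mean(pvals < 0.05), 0.08)
})
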