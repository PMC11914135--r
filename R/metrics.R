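#' Build a confusion matrix from counts
#'
#' @param tp,tn,fp,fn Non-negative integer counts.
#' @return A `confusion_matrix` list.
#' @export
confusion_matrix <- function(tp, tn, fp, fn) {
  counts <- c(TP = tp, TN = tn, FP = fp, FN = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' Confusion counts from labels and predictions
#'
#' @param labels Binary true labels (1 = target).
#' @param predictions Binary predicted labels.
#' @return A `confusion_matrix`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop("labels and predictions must have equal length")
  }
  confusion_matrix(
    tp = sum(labels == 1 & predictions == 1),
    tn = sum(labels == 0 & predictions == 0),
    fp = sum(labels == 0 & predictions == 1),
    fn = sum(labels == 1 & predictions == 0)
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix TP=%d FN=%d FP=%d TN=%d>\n",
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

#' Balanced accuracy
#'
#' The mean of sensitivity (true positive rate) and specificity (true
#' negative rate): `BA = (TPR + TNR) / 2`. Robust to the heavy non-target
#' majority of RSVP calibration data, where plain accuracy saturates.
#'
#' @param cm A `confusion_matrix`.
#' @return BA in `[0, 1]`; error if either class is empty.
#' @export
balanced_accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$TP + cm$FN == 0 || cm$TN + cm$FP == 0) {
    stop("balanced accuracy undefined: one class has no items")
  }
  (cm$TP / (cm$TP + cm$FN) + cm$TN / (cm$TN + cm$FP)) / 2
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, ranging
#' from -1 (total disagreement) through 0 (chance) to +1 (perfect
#' prediction). When any denominator factor is zero (e.g. the classifier
#' emits a single class) the chance value 0 is returned.
#'
#' @param cm A `confusion_matrix`.
#' @return MCC in `[-1, 1]`.
#' @export
matthews_cc <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- as.numeric(cm$TP); tn <- as.numeric(cm$TN)
  fp <- as.numeric(cm$FP); fn <- as.numeric(cm$FN)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' Paired sign-flip permutation t-test
#'
#' Tests whether the per-subject paired differences `a - b` have zero mean.
#' The observed statistic is the one-sample t on the differences; the null
#' distribution is built from `n_permutations` seeded random sign flips of
#' the differences, with the two-tailed Monte-Carlo p-value
#' `(1 + #\{|t_perm| >= |t_obs|\}) / (1 + n_permutations)`. The two-tailed t
#' quantile at `alpha` with `df` degrees of freedom is reported alongside as
#' the cluster-forming threshold; on scalar per-subject metrics the cluster
#' test degenerates to this single-point sign-flip test.
#'
#' @param a,b Paired per-subject metric vectors of equal length >= 2.
#' @param n_permutations Number of sign-flip draws (default 50000).
#' @param alpha Two-tailed significance level (default 0.05).
#' @param df Degrees of freedom for the reported threshold (default
#'   `length(a) - 1`).
#' @param seed Integer seed for the sign flips.
#' @return List with `t_observed`, `p_value`, `threshold`, `mean_diff`,
#'   `n_permutations`, `df`.
#' @export
paired_permutation_test <- function(a, b, n_permutations = 50000,
                                    alpha = 0.05, df = length(a) - 1,
                                    seed = 1L) {
  if (length(a) != length(b) || length(a) < 2) {
    stop("a and b must be paired vectors of equal length >= 2")
  }
  if (anyNA(a) || anyNA(b)) stop("missing values are not allowed")
  stopifnot(n_permutations >= 1, alpha > 0, alpha < 1)
  d <- a - b
  n <- length(d)
  threshold <- stats::qt(1 - alpha / 2, df = df)
  if (all(d == 0)) {
    return(list(t_observed = 0, p_value = 1, threshold = threshold,
                mean_diff = 0, n_permutations = n_permutations, df = df))
  }
  tstat <- function(m, ssq) {
    v <- (ssq - n * m^2) / (n - 1)
    ifelse(v <= 0, sign(m) * Inf, m / sqrt(v / n))
  }
  ssq <- sum(d^2)                      # invariant under sign flips
  t_obs <- tstat(mean(d), ssq)
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_permutations * n, replace = TRUE),
                  n_permutations, n)
  m_perm <- as.numeric(signs %*% d) / n
  t_perm <- tstat(m_perm, ssq)
  p <- (1 + sum(abs(t_perm) >= abs(t_obs))) / (1 + n_permutations)
  list(t_observed = t_obs, p_value = p, threshold = threshold,
       mean_diff = mean(d), n_permutations = n_permutations, df = df)
}
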