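#' Likelihood scoring rule
#'
#' The online decision rule: a trial is called a target when its likelihood
#' ratio is strictly greater than `threshold`; a likelihood exactly equal to
#' the threshold is classified negative.
#'
#' @param threshold Likelihood cutoff (default 1.0).
#' @return A `scoring_rule` list.
#' @export
scoring_rule <- function(threshold = 1.0) {
  structure(list(threshold = threshold, positive_if = "strictly_greater"),
            class = "scoring_rule")
}

#' Score likelihoods against labels into a confusion matrix
#'
#' Applies the four online scoring criteria: targets with likelihood
#' > threshold are TP, targets <= threshold are FN; non-targets > threshold
#' are FP, non-targets <= threshold are TN.
#'
#' @param likelihoods Numeric vector of likelihood ratios.
#' @param labels Binary labels (1 = target), same length.
#' @param rule A [scoring_rule()].
#' @return A `confusion_matrix`.
#' @export
score_likelihoods <- function(likelihoods, labels, rule = scoring_rule()) {
  if (length(likelihoods) != length(labels)) {
    stop("likelihoods and labels must have equal length")
  }
  confusion_counts(labels, as.integer(likelihoods > rule$threshold))
}

#' Replay a copy-phrase session through the online pipeline and a model
#'
#' Simulates closed-loop use: the session is processed inquiry-by-inquiry
#' through the online-parity pipeline (never the conventional one), the
#' saved model produces per-trial likelihood ratios, and the ratios are
#' scored into a confusion matrix with the online threshold rule. BA and MCC
#' are computed from the matrix; every (inquiry, label, likelihood) record is
#' kept so alternative decision rules can be layered without re-simulation.
#'
#' @param model A `trained_model` whose montage and trial shape match the
#'   session.
#' @param session A `raw_session` (typically from
#'   [build_copy_phrase_schedule()] + [synthesize_session()]).
#' @param spec A [filter_spec()].
#' @param rule A [scoring_rule()].
#' @param trial_window_s,buffer_s Online epoching parameters as in
#'   [online_pipeline()].
#' @return A `simulation_result`: `confusion` matrix, `ba`, `mcc`, and a
#'   `records` data frame (inquiry, label, likelihood).
#' @export
simulate_copy_phrase <- function(model, session, spec = filter_spec(),
                                 rule = scoring_rule(),
                                 trial_window_s = 0.5, buffer_s = 1.0) {
  stopifnot(inherits(model, "trained_model"), inherits(session, "raw_session"))
  if (!identical(model$channel_names, session$channel_names)) {
    stop("channel montage of the session does not match the trained model")
  }
  ds <- online_pipeline(session, spec, trial_window_s, buffer_s)
  stopifnot(identical(ds$provenance, "OF"))
  lik <- predict_likelihoods(model, ds)
  cm <- score_likelihoods(lik, ds$labels, rule)
  stims <- vapply(session$schedule$inquiries,
                  function(q) length(q$stimulus_onsets), 1L)
  structure(
    list(confusion = cm,
         ba = balanced_accuracy(cm),
         mcc = matthews_cc(cm),
         records = data.frame(
           inquiry = rep(seq_along(stims), stims),
           label = ds$labels,
           likelihood = lik
         ),
         rule = rule),
    class = "simulation_result"
  )
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("<simulation_result: BA %.3f, MCC %.3f, TP=%d FN=%d FP=%d TN=%d>\n",
              x$ba, x$mcc, x$confusion$TP, x$confusion$FN, x$confusion$FP,
              x$confusion$TN))
  invisible(x)
}
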