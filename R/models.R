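#' Model hyperparameters
#'
#' Collects the tunable settings of the three trial classifiers and the
#' cross-validation harness.
#'
#' @param lr_C Inverse regularization strength of the L2 logistic regression
#'   (default 0.0183, fixed rather than grid-searched).
#' @param pca_variance_kept Per-channel cumulative variance retained by the
#'   PRK projection step (default 0.95).
#' @param rda_lambda Shrinkage of each class covariance toward the pooled
#'   covariance (default 0.9).
#' @param rda_gamma Shrinkage toward a scaled identity (default 0.1).
#' @param kde_bandwidth_rule Bandwidth rule for the score densities; only
#'   `"silverman"` is implemented.
#' @param xdawn_filters_per_class Spatial filters retained per class in the
#'   Riemannian LDA (default 2).
#' @param cv_folds Stratified cross-validation folds (default 10).
#' @param selection_metric Metric maximized when a hyperparameter grid is
#'   supplied (default `"MCC"`).
#' @param lr_max_iter Iteration cap for the logistic solver (default 1000).
#' @return A `model_hyperparams` list.
#' @export
model_hyperparams <- function(lr_C = 0.0183,
                              pca_variance_kept = 0.95,
                              rda_lambda = 0.9, rda_gamma = 0.1,
                              kde_bandwidth_rule = "silverman",
                              xdawn_filters_per_class = 2,
                              cv_folds = 10,
                              selection_metric = c("MCC", "BA"),
                              lr_max_iter = 1000) {
  stopifnot(pca_variance_kept > 0, pca_variance_kept <= 1,
            rda_lambda >= 0, rda_lambda <= 1,
            rda_gamma >= 0, rda_gamma <= 1,
            cv_folds >= 2, lr_C > 0)
  structure(
    list(
      lr = list(inverse_regularization_C = lr_C, max_iter = lr_max_iter),
      prk = list(pca_variance_kept = pca_variance_kept,
                 rda_lambda = rda_lambda, rda_gamma = rda_gamma,
                 kde_bandwidth_rule = match.arg(kde_bandwidth_rule,
                                                "silverman")),
      rlda = list(xdawn_filters_per_class = as.integer(xdawn_filters_per_class)),
      cv_folds = as.integer(cv_folds),
      selection_metric = match.arg(selection_metric)
    ),
    class = "model_hyperparams"
  )
}

.check_two_classes <- function(labels) {
  if (length(unique(labels)) < 2) {
    stop("both target and non-target trials are required for fitting")
  }
}

# flatten n x C x T trials to n x (C*T)
.flatten_trials <- function(trials) {
  d <- dim(trials)
  matrix(trials, d[1], d[2] * d[3])
}

# ---------------------------------------------------------------------------
# PRK: channel-wise PCA -> regularized discriminant analysis -> kernel
# density likelihoods

.silverman_bw <- function(s) {
  n <- length(s)
  sig <- min(stats::sd(s), stats::IQR(s) / 1.349)
  if (!is.finite(sig) || sig <= 0) sig <- stats::sd(s)
  if (!is.finite(sig) || sig <= 0) sig <- 0
  max(0.9 * sig * n^(-1 / 5), 1e-8)
}

.kde_eval <- function(x, centers, h) {
  vapply(x, function(xi) mean(stats::dnorm((xi - centers) / h)) / h, 1)
}

.fit_rda <- function(feats, labels, lambda, gamma) {
  d <- ncol(feats)
  i1 <- labels == 1L; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  mu1 <- colMeans(feats[i1, , drop = FALSE])
  mu0 <- colMeans(feats[i0, , drop = FALSE])
  S1 <- stats::cov(feats[i1, , drop = FALSE])
  S0 <- stats::cov(feats[i0, , drop = FALSE])
  Sp <- ((n1 - 1) * S1 + (n0 - 1) * S0) / (n1 + n0 - 2)
  shrink <- function(Sc) {
    Sl <- (1 - lambda) * Sc + lambda * Sp
    Sg <- (1 - gamma) * Sl + gamma * (sum(diag(Sl)) / d) * diag(d)
    Sg + diag(1e-12, d)   # absolute floor for exactly degenerate classes
  }
  chol_or_stop <- function(S) {
    tryCatch(chol(S), error = function(e) {
      stop("singular class covariance despite regularization")
    })
  }
  R1 <- chol_or_stop(shrink(S1))
  R0 <- chol_or_stop(shrink(S0))
  list(mu1 = mu1, mu0 = mu0, R1 = R1, R0 = R0,
       logdet1 = 2 * sum(log(diag(R1))), logdet0 = 2 * sum(log(diag(R0))))
}

# log N(x; mu1, S1) - log N(x; mu0, S0) per row of feats
.rda_score <- function(rda, feats) {
  quad <- function(R, mu) {
    z <- backsolve(R, t(feats) - mu, transpose = TRUE)
    colSums(z^2)
  }
  0.5 * (quad(rda$R0, rda$mu0) - quad(rda$R1, rda$mu1)) +
    0.5 * (rda$logdet0 - rda$logdet1)
}

#' Fit the PRK classifier (channel-wise PCA + RDA + KDE)
#'
#' Per channel, learns a principal-component basis on the trials'
#' time-sample matrix, keeping the smallest component count whose cumulative
#' variance reaches `pca_variance_kept`. Projected scores are concatenated
#' across channels and fed to a regularized discriminant analysis whose class
#' covariances are shrunk toward the pooled covariance (`lambda`) and a
#' scaled identity (`gamma`). The one-dimensional discriminant score (target
#' minus non-target Gaussian log-likelihood) is then modeled per class with a
#' Gaussian kernel density estimator (Silverman bandwidth), yielding
#' per-trial likelihood ratios.
#'
#' @param data A `trial_dataset` containing both classes.
#' @param hp A [model_hyperparams()].
#' @param seed Integer seed (kept for interface symmetry; the fit itself is
#'   deterministic).
#' @return A `trained_model` with `kind = "PRK"`.
#' @export
fit_prk <- function(data, hp = model_hyperparams(), seed = 1L) {
  stopifnot(inherits(data, "trial_dataset"))
  .check_two_classes(data$labels)
  trials <- data$trials
  d <- dim(trials)
  if (d[1] <= d[2]) stop("need more trials than channels")
  labels <- data$labels

  channels <- vector("list", d[2])
  feats <- NULL
  for (c in seq_len(d[2])) {
    X <- trials[, c, ]
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd(Xc, nu = 0)
    var <- sv$d^2
    k <- which(cumsum(var) / sum(var) >= hp$prk$pca_variance_kept)[1]
    if (is.na(k) || sum(var) == 0) k <- 1L
    rot <- sv$v[, seq_len(k), drop = FALSE]
    channels[[c]] <- list(mean = mu, rotation = rot)
    feats <- cbind(feats, Xc %*% rot)
  }

  rda <- .fit_rda(feats, labels, hp$prk$rda_lambda, hp$prk$rda_gamma)
  scores <- .rda_score(rda, feats)
  s1 <- scores[labels == 1L]; s0 <- scores[labels == 0L]
  kde <- list(target = list(centers = s1, h = .silverman_bw(s1)),
              nontarget = list(centers = s0, h = .silverman_bw(s0)))

  structure(
    list(kind = "PRK", channels = channels, rda = rda, kde = kde,
         hyperparams = hp$prk,
         n_features = ncol(feats),
         trial_shape = d[2:3], channel_names = data$channel_names,
         band = data$band, provenance = data$provenance, seed = seed),
    class = "trained_model"
  )
}

.prk_features <- function(model, trials) {
  feats <- NULL
  for (c in seq_along(model$channels)) {
    ch <- model$channels[[c]]
    feats <- cbind(feats, sweep(trials[, c, , drop = TRUE], 2, ch$mean) %*%
                     ch$rotation)
  }
  feats
}

# ---------------------------------------------------------------------------
# L2 logistic regression on standardized flattened trials

#' Fit the L2-penalized logistic regression classifier
#'
#' Features are the flattened (channels x samples) trials, standardized per
#' feature with training-set mean and standard deviation (zero-variance
#' features stay at zero after centering). The ridge-penalized logistic model
#' is fit at the fixed inverse regularization `C`; on glmnet's scale this is
#' `lambda = 1 / (n * C)`.
#'
#' @inheritParams fit_prk
#' @return A `trained_model` with `kind = "LR"`.
#' @export
fit_logistic <- function(data, hp = model_hyperparams(), seed = 1L) {
  stopifnot(inherits(data, "trial_dataset"))
  .check_two_classes(data$labels)
  X <- .flatten_trials(data$trials)
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  scale_ <- ifelse(sdv > 0, sdv, 1)
  Xs <- sweep(sweep(X, 2, mu), 2, scale_, "/")
  lam <- 1 / (n * hp$lr$inverse_regularization_C)
  if (all(sdv == 0)) {
    # intercept-only: every prediction is the class prior
    return(structure(
      list(kind = "LR", fit = NULL, prior = mean(data$labels),
           lambda = lam, center = mu, scale = scale_,
           trial_shape = dim(data$trials)[2:3],
           channel_names = data$channel_names,
           band = data$band, provenance = data$provenance, seed = seed),
      class = "trained_model"))
  }
  fit <- glmnet::glmnet(Xs, factor(data$labels, levels = c(0, 1)),
                        family = "binomial", alpha = 0,
                        lambda = c(100 * lam, 10 * lam, lam),
                        standardize = FALSE, thresh = 1e-8,
                        maxit = hp$lr$max_iter * 100)
  structure(
    list(kind = "LR", fit = fit, lambda = lam, center = mu, scale = scale_,
         trial_shape = dim(data$trials)[2:3],
         channel_names = data$channel_names,
         band = data$band, provenance = data$provenance, seed = seed),
    class = "trained_model"
  )
}

# ---------------------------------------------------------------------------
# xDAWN + Riemannian tangent space + shrinkage LDA

.xdawn_filters <- function(trials, labels, n_filters) {
  d <- dim(trials)
  Tn <- d[3]
  Sx <- matrix(0, d[2], d[2])
  for (i in seq_len(d[1])) {
    X <- trials[i, , ]
    Sx <- Sx + tcrossprod(X)
  }
  Sx <- Sx / (d[1] * Tn)
  Sx <- Sx + diag(1e-10 * mean(diag(Sx)), d[2])
  B <- chol(Sx)
  Binv <- backsolve(B, diag(d[2]))
  one_class <- function(cls) {
    P <- apply(trials[labels == cls, , , drop = FALSE], c(2, 3), mean)
    A <- tcrossprod(P) / Tn
    K <- t(Binv) %*% A %*% Binv
    e <- eigen((K + t(K)) / 2, symmetric = TRUE)
    V <- Binv %*% e$vectors[, seq_len(n_filters), drop = FALSE]
    list(filters = t(V), prototype = P)
  }
  list(target = one_class(1L), nontarget = one_class(0L))
}

.super_cov <- function(X, xd, V_all) {
  S <- rbind(xd$target$filters %*% xd$target$prototype,
             xd$nontarget$filters %*% xd$nontarget$prototype,
             V_all %*% X)
  Cv <- tcrossprod(S) / (ncol(S) - 1)
  Cv + diag(1e-10 * mean(diag(Cv)), nrow(Cv))
}

.rlda_covs <- function(model_or_xd, trials) {
  xd <- model_or_xd
  V_all <- rbind(xd$target$filters, xd$nontarget$filters)
  lapply(seq_len(dim(trials)[1]), function(i) {
    .super_cov(trials[i, , ], xd, V_all)
  })
}

#' Fit the Riemannian LDA classifier (xDAWN + tangent space + shrinkage LDA)
#'
#' Estimates `xdawn_filters_per_class` spatial filters per class by a
#' generalized eigendecomposition of the class-average evoked response
#' covariance against the overall signal covariance. Each trial is expanded
#' into a "super trial" (filtered class prototypes stacked on the filtered
#' trial) whose covariance matrix is mapped to the tangent space at the
#' affine-invariant mean of the training covariances; a Ledoit-Wolf
#' shrinkage linear discriminant is fit on the tangent vectors.
#'
#' @inheritParams fit_prk
#' @return A `trained_model` with `kind = "RLDA"`.
#' @export
fit_rlda <- function(data, hp = model_hyperparams(), seed = 1L) {
  stopifnot(inherits(data, "trial_dataset"))
  .check_two_classes(data$labels)
  trials <- data$trials
  labels <- data$labels
  xd <- .xdawn_filters(trials, labels, hp$rlda$xdawn_filters_per_class)
  covs <- .rlda_covs(xd, trials)
  M <- spd_mean(covs, tol = 1e-8, max_iter = 50)
  Z <- tangent_space(covs, M)

  i1 <- labels == 1L
  mu1 <- colMeans(Z[i1, , drop = FALSE])
  mu0 <- colMeans(Z[!i1, , drop = FALSE])
  Zc <- rbind(sweep(Z[i1, , drop = FALSE], 2, mu1),
              sweep(Z[!i1, , drop = FALSE], 2, mu0))
  lw <- .ledoit_wolf(Zc)
  # absolute ridge keeps zero-scatter (perfectly separable) inputs solvable
  ridge <- diag(1e-10 * max(mean(diag(lw$cov)), 1), ncol(Zc))
  w <- solve(lw$cov + ridge, mu1 - mu0)
  b <- -0.5 * sum((mu1 + mu0) * w) + log(sum(i1) / sum(!i1))

  structure(
    list(kind = "RLDA", xdawn = xd, mean_cov = M,
         lda = list(w = w, b = b, shrinkage = lw$shrinkage),
         trial_shape = dim(trials)[2:3], channel_names = data$channel_names,
         band = data$band, provenance = data$provenance, seed = seed),
    class = "trained_model"
  )
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model %s: %d channels x %d samples, trained on %s>\n",
              x$kind, x$trial_shape[1], x$trial_shape[2],
              x$provenance %||% "?"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------

#' Per-trial target/non-target likelihood ratios
#'
#' Evaluates a fitted model on a trial dataset and returns one strictly
#' positive, finite likelihood ratio per trial: the PRK model returns
#' `kde_target(score) / kde_nontarget(score)` (denominator floored at
#' 1e-300); the logistic and Riemannian LDA models return the posterior odds
#' `p(target|x) / p(nontarget|x)`. Ratios above 1.0 favor the target class.
#'
#' @param model A `trained_model`.
#' @param data A `trial_dataset` with the same channel count and trial length
#'   as the training data.
#' @return Numeric vector of likelihood ratios, one per trial.
#' @export
predict_likelihoods <- function(model, data) {
  stopifnot(inherits(model, "trained_model"), inherits(data, "trial_dataset"))
  d <- dim(data$trials)
  if (!identical(as.integer(d[2:3]), as.integer(model$trial_shape))) {
    stop(sprintf("trial shape (%d channels x %d samples) != training shape (%d x %d)",
                 d[2], d[3], model$trial_shape[1], model$trial_shape[2]))
  }
  clip_exp <- function(z) exp(pmin(pmax(z, -690), 690))
  lik <- switch(
    model$kind,
    PRK = {
      scores <- .rda_score(model$rda, .prk_features(model, data$trials))
      num <- .kde_eval(scores, model$kde$target$centers, model$kde$target$h)
      den <- .kde_eval(scores, model$kde$nontarget$centers,
                       model$kde$nontarget$h)
      pmax(num, 1e-300) / pmax(den, 1e-300)
    },
    LR = {
      X <- .flatten_trials(data$trials)
      Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
      p <- if (is.null(model$fit)) {
        rep(model$prior, nrow(Xs))
      } else {
        as.numeric(stats::predict(model$fit, Xs, s = model$lambda,
                                  type = "response"))
      }
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      p / (1 - p)
    },
    RLDA = {
      covs <- .rlda_covs(model$xdawn, data$trials)
      Z <- tangent_space(covs, model$mean_cov)
      clip_exp(drop(Z %*% model$lda$w) + model$lda$b)
    },
    stop("unknown model kind: ", model$kind)
  )
  stopifnot(all(is.finite(lik)), all(lik > 0))
  lik
}

.fit_model <- function(kind, data, hp, seed) {
  switch(kind,
         PRK = fit_prk(data, hp, seed),
         LR = fit_logistic(data, hp, seed),
         RLDA = fit_rlda(data, hp, seed),
         stop("unknown model kind: ", kind))
}

.subset_trials <- function(data, idx) {
  .new_trial_dataset(data$trials[idx, , , drop = FALSE], data$labels[idx],
                     data$trial_window_s, data$effective_fs, data$provenance,
                     data$band, data$channel_names)
}

# stratified fold assignment: within each class, shuffle then deal
.stratified_folds <- function(labels, k, seed) {
  set.seed(seed)
  folds <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- sample(which(labels == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Stratified k-fold cross-validation of a trial classifier
#'
#' Splits the trials into `cv_folds` stratified folds (seeded), fits the
#' chosen model on each training portion, predicts likelihood ratios on the
#' held-out fold, classifies at ratio > 1.0, and accumulates per-fold
#' balanced accuracy and Matthews correlation. When `grid` is supplied (a
#' data frame of `rda_lambda`, `rda_gamma` values; PRK only), every grid
#' point is cross-validated and the point maximizing the mean selection
#' metric is reported.
#'
#' @param model_kind One of `"PRK"`, `"LR"`, `"RLDA"`.
#' @param data A `trial_dataset`.
#' @param hp A [model_hyperparams()].
#' @param seed Integer seed controlling the fold split.
#' @param grid Optional hyperparameter grid (PRK only).
#' @return A `metric_result`: fold-mean and sd of BA and MCC, the per-fold
#'   vectors, and the selected hyperparameters.
#' @export
cross_validate <- function(model_kind, data, hp = model_hyperparams(),
                           seed = 1L, grid = NULL) {
  stopifnot(inherits(data, "trial_dataset"))
  n <- length(data$labels)
  if (n < hp$cv_folds) stop("fewer trials than folds")
  if (min(table(data$labels)) < hp$cv_folds) {
    stop("every fold must contain both classes; too few minority trials")
  }

  run_once <- function(hp_use) {
    folds <- .stratified_folds(data$labels, hp_use$cv_folds, seed)
    fold_ba <- fold_mcc <- numeric(hp_use$cv_folds)
    for (f in seq_len(hp_use$cv_folds)) {
      tr <- .subset_trials(data, which(folds != f))
      te <- .subset_trials(data, which(folds == f))
      model <- .fit_model(model_kind, tr, hp_use, seed)
      lik <- predict_likelihoods(model, te)
      pred <- as.integer(lik > 1.0)
      cm <- confusion_counts(te$labels, pred)
      fold_ba[f] <- balanced_accuracy(cm)
      fold_mcc[f] <- matthews_cc(cm)
    }
    list(ba = mean(fold_ba), mcc = mean(fold_mcc),
         ba_sd = stats::sd(fold_ba), mcc_sd = stats::sd(fold_mcc),
         fold_ba = fold_ba, fold_mcc = fold_mcc)
  }

  if (is.null(grid)) {
    res <- run_once(hp)
    sel <- NULL
  } else {
    if (model_kind != "PRK") stop("hyperparameter grids are supported for PRK only")
    best <- NULL; best_val <- -Inf; sel <- NULL
    for (g in seq_len(nrow(grid))) {
      hp_g <- hp
      hp_g$prk$rda_lambda <- grid$rda_lambda[g]
      hp_g$prk$rda_gamma <- grid$rda_gamma[g]
      r <- run_once(hp_g)
      val <- if (hp$selection_metric == "MCC") r$mcc else r$ba
      if (val > best_val) {
        best_val <- val; best <- r
        sel <- as.list(grid[g, , drop = FALSE])
      }
    }
    res <- best
  }

  structure(
    c(res, list(model_kind = model_kind, n = n, cv_folds = hp$cv_folds,
                seed = seed, selected = sel)),
    class = "metric_result"
  )
}

#' @export
print.metric_result <- function(x, ...) {
  cat(sprintf("<metric_result %s: BA %.3f (sd %.3f), MCC %.3f (sd %.3f), %d-fold>\n",
              x$model_kind, x$ba, x$ba_sd, x$mcc, x$mcc_sd, x$cv_folds))
  invisible(x)
}
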