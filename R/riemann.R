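# Symmetric-matrix spectral calculus and affine-invariant geometry for SPD
# covariance matrices, used by the xDAWN + tangent-space classifier.

.sym_fun <- function(M, f) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  e$vectors %*% (f(e$values) * t(e$vectors))
}

spd_logm <- function(M) {
  .sym_fun(M, function(v) {
    if (any(v <= 0)) stop("matrix is not positive definite")
    log(v)
  })
}

spd_expm <- function(M) .sym_fun(M, exp)
spd_sqrtm <- function(M) .sym_fun(M, function(v) sqrt(pmax(v, 0)))
spd_invsqrtm <- function(M) {
  .sym_fun(M, function(v) {
    if (any(v <= 0)) stop("matrix is not positive definite")
    1 / sqrt(v)
  })
}

#' Affine-invariant (geometric) mean of SPD matrices
#'
#' Fixed-point iteration for the Riemannian barycenter of a set of symmetric
#' positive-definite matrices under the affine-invariant metric. For two
#' commuting matrices this reduces to the elementwise geometric mean of the
#' eigenvalues.
#'
#' @param mats List of SPD matrices of common dimension.
#' @param tol Frobenius-norm convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 50); non-convergence is an error.
#' @return The SPD mean matrix.
#' @export
spd_mean <- function(mats, tol = 1e-8, max_iter = 50) {
  stopifnot(length(mats) >= 1)
  if (length(mats) == 1) return(mats[[1]])
  M <- Reduce(`+`, mats) / length(mats)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    W <- spd_invsqrtm(M)
    Wi <- spd_sqrtm(M)
    S <- Reduce(`+`, lapply(mats, function(C) spd_logm(W %*% C %*% W))) /
      length(mats)
    snorm <- sqrt(sum(S^2))
    if (snorm < tol) return(M)
    # ill-conditioned inputs (eigenvalue spread near machine precision) can
    # stall above tol on eigendecomposition round-off; accept the plateau
    # when the gradient is already tiny and no longer decreasing
    if (snorm >= prev && snorm < sqrt(tol)) return(M)
    prev <- snorm
    M <- Wi %*% spd_expm(S) %*% Wi
    M <- (M + t(M)) / 2
  }
  stop(sprintf("SPD mean did not converge within %d iterations", max_iter))
}

#' Tangent-space coordinates of SPD matrices at a reference point
#'
#' Maps each matrix `C` to `vec(log(M^-1/2 C M^-1/2))`, the affine-invariant
#' log-map at `M`, vectorized as the upper triangle with off-diagonal entries
#' scaled by `sqrt(2)` so Euclidean distance in the vector space matches the
#' Frobenius norm. A d x d matrix yields d(d+1)/2 coordinates; the reference
#' itself maps to the zero vector.
#'
#' @param mats List of SPD matrices.
#' @param M Reference SPD matrix (typically their [spd_mean()]).
#' @return Matrix of tangent vectors, one row per input matrix.
#' @export
tangent_space <- function(mats, M) {
  W <- spd_invsqrtm(M)
  d <- nrow(M)
  ut <- upper.tri(M, diag = FALSE)
  t(vapply(mats, function(C) {
    L <- spd_logm(W %*% C %*% W)
    c(diag(L), sqrt(2) * L[ut])
  }, numeric(d * (d + 1) / 2)))
}

# Ledoit-Wolf shrinkage covariance of centered rows (n x p): shrinks the
# empirical covariance toward a scaled identity with data-driven intensity
.ledoit_wolf <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  S <- crossprod(Xc) / n
  mu <- sum(diag(S)) / p
  d2 <- sum((S - diag(mu, p))^2) / p
  if (d2 < .Machine$double.eps) {
    return(list(cov = diag(mu, p), shrinkage = 0))
  }
  sq_norms <- rowSums(Xc^2)
  b2 <- (sum(sq_norms^2) - n * sum(S^2)) / (n^2 * p)
  b2 <- min(max(b2, 0), d2)
  rho <- b2 / d2
  list(cov = (1 - rho) * S + diag(rho * mu, p), shrinkage = rho)
}
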