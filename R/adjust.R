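#' Build the covariate design block for shape adjustment
#'
#' Assembles the ten adjustment covariates — age, age squared, sex, weight,
#' height, facial size (centroid size before scaling), and four ancestry
#' axes — from a covariate table. Age squared is computed internally.
#'
#' @param covariates Data frame with columns `age` (yrs), `sex` (0/1),
#'   `height` (cm), `weight` (kg), `pc1`..`pc4` (ancestry axes).
#' @param facial_size Numeric vector of centroid sizes (mm), one per subject.
#' @return An `n x 10` numeric matrix of class `covariate_block`.
#' @export
covariate_block <- function(covariates, facial_size) {
  need <- c("age", "sex", "height", "weight", "pc1", "pc2", "pc3", "pc4")
  missing <- setdiff(need, names(covariates))
  assert_that(length(missing) == 0,
              paste("covariate table is missing:", paste(missing, collapse = ", ")))
  assert_that(length(facial_size) == nrow(covariates),
              "facial_size length must match the covariate table")
  X <- cbind(age = covariates$age, age2 = covariates$age^2, sex = covariates$sex,
             weight = covariates$weight, height = covariates$height,
             size = facial_size,
             pc1 = covariates$pc1, pc2 = covariates$pc2,
             pc3 = covariates$pc3, pc4 = covariates$pc4)
  X <- as.matrix(X)
  assert_that(!anyNA(X), "covariates contain missing values")
  # constant columns carry no adjustable signal; subgroup analyses (e.g.
  # male-only, where sex is constant) drop them rather than fail
  keep <- apply(X, 2, sd) > 0
  assert_that(any(keep), "all covariate columns are constant")
  dropped <- colnames(X)[!keep]
  X <- X[, keep, drop = FALSE]
  attr(X, "dropped") <- dropped
  class(X) <- c("covariate_block", class(X))
  X
}

# PLS2 component extraction (X deflated, Y kept): returns orthonormal score
# basis T spanning up to ncomp PLS directions of centered X.
pls_score_basis <- function(Xc, Yc, ncomp) {
  n <- nrow(Xc)
  Xd <- Xc
  Tmat <- matrix(0, n, ncomp)
  for (h in seq_len(ncomp)) {
    M <- crossprod(Xd, Yc)                 # p x q
    w <- svd(M, nu = 1, nv = 0)$u[, 1]     # dominant covariance direction
    t_h <- Xd %*% w
    nt <- sqrt(sum(t_h^2))
    if (nt < 1e-12) { Tmat <- Tmat[, seq_len(h - 1L), drop = FALSE]; break }
    t_h <- t_h / nt
    Tmat[, h] <- t_h
    Xd <- Xd - t_h %*% crossprod(t_h, Xd)  # deflate X
  }
  Tmat
}

#' Remove covariate effects by partial least-squares regression
#'
#' Fits a PLS regression of a (multivariate) response on the standardized
#' covariate block and returns the residuals. With `n_components` equal to
#' the rank of the covariates (the default) the fit spans the full covariate
#' column space and the residuals coincide with ordinary least-squares
#' residuals; fewer components give a shrunken adjustment for
#' under-determined settings. Applied to flattened shape coordinates and,
#' with a one-column `Y`, to SNP dosages, so both sides of the association
#' test are corrected for the same covariates. Adjustment is cohort-local:
#' call it once per cohort.
#'
#' @param Y `n x p` response matrix (or vector).
#' @param X Covariate matrix, typically a [covariate_block()].
#' @param n_components Number of PLS components; default `rank(X)`.
#' @return Residual matrix with the same dimensions as `Y`; column means are
#'   zero (the intercept is handled by centering). Constant `Y` columns pass
#'   through centered.
#' @export
plsr_residualize <- function(Y, X, n_components = NULL) {
  Y <- as.matrix(Y)
  X <- unclass(as.matrix(X))
  n <- nrow(Y)
  assert_that(nrow(X) == n, "Y and X must have the same number of rows")
  assert_that(n > ncol(X), "need more subjects than covariates")
  Xs <- scale(X)  # standardize; also centers (intercept)
  assert_that(!anyNA(Xs), "covariates contain missing or constant columns")
  rk <- qr(Xs)$rank
  if (is.null(n_components)) n_components <- rk
  assert_that(n_components >= 1 && n_components <= rk,
              sprintf("n_components must be in 1..rank(X) = %d", rk))
  mu <- colMeans(Y)
  Yc <- sweep(Y, 2, mu)
  Tmat <- pls_score_basis(Xs, Yc, n_components)
  Yc - Tmat %*% crossprod(Tmat, Yc)
}

#' Covariate-adjust aligned shapes, keeping them configuration-like
#'
#' Residualizes the flattened aligned coordinates on the covariate block via
#' [plsr_residualize()] and adds the consensus back, so downstream stages
#' (per-module Procrustes, segmentation) still see landmark configurations.
#'
#' @param aligned An `aligned_set`.
#' @param X A [covariate_block()].
#' @param n_components Passed to [plsr_residualize()].
#' @return An `n x L x 3` array of adjusted configurations.
#' @export
adjust_shapes <- function(aligned, X, n_components = NULL) {
  stopifnot(inherits(aligned, "aligned_set"))
  flat <- flatten_configs(aligned$aligned)
  res <- plsr_residualize(flat, X, n_components)
  con <- as.vector(t(aligned$consensus))
  unflatten_configs(sweep(res, 2, -con))
}
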