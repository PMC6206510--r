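#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all landmarks to their
#' centroid — the standard geometric-morphometrics size measure, and the
#' "facial size" covariate used in shape adjustment.
#'
#' @param config An `L x 3` coordinate matrix (mm).
#' @return Centroid size (mm). Zero for a fully degenerate configuration
#'   (all landmarks coincident); downstream stages treat that as an error.
#' @examples
#' sq <- cbind(c(.5, .5, -.5, -.5), c(.5, -.5, .5, -.5), 0)
#' centroid_size(sq)  # sqrt(2)
#' @export
centroid_size <- function(config) {
  config <- as.matrix(config)
  assert_that(ncol(config) == 3 && nrow(config) >= 1, "config must be an L x 3 matrix")
  ctr <- colMeans(config)
  sqrt(sum(sweep(config, 2, ctr)^2))
}

#' Symmetrize configurations across the midsagittal plane
#'
#' Averages each configuration with its reflected, relabelled mirror image
#' (sign of x flipped, landmarks swapped by the mirror map). The result is
#' exactly invariant under reflect-and-relabel, so midline landmarks land on
#' `x = 0`.
#'
#' @param configs An `L x 3` matrix or an `n x L x 3` array.
#' @param mirror_map Integer involution over landmark indices (midline
#'   landmarks map to themselves).
#' @return Same shape as the input, symmetrized.
#' @export
symmetrize <- function(configs, mirror_map) {
  mirror_map <- as.integer(mirror_map)
  assert_that(all(mirror_map[mirror_map] == seq_along(mirror_map)),
              "mirror_map must be an involution (mirror_map[mirror_map[i]] == i)")
  one <- function(cfg) {
    refl <- cfg
    refl[, 1] <- -refl[, 1]
    (cfg + refl[mirror_map, , drop = FALSE]) / 2
  }
  if (length(dim(configs)) == 3) {
    assert_that(dim(configs)[2] == length(mirror_map), "mirror_map length must equal L")
    out <- configs
    for (i in seq_len(dim(configs)[1])) out[i, , ] <- one(configs[i, , ])
    out
  } else {
    cfg <- as.matrix(configs)
    assert_that(nrow(cfg) == length(mirror_map), "mirror_map length must equal L")
    one(cfg)
  }
}

#' Generalized Procrustes superimposition
#'
#' Iteratively centers each configuration, scales it to unit centroid size,
#' rotates it onto the current consensus by rotation-only orthogonal
#' Procrustes (SVD with determinant correction, so reflections are never
#' introduced), and updates the consensus until it stabilizes. The final
#' solution is put in a canonical orientation (consensus principal axes with
#' a deterministic sign convention), which makes the output invariant to a
#' common rotation of all inputs and to subject order.
#'
#' @param configs `n x L x 3` array of configurations (mm).
#' @param tol Convergence threshold on the Frobenius change of the consensus.
#' @param max_iter Maximum number of iterations.
#' @return An object of class `aligned_set`: list with `aligned`
#'   (`n x L x 3`, centered, unit centroid size), `consensus` (`L x 3`, unit
#'   size), `centroid_sizes` (mm), `iterations`, `delta`.
#' @export
gpa <- function(configs, tol = 1e-9, max_iter = 200) {
  assert_that(length(dim(configs)) == 3 && dim(configs)[3] == 3,
              "configs must be an n x L x 3 array")
  n <- dim(configs)[1]
  assert_that(n >= 2, "GPA needs at least two configurations")
  flat <- flatten_configs(configs)
  cs <- .cpp_center_scale(flat)
  assert_that(all(cs$sizes > 0), "degenerate configuration (zero centroid size)")
  fit <- .cpp_gpa_iterate(cs$scaled, tol, as.integer(max_iter))
  if (fit$delta >= tol && fit$iterations >= max_iter)
    abort(sprintf("GPA did not converge in %d iterations (last consensus change %.3e)",
                  max_iter, fit$delta))

  # canonical orientation: consensus principal axes, signs fixed so the
  # largest-|coordinate| landmark on each axis is positive, determinant +1
  con <- fit$consensus
  ev <- eigen(crossprod(con), symmetric = TRUE)
  R <- ev$vectors
  rot <- con %*% R
  for (k in 1:3) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) R[, k] <- -R[, k]
  }
  if (det(R) < 0) R[, 3] <- -R[, 3]
  con <- con %*% R
  # apply the same orientation to every aligned configuration
  aligned <- unflatten_configs(fit$aligned)
  arr <- array(0, dim = dim(aligned))
  for (i in seq_len(n)) arr[i, , ] <- aligned[i, , ] %*% R

  structure(list(aligned = arr, consensus = con,
                 centroid_sizes = as.numeric(cs$sizes),
                 iterations = fit$iterations, delta = fit$delta),
            class = "aligned_set")
}

#' @export
print.aligned_set <- function(x, ...) {
  d <- dim(x$aligned)
  cat(sprintf("<aligned_set> %d subjects, %d landmarks; converged in %d iterations (delta %.2e)\n",
              d[1], d[2], x$iterations, x$delta))
  invisible(x)
}

#' One-row summary of a Procrustes fit
#'
#' @param x An `aligned_set`.
#' @param ... Unused.
#' @return A one-row tibble: n, landmark count, iterations, convergence
#'   delta, mean centroid size (mm), and the Procrustes sum of squares.
#' @method glance aligned_set
#' @export
glance.aligned_set <- function(x, ...) {
  d <- dim(x$aligned)
  con_flat <- as.vector(t(x$consensus))  # x1,y1,z1,x2,... matches flatten_configs
  tibble::tibble(n = d[1], n_landmarks = d[2], iterations = x$iterations,
                 delta = x$delta,
                 mean_centroid_size = mean(x$centroid_sizes),
                 procrustes_ss = sum(sweep(flatten_configs(x$aligned), 2, con_flat)^2))
}

#' Flag atypical faces by Mahalanobis distance in shape PC space
#'
#' Computes each subject's Mahalanobis distance to the mean face in the
#' principal-component space retaining `var_frac` of the aligned shape
#' variance (the full-space covariance is singular when `3L > n`),
#' standardizes the distances to z-scores over subjects, and flags subjects
#' whose z-score exceeds the threshold. Flagged subjects are reported, not
#' removed; dropping them is the caller's decision.
#'
#' @param aligned An `aligned_set` from [gpa()].
#' @param z_threshold Flagging threshold on the z-score (default 2).
#' @param var_frac Fraction of shape variance retained for the metric.
#' @return A tibble with `subject`, `mahalanobis`, `z`, `flagged`.
#' @export
qc_outliers <- function(aligned, z_threshold = 2, var_frac = 0.98) {
  stopifnot(inherits(aligned, "aligned_set"))
  X <- flatten_configs(aligned$aligned)
  X <- sweep(X, 2, colMeans(X))
  n <- nrow(X)
  pc <- svd(X, nu = 0)
  lam <- pc$d^2 / (n - 1)
  keep <- which(cumsum(lam) / sum(lam) <= var_frac)
  k <- max(length(keep), 1L)
  k <- min(k, n - 2L)
  assert_that(n > k, "too few subjects for the Mahalanobis metric")
  scores <- X %*% pc$v[, seq_len(k), drop = FALSE]
  d2 <- rowSums(sweep(scores^2, 2, lam[seq_len(k)], "/"))
  d <- sqrt(d2)
  z <- as.numeric(scale(d))
  tibble::tibble(subject = seq_len(n), mahalanobis = d, z = z,
                 flagged = is.finite(z) & z > z_threshold)
}
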