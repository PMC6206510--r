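#' Per-module shape space: Procrustes alignment + PCA
#'
#' Extracts a module's landmarks from each subject, superimposes them with a
#' fresh generalized Procrustes fit (the module is aligned in its own right,
#' not sliced out of the full-face alignment), flattens and centers the
#' aligned coordinates, and decomposes their covariance. All components up
#' to numerical rank are returned; truncation to the retained dimension is a
#' separate step ([retain_components()], usually driven by
#' [parallel_analysis()]).
#'
#' @param shapes `n x L x 3` array of (symmetrized, adjusted) configurations.
#' @param module Integer vector of landmark indices (>= 3 landmarks).
#' @param module_id Optional identifier carried through to results.
#' @return An object of class `module_phenotype`: `scores` (`n x r`),
#'   `loadings` (`3m x r`, orthonormal), `eigenvalues` (length `r`),
#'   `center` (length `3m`), `consensus` (`m x 3` module consensus),
#'   `landmarks`, `module_id`, `k` (retained dimension; initially `r`).
#' @export
module_shape_space <- function(shapes, module, module_id = NA_integer_) {
  assert_that(length(dim(shapes)) == 3, "shapes must be n x L x 3")
  module <- as.integer(module)
  assert_that(length(module) >= 3,
              sprintf("module %s has %d landmarks; per-module Procrustes needs at least 3",
                      module_id, length(module)))
  n <- dim(shapes)[1]
  assert_that(n > 3, "need more than 3 subjects")
  sub <- shapes[, module, , drop = FALSE]
  fit <- gpa(sub)
  X <- flatten_configs(fit$aligned)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  if (ncol(Xc) <= n) {
    eg <- eigen(crossprod(Xc), symmetric = TRUE)
    lam <- pmax(eg$values, 0) / (n - 1)
    Vfull <- eg$vectors
  } else {
    sv <- svd(Xc, nu = 0)
    lam <- sv$d^2 / (n - 1)
    Vfull <- sv$v
  }
  r <- sum(lam > max(lam) * 1e-15)
  r <- max(r, 1L)
  V <- Vfull[, seq_len(r), drop = FALSE]
  # sign convention: largest-|loading| entry positive per component
  for (k in seq_len(r)) {
    j <- which.max(abs(V[, k]))
    if (V[j, k] < 0) V[, k] <- -V[, k]
  }
  structure(list(scores = Xc %*% V, loadings = V,
                 eigenvalues = lam[seq_len(r)], center = ctr,
                 consensus = fit$consensus, landmarks = module,
                 module_id = module_id, k = r),
            class = "module_phenotype")
}

#' @export
print.module_phenotype <- function(x, ...) {
  cat(sprintf("<module_phenotype> module %s: %d landmarks, %d subjects, %d/%d PCs retained\n",
              x$module_id, length(x$landmarks), nrow(x$scores), x$k, ncol(x$scores)))
  invisible(x)
}

#' Truncate a module phenotype to its retained dimension
#'
#' @param pheno A `module_phenotype`.
#' @param k Number of leading components to retain (>= 1).
#' @return The phenotype with `k` set; `scores`/`loadings` keep full rank so
#'   the retained block is always `[, 1:k]`.
#' @export
retain_components <- function(pheno, k) {
  stopifnot(inherits(pheno, "module_phenotype"))
  assert_that(k >= 1 && k <= ncol(pheno$scores), "k out of range")
  pheno$k <- as.integer(k)
  pheno
}

#' Horn-style parallel analysis for component retention
#'
#' Compares each observed covariance eigenvalue, rank by rank, with the
#' chosen percentile of eigenvalues obtained from null matrices in which
#' every column of the data is independently permuted (a distribution-free
#' null that keeps the column variances but destroys all correlation).
#' Retention stops at the first rank whose observed eigenvalue fails to
#' exceed its null percentile; at least one component is always retained.
#'
#' @param data `n x p` matrix (centered internally).
#' @param n_iter Number of null permutations (>= 50; default 200).
#' @param percentile Null percentile in (0, 100]; default 95.
#' @param seed Optional integer seed for the permutation draws (local RNG).
#' @param max_n Optional cap on the number of subjects used (a random
#'   subsample is drawn once); retention decisions stabilize well below
#'   typical cohort sizes, so large studies need not pay the full
#'   permutation cost.
#' @return Retained dimension `k` (integer >= 1), with the observed and
#'   null-threshold eigenvalues attached as attributes `observed`, `null`.
#' @export
parallel_analysis <- function(data, n_iter = 200, percentile = 95, seed = NULL,
                              max_n = NULL) {
  X <- as.matrix(data)
  assert_that(n_iter >= 50, "n_iter must be at least 50")
  assert_that(percentile > 0 && percentile <= 100, "percentile must be in (0, 100]")
  runner <- function() {
    if (!is.null(max_n) && nrow(X) > max_n) X <- X[sample.int(nrow(X), max_n), , drop = FALSE]
    Xc <- sweep(X, 2, colMeans(X))
    obs <- cov_eigenvalues(Xc)
    list(obs = obs, null = .cpp_pa_null(Xc, as.integer(n_iter)))
  }
  out <- if (is.null(seed)) runner() else with_local_seed(seed, runner())
  obs <- out$obs
  null_mat <- out$null
  thr <- apply(null_mat, 2, quantile, probs = percentile / 100, names = FALSE)
  below <- which(obs <= thr)
  k <- if (length(below) == 0) length(obs) else below[1] - 1L
  k <- max(k, 1L)
  structure(as.integer(k), observed = obs, null = thr)
}

# eigenvalues of the covariance of a centered matrix, via the smaller Gram side
cov_eigenvalues <- function(Xc) {
  n <- nrow(Xc); p <- ncol(Xc)
  G <- if (p <= n) crossprod(Xc) else tcrossprod(Xc)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  pmax(ev, 0)[seq_len(min(n, p))] / (n - 1)
}

# evaluate `expr` under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phenotype every module of a tree in every cohort
#'
#' Runs [module_shape_space()] for each (module, cohort) pair and truncates
#' with [parallel_analysis()] on the retained-PC scores. Returns the adjusted
#' shapes alongside so replication cohorts can later be projected into a
#' discovery cohort's module frame.
#'
#' @param adj_shapes Named list of `n_c x L x 3` arrays, one per cohort
#'   (symmetrized, aligned, covariate-adjusted).
#' @param tree A `module_tree`.
#' @param pa_iter,pa_percentile,pa_max_n Parallel-analysis settings (see
#'   [parallel_analysis()]); `pa_max_n` caps the subjects used there.
#' @param seed Integer seed for the parallel-analysis permutations.
#' @return Object of class `phenotyped_cohorts`: `phenos[[cohort]][[module]]`
#'   plus `shapes`, `tree`, `cohorts`.
#' @export
phenotype_cohorts <- function(adj_shapes, tree, pa_iter = 200, pa_percentile = 95,
                              pa_max_n = 500, seed = 1L) {
  assert_that(is.list(adj_shapes) && length(adj_shapes) >= 1, "adj_shapes must be a list of arrays")
  if (is.null(names(adj_shapes))) names(adj_shapes) <- paste0("cohort", seq_along(adj_shapes))
  phenos <- lapply(names(adj_shapes), function(cn) {
    sh <- adj_shapes[[cn]]
    out <- vector("list", nrow(tree))
    names(out) <- as.character(tree$module_id)
    for (i in seq_len(nrow(tree))) {
      ph <- module_shape_space(sh, tree$landmarks[[i]], module_id = tree$module_id[i])
      # PA runs on the centered module coordinates (not the PC scores, whose
      # permutation null would be degenerate)
      Xc <- ph$scores %*% t(ph$loadings)
      k <- parallel_analysis(Xc, n_iter = pa_iter, percentile = pa_percentile,
                             seed = seed + 1000L * i, max_n = pa_max_n)
      out[[i]] <- retain_components(ph, min(as.integer(k), ph$k))
    }
    out
  })
  names(phenos) <- names(adj_shapes)
  structure(list(phenos = phenos, shapes = adj_shapes, tree = tree,
                 cohorts = names(adj_shapes)),
            class = "phenotyped_cohorts")
}

#' @export
print.phenotyped_cohorts <- function(x, ...) {
  cat(sprintf("<phenotyped_cohorts> %d cohorts x %d modules\n",
              length(x$cohorts), nrow(x$tree)))
  invisible(x)
}
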