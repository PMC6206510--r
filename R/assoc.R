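#' Single-SNP canonical correlation test against a module phenotype
#'
#' With a single genetic variable, canonical correlation analysis reduces
#' exactly to multiple regression: the canonical correlation is the multiple
#' correlation of the dosage on the module PC scores, the canonical loadings
#' are the (normalized) regression direction, and Rao's F approximation to
#' Wilks' lambda `1 - CC^2` is the exact overall-regression F with
#' `(k, n - k - 1)` degrees of freedom, tested right-tailed. Inputs are
#' expected to be covariate-residualized on both sides.
#'
#' @param dosage_residual Numeric n-vector (covariate-residualized dosage).
#' @param scores `n x k` matrix of retained module PC scores.
#' @return Object of class `cca_result`: `cc`, `loadings` (unit norm,
#'   oriented so the canonical variate correlates positively with the
#'   dosage), `p_value`, `n`, `k`.
#' @export
cca_single_snp <- function(dosage_residual, scores) {
  d <- as.numeric(dosage_residual)
  S <- as.matrix(scores)
  n <- length(d); k <- ncol(S)
  assert_that(nrow(S) == n, "dosage and scores must have the same length")
  assert_that(n > k + 2, "need n > k + 2")
  assert_that(sd(d) > 0, "constant dosage")
  d <- d - mean(d)
  Sc <- sweep(S, 2, colMeans(S))
  qr_s <- qr(Sc)
  assert_that(qr_s$rank == k, "singular score matrix")
  fit <- cca_from_qr(qr_s, d, n, k)
  structure(c(fit, list(n = n, k = k)), class = "cca_result")
}

# core CCA computation given a (reusable) QR of the centered score matrix
cca_from_qr <- function(qr_s, d_centered, n, k) {
  qtd <- qr.qty(qr_s, d_centered)[seq_len(k)]
  ssd <- sum(d_centered^2)
  r2 <- min(sum(qtd^2) / ssd, 1)
  b <- backsolve(qr.R(qr_s), qtd)
  nb <- sqrt(sum(b^2))
  if (nb > 0) b <- b / nb
  fstat <- ((n - k - 1) / k) * r2 / max(1 - r2, .Machine$double.eps)
  list(cc = sqrt(r2), loadings = as.numeric(b),
       p_value = pf(fstat, k, n - k - 1, lower.tail = FALSE))
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> CC = %.4f, p = %.3g (n = %d, k = %d)\n",
              x$cc, x$p_value, x$n, x$k))
  invisible(x)
}

#' @method tidy cca_result
#' @export
tidy.cca_result <- function(x, ...) {
  tibble::tibble(component = seq_along(x$loadings), loading = x$loadings)
}

#' @method glance cca_result
#' @export
glance.cca_result <- function(x, ...) {
  tibble::tibble(cc = x$cc, p_value = x$p_value, n = x$n, k = x$k)
}

#' Genetic effect score: project PC scores onto discovery loadings
#'
#' Turns the shape direction discovered by CCA in one cohort into a
#' measurable univariate trait in another: each subject's score is the inner
#' product of their module PC vector (expressed in the discovery PC basis)
#' with the discovery canonical loadings.
#'
#' @param scores `n x k` matrix of PC scores in the discovery basis.
#' @param loadings Length-`k` canonical loading vector from the discovery
#'   [cca_single_snp()].
#' @return Numeric n-vector of effect scores.
#' @export
project_effect_score <- function(scores, loadings) {
  S <- as.matrix(scores)
  assert_that(ncol(S) == length(loadings),
              sprintf("dimension mismatch: %d score columns vs %d loadings",
                      ncol(S), length(loadings)))
  as.numeric(S %*% loadings)
}

#' One-sided replication test of a genetic effect score
#'
#' Simple linear regression of the effect score on the dosage; the p-value
#' is the upper tail of the slope t-statistic with `n - 2` degrees of
#' freedom. One-sided because the discovery orientation fixes the expected
#' direction: concordant replication gives small p, discordant gives
#' p near 1.
#'
#' @param effect_score Numeric n-vector from [project_effect_score()].
#' @param dosage_residual Numeric n-vector.
#' @return Upper-tail p-value.
#' @export
replication_test <- function(effect_score, dosage_residual) {
  y <- as.numeric(effect_score); x <- as.numeric(dosage_residual)
  n <- length(y)
  assert_that(length(x) == n, "inputs must have equal length")
  assert_that(n >= 4, "need at least 4 observations")
  assert_that(sd(x) > 0 && sd(y) > 0, "zero-variance input")
  r <- cor(x, y)
  r <- max(min(r, 1 - 1e-15), -1 + 1e-15)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  pt(tstat, df = n - 2, lower.tail = FALSE)
}

#' Combine p-values by Stouffer's method
#'
#' Each p is converted to a z-score `qnorm(1 - p)`; the weighted sum
#' `sum(w z) / sqrt(sum(w^2))` is referred back to the standard normal
#' upper tail. Unweighted by default.
#'
#' @param p_values Numeric vector of p-values strictly inside (0, 1);
#'   callers should clamp boundary values first (see [clamp_p()]).
#' @param weights Optional positive weights (e.g. `sqrt(n)` per cohort).
#' @return Combined p-value.
#' @export
stouffer_combine <- function(p_values, weights = NULL) {
  p <- as.numeric(p_values)
  assert_that(all(p > 0 & p < 1), "p-values must lie strictly in (0, 1); clamp first")
  if (is.null(weights)) weights <- rep(1, length(p))
  assert_that(length(weights) == length(p) && all(weights > 0), "bad weights")
  z <- qnorm(p, lower.tail = FALSE)  # = qnorm(1 - p), accurate for tiny p
  Z <- sum(weights * z) / sqrt(sum(weights^2))
  structure(pnorm(Z, lower.tail = FALSE), z = Z)
}

#' Clamp p-values away from 0 and 1 for z-conversion
#'
#' @param p Numeric vector.
#' @param eps Lower clamp (default 1e-300); upper clamp is `1 - 1e-16`.
#' @return Clamped vector.
#' @export
clamp_p <- function(p, eps = 1e-300) pmin(pmax(p, eps), 1 - 1e-16)

#' Li–Ji effective number of independent tests
#'
#' From the eigenvalues of a correlation matrix among `t` tests,
#' `Meff = sum over i of [ 1(|lambda_i| >= 1) + (|lambda_i| - floor(|lambda_i|)) ]`.
#' Perfect correlation gives 1, independence gives `t`. The integer-rounded
#' value feeds the Bonferroni threshold; the raw sum is attached as an
#' attribute.
#'
#' @param correlation Symmetric correlation matrix with unit diagonal.
#' @return Integer effective test count, with attribute `raw`.
#' @export
li_ji_meff <- function(correlation) {
  R <- as.matrix(correlation)
  assert_that(nrow(R) == ncol(R) && max(abs(R - t(R))) < 1e-8,
              "correlation matrix must be symmetric")
  lam <- abs(eigen((R + t(R)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  # guard the floor against eigenvalues that are integers up to rounding
  # (e.g. 29.999... for a rank-1 all-ones matrix must contribute 1, not ~2)
  fl <- floor(lam + 1e-9)
  f <- as.numeric(lam >= 1 - 1e-9) + pmax(lam - fl, 0)
  raw <- sum(f)
  structure(as.integer(round(raw)), raw = raw)
}

#' Study-wide Bonferroni threshold over effective tests
#'
#' `alpha / (meff_modules * meff_snps * n_meta)`: effective module count,
#' effective SNP count, and the number of round-robin meta-analyses.
#'
#' @param meff_modules,meff_snps,n_meta Positive counts.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Significance cutoff.
#' @examples
#' study_threshold(37, 30, 3)        # 1.5e-05
#' study_threshold(42, 1, 1)         # ratio arm, 0.05/42
#' @export
study_threshold <- function(meff_modules, meff_snps, n_meta, alpha = 0.05) {
  assert_that(all(c(meff_modules, meff_snps, n_meta, alpha) > 0), "all arguments must be positive")
  alpha / (meff_modules * meff_snps * n_meta)
}

# Align replication module configurations into a discovery module frame and
# return their scores in the discovery PC basis (centered on the discovery
# center). Cached by callers across SNPs.
project_into_frame <- function(shapes, landmarks, frame) {
  sub <- shapes[, landmarks, , drop = FALSE]
  flat <- flatten_configs(sub)
  cs <- .cpp_center_scale(flat)
  rot <- .cpp_rotate_all(cs$scaled, frame$consensus)
  sweep(rot, 2, frame$center) %*% frame$loadings
}

#' Round-robin CCA discovery, projection replication and Stouffer meta-analysis
#'
#' For every rotation (each cohort once as discovery), every SNP and every
#' requested module: run the discovery CCA on the retained module PCs; map
#' the two replication cohorts' module configurations into the discovery
#' Procrustes/PCA frame (align to the discovery consensus, project on the
#' discovery loadings); score them with [project_effect_score()]; test
#' replication one-sided with [replication_test()]; and combine the
#' discovery and two replication p-values with [stouffer_combine()]
#' (discovery p converted via `z = qnorm(1 - p)`, all p clamped at 1e-300).
#'
#' @param phenos A `phenotyped_cohorts` object (3 cohorts).
#' @param dosage_residual Named list (per cohort) of `n_c x S`
#'   covariate-residualized dosage matrices with common SNP columns.
#' @param modules Module ids to test (default: all in the tree).
#' @param weights `"equal"` (default) or `"sqrt_n"` Stouffer weights.
#' @param threshold Optional significance cutoff for the `significant` flag
#'   (e.g. from [study_threshold()]).
#' @return A tibble (class `meta_result`): `snp`, `module_id`, `rotation`
#'   (discovery cohort), `cc`, `k`, `p_discovery`, `p_rep1`, `p_rep2`,
#'   `p_meta`, `z_meta` (the Stouffer Z, which stays informative when
#'   `p_meta` underflows), `significant`.
#' @export
round_robin_meta <- function(phenos, dosage_residual, modules = NULL,
                             weights = c("equal", "sqrt_n"), threshold = NULL) {
  stopifnot(inherits(phenos, "phenotyped_cohorts"))
  weights <- match.arg(weights)
  cohorts <- phenos$cohorts
  assert_that(length(cohorts) == 3, "round-robin meta-analysis expects exactly 3 cohorts")
  assert_that(all(cohorts %in% names(dosage_residual)), "dosage list must cover all cohorts")
  dn <- lapply(dosage_residual[cohorts], as.matrix)
  snp_ids <- colnames(dn[[1]])
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dn[[1]])))
  assert_that(all(vapply(dn, ncol, 1L) == length(snp_ids)), "SNP columns differ across cohorts")
  if (is.null(modules)) modules <- phenos$tree$module_id

  out <- vector("list", length(modules) * 3L)
  idx <- 0L
  for (mod in modules) {
    mkey <- as.character(mod)
    lmk <- phenos$tree$landmarks[[which(phenos$tree$module_id == mod)]]
    for (ci in seq_along(cohorts)) {
      disc <- cohorts[ci]; reps <- cohorts[-ci]
      ph <- phenos$phenos[[disc]][[mkey]]
      k <- ph$k
      Sd <- ph$scores[, seq_len(k), drop = FALSE]
      Sdc <- sweep(Sd, 2, colMeans(Sd))
      qr_s <- qr(Sdc)
      n_d <- nrow(Sdc)
      frame <- list(consensus = ph$consensus, center = ph$center,
                    loadings = ph$loadings[, seq_len(k), drop = FALSE])
      rep_scores <- lapply(reps, function(rc)
        project_into_frame(phenos$shapes[[rc]], lmk, frame))
      names(rep_scores) <- reps
      Dd <- dn[[disc]]
      res <- matrix(NA_real_, length(snp_ids), 6)
      for (s in seq_along(snp_ids)) {
        dvec <- Dd[, s] - mean(Dd[, s])
        fit <- cca_from_qr(qr_s, dvec, n_d, k)
        p_rep <- vapply(reps, function(rc) {
          es <- project_effect_score(rep_scores[[rc]], fit$loadings)
          replication_test(es, dn[[rc]][, s])
        }, numeric(1))
        w <- if (weights == "equal") NULL else
          sqrt(c(n_d, vapply(reps, function(rc) nrow(dn[[rc]]), numeric(1))))
        p_meta <- stouffer_combine(clamp_p(c(fit$p_value, p_rep)), w)
        res[s, ] <- c(fit$cc, fit$p_value, p_rep, p_meta, attr(p_meta, "z"))
      }
      idx <- idx + 1L
      out[[idx]] <- tibble::tibble(
        snp = snp_ids, module_id = mod, rotation = disc, cc = res[, 1], k = k,
        p_discovery = res[, 2], p_rep1 = res[, 3], p_rep2 = res[, 4],
        p_meta = res[, 5], z_meta = res[, 6])
    }
  }
  tb <- dplyr::bind_rows(out)
  tb$significant <- if (is.null(threshold)) NA else tb$p_meta < threshold
  class(tb) <- c("meta_result", class(tb))
  tb
}

#' Correlation matrices feeding the Li–Ji correction
#'
#' Modules are summarized by their first PC score in a reference cohort and
#' correlated across modules; SNPs by their dosage correlations pooled over
#' cohorts.
#'
#' @param phenos A `phenotyped_cohorts`.
#' @param dosages Named list of dosage matrices (per cohort).
#' @param cohort Reference cohort for the module summary (default first).
#' @return List with `modules` and `snps` correlation matrices.
#' @export
meff_correlations <- function(phenos, dosages, cohort = NULL) {
  if (is.null(cohort)) cohort <- phenos$cohorts[1]
  first_pcs <- vapply(phenos$phenos[[cohort]], function(ph) ph$scores[, 1],
                      numeric(nrow(phenos$shapes[[cohort]])))
  Dall <- do.call(rbind, lapply(dosages, as.matrix))
  list(modules = stats::cor(first_pcs), snps = stats::cor(Dall))
}
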