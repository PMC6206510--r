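#' Default facial ratio definitions
#'
#' Five literature-standard width-to-height-style ratio endpoints built on
#' the template's named landmarks. These are configurable defaults — the
#' exact endpoint set of any particular study should be passed explicitly
#' when known.
#'
#' * `fwhr_total` — bizygomatic width / nasion–gnathion height
#' * `fwhr_upper` (FWH1) — bizygomatic width / nasion–prosthion height
#' * `lower_to_total_height` — stomion–gnathion / nasion–gnathion
#' * `width_to_lower_height` — bizygomatic width / stomion–gnathion
#' * `cheek_prominence` — bizygomatic width / glabella–gnathion profile length
#'
#' @return Tibble with columns `name`, `num_a`, `num_b`, `den_a`, `den_b`
#'   (landmark names).
#' @export
default_ratio_definitions <- function() {
  tibble::tribble(
    ~name, ~num_a, ~num_b, ~den_a, ~den_b,
    "fwhr_total", "zygion_l", "zygion_r", "nasion", "gnathion",
    "fwhr_upper", "zygion_l", "zygion_r", "nasion", "prosthion",
    "lower_to_total_height", "stomion", "gnathion", "nasion", "gnathion",
    "width_to_lower_height", "zygion_l", "zygion_r", "stomion", "gnathion",
    "cheek_prominence", "zygion_l", "zygion_r", "glabella", "gnathion")
}

#' Compute facial ratios from named landmarks
#'
#' Each ratio is the Euclidean distance between its numerator landmark pair
#' divided by the distance between its denominator pair; ratios are
#' invariant to rigid motion and uniform scaling of the configuration.
#'
#' @param configs `L x 3` matrix or `n x L x 3` array (mm).
#' @param definitions Ratio definition tibble (see
#'   [default_ratio_definitions()]).
#' @param named_landmarks Named integer vector mapping landmark names to
#'   indices (e.g. `template$named_landmarks`).
#' @return Tibble with one row per subject and one column per ratio.
#' @export
compute_ratios <- function(configs, definitions = default_ratio_definitions(),
                           named_landmarks) {
  defs <- tibble::as_tibble(definitions)
  used <- unique(unlist(defs[, c("num_a", "num_b", "den_a", "den_b")]))
  missing <- setdiff(used, names(named_landmarks))
  assert_that(length(missing) == 0,
              paste("unresolvable landmark names:", paste(missing, collapse = ", ")))
  if (length(dim(configs)) == 2) configs <- array(configs, dim = c(1, dim(configs)))
  n <- dim(configs)[1]
  dist_pair <- function(a, b) {
    ia <- named_landmarks[[a]]; ib <- named_landmarks[[b]]
    d <- configs[, ia, ] - configs[, ib, ]
    if (is.null(dim(d))) d <- matrix(d, nrow = 1)
    sqrt(rowSums(d^2))
  }
  out <- lapply(seq_len(nrow(defs)), function(r) {
    num <- dist_pair(defs$num_a[r], defs$num_b[r])
    den <- dist_pair(defs$den_a[r], defs$den_b[r])
    assert_that(all(den > 0),
                sprintf("zero denominator distance in ratio '%s'", defs$name[r]))
    num / den
  })
  names(out) <- defs$name
  tibble::as_tibble(out)
}

#' Two-stage linear association of a facial ratio with a SNP
#'
#' Stage one residualizes the ratio on sex, age and body size; stage two
#' regresses the residual on the additive dosage adjusting for four
#' ancestry axes, reporting the dosage slope and its two-sided p-value.
#'
#' @param ratio Numeric n-vector.
#' @param dosage Numeric n-vector in `[0, 2]`.
#' @param covariates Tibble with `sex`, `age`, `height` (body size) and
#'   `pc1`..`pc4`.
#' @return One-row tibble: `slope`, `se`, `statistic`, `p_value`, `n`.
#' @export
ratio_association <- function(ratio, dosage, covariates) {
  n <- length(ratio)
  assert_that(length(dosage) == n && nrow(covariates) == n, "length mismatch")
  assert_that(n > 9, "need more than 9 subjects")
  need <- c("sex", "age", "height", "pc1", "pc2", "pc3", "pc4")
  assert_that(all(need %in% names(covariates)),
              paste("covariates must include:", paste(need, collapse = ", ")))
  X1 <- cbind(1, covariates$sex, covariates$age, covariates$height)
  # constant columns (e.g. sex in a single-sex subgroup) carry no signal
  X1 <- X1[, c(TRUE, apply(X1[, -1, drop = FALSE], 2, sd) > 0), drop = FALSE]
  kap <- kappa(crossprod(scale(X1[, -1, drop = FALSE])), exact = TRUE)
  assert_that(is.finite(kap) && kap < 1e10,
              sprintf("collinear adjustment covariates (condition number %.3g)", kap))
  res <- ratio - X1 %*% solve(crossprod(X1), crossprod(X1, ratio))
  df2 <- data.frame(res = as.numeric(res), dosage = dosage,
                    covariates[, c("pc1", "pc2", "pc3", "pc4")])
  fit <- lm(res ~ dosage + pc1 + pc2 + pc3 + pc4, data = df2)
  sm <- summary(fit)$coefficients["dosage", ]
  tibble::tibble(slope = sm[1], se = sm[2], statistic = sm[3], p_value = sm[4], n = n)
}

#' Scan all SNPs against all ratios, with subgroup filters
#'
#' Applies [ratio_association()] to every SNP x ratio pair, optionally in a
#' subgroup (`male`, `female`, `postpubertal` = age > 14), with the filter
#' applied before adjustment. The Bonferroni flag marks p-values below
#' `alpha / n_snps`.
#'
#' @param ratios Tibble of ratios (one column per ratio) for all subjects.
#' @param genotypes `n x S` dosage matrix.
#' @param covariates Covariate tibble (see [ratio_association()]).
#' @param subgroup `"all"`, `"male"`, `"female"` or `"postpubertal"`.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return Tibble: `snp`, `ratio`, `subgroup`, `slope`, `se`, `p_value`,
#'   `n`, `significant`.
#' @export
ratio_scan <- function(ratios, genotypes, covariates,
                       subgroup = c("all", "male", "female", "postpubertal"),
                       alpha = 0.05) {
  subgroup <- match.arg(subgroup)
  keep <- switch(subgroup,
                 all = rep(TRUE, nrow(covariates)),
                 male = covariates$sex == 1,
                 female = covariates$sex == 0,
                 postpubertal = covariates$age > 14)
  ratios <- ratios[keep, , drop = FALSE]
  G <- as.matrix(genotypes)[keep, , drop = FALSE]
  covs <- covariates[keep, ]
  thr <- alpha / ncol(G)
  out <- list()
  for (s in seq_len(ncol(G))) {
    for (r in names(ratios)) {
      row <- ratio_association(ratios[[r]], G[, s], covs)
      out[[length(out) + 1L]] <- dplyr::mutate(row,
        snp = colnames(G)[s], ratio = r, subgroup = subgroup, .before = 1)
    }
  }
  res <- dplyr::bind_rows(out)
  res$significant <- res$p_value < thr
  attr(res, "threshold") <- thr
  res
}
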