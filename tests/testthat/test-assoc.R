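test_that("single-SNP CCA equals the overall regression F-test on random instances", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(30:150, 1); k <- sample(2:8, 1)
    S <- matrix(rnorm(n * k), n, k)
    d <- rnorm(n) + S %*% rnorm(k, sd = runif(1, 0, .5))
    fit <- cca_single_snp(d, S)
    oracle <- summary(lm(d ~ S))
    p_oracle <- pf(oracle$fstatistic[1], oracle$fstatistic[2], oracle$fstatistic[3],
                   lower.tail = FALSE)
    expect_equal(fit$p_value, unname(p_oracle), tolerance = 1e-10)
    expect_equal(fit$cc, sqrt(oracle$r.squared), tolerance = 1e-10)
  }
})

test_that("a dosage that is an exact score combination gives CC = 1 and vanishing p", {
  set.seed(1)
  S <- matrix(rnorm(50 * 3), 50, 3)
  d <- S %*% c(1, -2, 0.5)
  fit <- cca_single_snp(d, S)
  expect_equal(fit$cc, 1, tolerance = 1e-8)
  expect_lt(fit$p_value, 1e-60)
  expect_equal(sum(fit$loadings^2), 1, tolerance = 1e-12)
})

test_that("degenerate CCA inputs are rejected", {
  S <- matrix(rnorm(40 * 2), 40, 2)
  expect_error(cca_single_snp(rep(1, 40), S), "constant")
  expect_error(cca_single_snp(rnorm(40), cbind(S[, 1], S[, 1])), "singular")
})

test_that("effect-score projection is the stated inner product and linear", {
  set.seed(2)
  S <- matrix(rnorm(30 * 4), 30, 4)
  expect_equal(project_effect_score(S, c(1, 0, 0, 0)), S[, 1])
  a <- rnorm(4); b <- rnorm(4)
  expect_equal(project_effect_score(S, a + 2 * b),
               project_effect_score(S, a) + 2 * project_effect_score(S, b),
               tolerance = 1e-12)
  expect_error(project_effect_score(S, c(1, 2)), "mismatch")
})

test_that("projecting the discovery cohort itself reproduces the canonical variate", {
  set.seed(3)
  S <- matrix(rnorm(100 * 5), 100, 5)
  d <- S %*% rnorm(5) + rnorm(100)
  fit <- cca_single_snp(d, S)
  variate <- project_effect_score(sweep(S, 2, colMeans(S)), fit$loadings)
  expect_equal(as.numeric(abs(cor(variate, as.numeric(d) - mean(d)))), fit$cc,
               tolerance = 1e-10)
})

test_that("the one-sided replication test has the stated symmetries", {
  set.seed(4)
  x <- rbinom(60, 2, .3)
  y <- rnorm(60)
  p <- replication_test(y, x)
  expect_equal(replication_test(-y, x), 1 - p, tolerance = 1e-12)
  # slope exactly zero: orthogonalize y against x
  y0 <- residuals(lm(y ~ x))
  expect_equal(replication_test(y0, x), 0.5, tolerance = 1e-12)
  expect_error(replication_test(rep(1, 60), x), "zero-variance")
})

test_that("Stouffer combination matches its closed form", {
  expect_equal(stouffer_combine(0.37), 0.37, tolerance = 1e-12, ignore_attr = TRUE)
  p3 <- stouffer_combine(rep(0.05, 3))
  Z <- 3 * qnorm(0.95) / sqrt(3)
  expect_equal(as.numeric(p3), pnorm(Z, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(as.numeric(p3), 2.19e-3, tolerance = 1e-2)
  expect_equal(as.numeric(stouffer_combine(c(0.5, 0.5))), 0.5, tolerance = 1e-12)
  # three concordant sub-0.05 p-values beat each of them
  p <- c(0.04, 0.02, 0.049)
  expect_lt(as.numeric(stouffer_combine(p)), min(p))
  expect_error(stouffer_combine(c(0, 0.5)), "strictly")
  expect_equal(clamp_p(c(0, 1)), c(1e-300, 1 - 1e-16))
  # sqrt-n weighting still returns a valid p
  expect_gt(as.numeric(stouffer_combine(c(.2, .3), weights = sqrt(c(100, 400)))), 0)
})

test_that("Li-Ji effective test counts match hand-computed eigenvalue structure", {
  expect_identical(as.integer(li_ji_meff(diag(17))), 17L)
  expect_identical(as.integer(li_ji_meff(matrix(1, 9, 9))), 1L)
  R2 <- matrix(c(1, .6, .6, 1), 2)
  m <- li_ji_meff(R2)
  expect_equal(attr(m, "raw"), 2.0, tolerance = 1e-12)  # f(1.6)+f(0.4)
  expect_error(li_ji_meff(matrix(c(1, .2, .6, 1), 2)), "symmetric")
})

test_that("study-wide thresholds reproduce the printed cutoffs", {
  expect_equal(study_threshold(37, 30, 3, 0.05), 1.50e-5, tolerance = 1e-3)
  expect_equal(study_threshold(1, 1, 1, 0.05), 0.05)
  expect_equal(study_threshold(42, 1, 1, 0.05), 1.19e-3, tolerance = 1e-3)
})

test_that("identical cohorts give identical round-robin rotations", {
  sp <- small_planted()
  one <- sp$pp$adj_shapes$cohortA
  shapes <- list(a = one, b = one, c = one)
  phen <- phenotype_cohorts(shapes, sp$spec$tree, pa_iter = 50, seed = 2)
  d <- sp$pp$dosage_residual$cohortA[, 1:3]
  meta <- round_robin_meta(phen, list(a = d, b = d, c = d))
  by_rot <- split(meta$p_meta, meta$rotation)
  expect_equal(by_rot[[1]], by_rot[[2]], tolerance = 1e-10)
  expect_equal(by_rot[[1]], by_rot[[3]], tolerance = 1e-10)
})

test_that("the planted SNP-module pair dominates the round-robin meta-analysis", {
  sp <- small_planted()
  phen <- phenotype_cohorts(sp$pp$adj_shapes, sp$spec$tree, pa_iter = 50, seed = 7)
  meta <- round_robin_meta(phen, sp$pp$dosage_residual,
                           threshold = study_threshold(10, 10, 3))
  top <- meta[which.max(meta$z_meta), ]
  expect_identical(top$snp, "rs_planted")
  # at this desk scale the best evidence sits on the planted module or its
  # direct lineage; strict localization is exercised at study scale in the
  # recovery suite
  planted <- meta[meta$snp == "rs_planted" & meta$module_id == 4L, ]
  expect_true(all(planted$significant))
  expect_true(top$module_id %in% c(4L, 2L, 8L, 9L))
  by_mod <- vapply(split(meta$z_meta[meta$snp == "rs_planted"],
                         meta$module_id[meta$snp == "rs_planted"]), max, numeric(1))
  expect_lte(which(names(sort(by_mod, decreasing = TRUE)) == "4"), 3L)
  # null SNPs stay near the nominal level (tests are correlated across
  # modules and rotations, so only a loose band is meaningful here)
  null_p <- meta$p_meta[meta$snp != "rs_planted"]
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.05)
})

test_that("stronger planted effects never weaken the median meta-analysis evidence", {
  zs <- vapply(c(0.2, 0.6), function(beta) {
    spec <- simulation_spec(
      n_subjects = c(150, 120, 160), L = 32, tree_depth = 2,
      snp_specs = tibble::tibble(id = "rs", maf = .3, beta = beta, target_module = 2L),
      seed = 99)
    pp <- preprocess_cohorts(spec)
    phen <- phenotype_cohorts(pp$adj_shapes, spec$tree, pa_iter = 50, seed = 99)
    meta <- round_robin_meta(phen, pp$dosage_residual, modules = 2L)
    median(meta$z_meta)
  }, numeric(1))
  expect_gt(zs[2], zs[1])
})

test_that("meff correlation matrices are valid inputs for Li-Ji", {
  sp <- small_planted()
  phen <- phenotype_cohorts(sp$pp$adj_shapes, sp$spec$tree, pa_iter = 50, seed = 1)
  cors <- meff_correlations(phen, lapply(sp$pp$cohorts, function(co) co$genotypes))
  expect_identical(dim(cors$modules), c(15L, 15L))
  expect_identical(dim(cors$snps), c(10L, 10L))
  m_mod <- li_ji_meff(cors$modules)
  expect_true(m_mod >= 1 && m_mod <= 15)
})
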