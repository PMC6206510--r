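test_that("ratios match direct distance measurements on the template", {
  tf <- generate_template_face(64)
  co <- tf$coordinates
  r <- compute_ratios(co, named_landmarks = tf$named_landmarks)
  nm <- tf$named_landmarks
  d <- function(a, b) sqrt(sum((co[nm[[a]], ] - co[nm[[b]], ])^2))
  expect_equal(r$fwhr_total, d("zygion_l", "zygion_r") / d("nasion", "gnathion"),
               tolerance = 1e-12)
  expect_equal(r$fwhr_upper, d("zygion_l", "zygion_r") / d("nasion", "prosthion"),
               tolerance = 1e-12)
  expect_equal(r$lower_to_total_height,
               d("stomion", "gnathion") / d("nasion", "gnathion"), tolerance = 1e-12)
  expect_identical(ncol(r), 5L)
})

test_that("ratios are invariant to similarity transforms", {
  tf <- generate_template_face(32)
  set.seed(1)
  cfg <- tf$coordinates + matrix(rnorm(32 * 3), 32, 3)
  r0 <- compute_ratios(cfg, named_landmarks = tf$named_landmarks)
  r_scaled <- compute_ratios(cfg * 2.3, named_landmarks = tf$named_landmarks)
  moved <- cfg %*% random_rotation(2) + matrix(c(10, -4, 6), 32, 3, byrow = TRUE)
  r_moved <- compute_ratios(moved, named_landmarks = tf$named_landmarks)
  expect_equal(r_scaled, r0, tolerance = 1e-10)
  expect_equal(r_moved, r0, tolerance = 1e-10)
})

test_that("bad ratio definitions fail loudly", {
  tf <- generate_template_face(32)
  defs <- tibble::tibble(name = "degenerate", num_a = "zygion_l", num_b = "zygion_r",
                         den_a = "nasion", den_b = "nasion")
  expect_error(compute_ratios(tf$coordinates, defs, tf$named_landmarks),
               "zero denominator.*degenerate")
  defs2 <- tibble::tibble(name = "x", num_a = "nose_tip", num_b = "zygion_r",
                          den_a = "nasion", den_b = "gnathion")
  expect_error(compute_ratios(tf$coordinates, defs2, tf$named_landmarks), "nose_tip")
})

test_that("ratio association keeps its nominal type-I error under the null", {
  n <- 120
  reps <- 2000
  hits <- 0L
  set.seed(10)
  for (i in seq_len(reps)) {
    covs <- tibble::tibble(sex = rbinom(n, 1, .5), age = runif(n, 5, 40),
                           height = rnorm(n, 170, 8), pc1 = rnorm(n),
                           pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n))
    ratio <- 1.8 + 0.02 * covs$sex + 0.001 * covs$age + rnorm(n, sd = 0.05)
    dosage <- rbinom(n, 2, 0.3)
    p <- ratio_association(ratio, dosage, covs)$p_value
    hits <- hits + (p < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.012)
})

test_that("power for a small planted ratio effect matches the analytic oracle", {
  # 0.1 residual-SD per allele, MAF 0.2, n = 2000: the slope z-statistic has
  # noncentrality 0.1 * sqrt(n * 2pq) ~ 2.53, so two-sided power at 0.05 is
  # ~0.72, and power at the 42-SNP Bonferroni cutoff is far below 0.8
  n <- 2000
  reps <- 150
  ncp <- 0.1 * sqrt(n * 2 * 0.2 * 0.8)
  pow_nominal <- pnorm(ncp - qnorm(0.975)) + pnorm(-ncp - qnorm(0.975))
  set.seed(20)
  p_vals <- vapply(seq_len(reps), function(i) {
    covs <- tibble::tibble(sex = rbinom(n, 1, .5), age = runif(n, 5, 40),
                           height = rnorm(n, 170, 8), pc1 = rnorm(n),
                           pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n))
    dosage <- rbinom(n, 2, 0.2)
    ratio <- 1.8 + 0.02 * covs$sex + 0.1 * 0.05 * dosage + rnorm(n, sd = 0.05)
    ratio_association(ratio, dosage, covs)$p_value
  }, numeric(1))
  expect_lt(abs(mean(p_vals < 0.05) - pow_nominal), 0.1)
  expect_lt(mean(p_vals < 0.05 / 42), 0.8)
})

test_that("two-stage p-values track a one-stage joint regression in rank order", {
  n <- 500
  set.seed(30)
  covs <- tibble::tibble(sex = rbinom(n, 1, .5), age = runif(n, 5, 40),
                         height = rnorm(n, 170, 8), pc1 = rnorm(n),
                         pc2 = rnorm(n), pc3 = rnorm(n), pc4 = rnorm(n))
  G <- vapply(seq(0.1, 0.45, length.out = 8), function(m) rbinom(n, 2, m), numeric(n))
  betas <- c(0, 0.001, 0.002, 0.004, 0, 0.006, 0.003, 0)
  two_stage <- joint <- numeric(8)
  for (s in 1:8) {
    ratio <- 1.8 + 0.02 * covs$sex + betas[s] * G[, s] + rnorm(n, sd = 0.05)
    two_stage[s] <- ratio_association(ratio, G[, s], covs)$p_value
    fit <- lm(ratio ~ G[, s] + sex + age + height + pc1 + pc2 + pc3 + pc4, data = covs)
    joint[s] <- summary(fit)$coefficients[2, 4]
  }
  expect_gt(cor(rank(two_stage), rank(joint)), 0.95)
})

test_that("subgroup scans filter before adjustment and flag at alpha over panel size", {
  sp <- small_planted()
  co <- sp$pp$cohorts$cohortA
  ratios <- compute_ratios(co$configurations,
                           named_landmarks = sp$spec$template$named_landmarks)
  males <- ratio_scan(ratios[, 1:2], co$genotypes[, 1:3], co$covariates,
                      subgroup = "male")
  expect_true(all(males$n == sum(co$covariates$sex == 1)))
  expect_equal(attr(males, "threshold"), 0.05 / 3)
  post <- ratio_scan(ratios[, 1, drop = FALSE], co$genotypes[, 1:2], co$covariates,
                     subgroup = "postpubertal")
  expect_true(all(post$n == sum(co$covariates$age > 14)))
})
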