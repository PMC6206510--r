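test_that("the same seed reproduces a cohort bitwise; different seeds differ", {
  spec1 <- simulation_spec(n_subjects = c(30, 25, 40), L = 32, seed = 9)
  spec2 <- simulation_spec(n_subjects = c(30, 25, 40), L = 32, seed = 9)
  spec3 <- simulation_spec(n_subjects = c(30, 25, 40), L = 32, seed = 10)
  a <- simulate_cohorts(spec1)
  b <- simulate_cohorts(spec2)
  c3 <- simulate_cohorts(spec3)
  expect_identical(a$cohortA$configurations, b$cohortA$configurations)
  expect_identical(a$cohortB$genotypes, b$cohortB$genotypes)
  expect_false(identical(a$cohortA$genotypes, c3$cohortA$genotypes))
})

test_that("genotypes follow Hardy-Weinberg draws at the stated MAF", {
  spec <- simulation_spec(n_subjects = c(2000, 20, 20), L = 32,
                          snp_specs = tibble::tibble(id = "s1", maf = 0.10,
                                                     beta = 0, target_module = NA),
                          seed = 4)
  g <- simulate_cohorts(spec)$cohortA$genotypes[, 1]
  expect_true(all(g %in% c(0, 1, 2)))
  phat <- mean(g) / 2
  # 99% binomial interval for the allele frequency at 2n draws
  half <- qnorm(0.995) * sqrt(0.1 * 0.9 / (2 * 2000))
  expect_gt(phat, 0.1 - half)
  expect_lt(phat, 0.1 + half)
})

test_that("dosage mode produces values in [0, 2] off the integer grid", {
  spec <- simulation_spec(n_subjects = c(50, 20, 20), L = 32,
                          dosage_mode = "dosage", seed = 2)
  g <- simulate_cohorts(spec)$cohortA$genotypes
  expect_true(all(g >= 0 & g <= 2))
  expect_false(all(g %in% c(0, 1, 2)))
})

test_that("with no planted effects, genotype-coordinate correlations center on zero", {
  spec <- simulation_spec(n_subjects = c(400, 20, 20), L = 32, seed = 6)
  co <- simulate_cohorts(spec)$cohortA
  flat <- matrix(co$configurations, nrow = 400)
  r <- cor(co$genotypes[, 1], flat)
  expect_lt(abs(mean(r)), 3 / sqrt(400))
  expect_lt(mean(abs(r)), 3 / sqrt(400))
})

test_that("a strong planted effect concentrates displacement energy on its module", {
  spec <- simulation_spec(
    n_subjects = c(600, 20, 20), L = 64, tree_depth = 3,
    snp_specs = tibble::tibble(id = "s", maf = 0.3, beta = 5, target_module = 4L),
    seed = 8)
  co <- simulate_cohorts(spec)$cohortA
  ali <- gpa(symmetrize(co$configurations, spec$template$mirror_map))
  f <- effect_field(ali$aligned, co$genotypes[, 1])
  lmk <- spec$tree$landmarks[[which(spec$tree$module_id == 4L)]]
  expect_gt(field_energy_concentration(f, lmk), 0.8)
})

test_that("invalid simulation parameters are rejected", {
  expect_error(simulation_spec(snp_specs = tibble::tibble(id = "x", maf = 0.6, beta = 0)),
               "MAF")
  expect_error(simulation_spec(snp_specs = tibble::tibble(id = "x", maf = 0.2, beta = -1)),
               "non-negative")
  expect_error(simulation_spec(n_subjects = c(10, -5, 10)), "positive")
  expect_error(simulation_spec(L = 15), "even")
  expect_error(simulation_spec(snp_specs = tibble::tibble(id = "x", maf = 0.2, beta = 1,
                                                          target_module = 999L)),
               "target_module")
})
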