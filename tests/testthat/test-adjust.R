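make_block <- function(n, seed = 1) {
  set.seed(seed)
  covariate_block(
    tibble::tibble(subject = sprintf("s%03d", 1:n), age = runif(n, 5, 40),
                   sex = rbinom(n, 1, .5), height = rnorm(n, 170, 7),
                   weight = rnorm(n, 70, 12), pc1 = rnorm(n), pc2 = rnorm(n),
                   pc3 = rnorm(n), pc4 = rnorm(n))[, -1],
    facial_size = rnorm(n, 450, 20))
}

test_that("the covariate block carries the ten adjustment covariates", {
  X <- make_block(50)
  expect_identical(colnames(X),
                   c("age", "age2", "sex", "weight", "height", "size",
                     paste0("pc", 1:4)))
  expect_equal(unname(X[, "age2"]), unname(X[, "age"])^2)
})

test_that("responses orthogonal to the covariates pass through unchanged", {
  n <- 80
  X <- make_block(n, seed = 2)
  Xs <- scale(unclass(X))
  set.seed(3)
  Y0 <- matrix(rnorm(n * 5), n, 5)
  # project Y away from the covariate span (and center)
  Q <- qr.Q(qr(cbind(1, Xs)))
  Y <- Y0 - Q %*% crossprod(Q, Y0)
  expect_equal(plsr_residualize(Y, X), Y, tolerance = 1e-8)
})

test_that("full-rank PLSR residuals coincide with OLS residuals", {
  n <- 120
  X <- make_block(n, seed = 4)
  set.seed(5)
  B <- matrix(rnorm(10 * 6), 10, 6)
  Y <- scale(unclass(X)) %*% B + matrix(rnorm(n * 6), n, 6)
  res <- plsr_residualize(Y, X)
  ols <- lm.fit(cbind(1, scale(unclass(X))), Y)$residuals
  expect_equal(res, ols, tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(colMeans(res))), 1e-8)
  expect_lt(max(abs(cor(res, unclass(X)))), 1e-6)
})

test_that("a dosage vector can be residualized like any response", {
  n <- 150
  X <- make_block(n, seed = 6)
  set.seed(7)
  d <- rbinom(n, 2, 0.3)
  r <- plsr_residualize(d, X)
  expect_identical(dim(r), c(as.integer(n), 1L))
  expect_lt(max(abs(cor(r, unclass(X)))), 1e-6)
})

test_that("fewer components remove less than the OLS fit", {
  n <- 100
  X <- make_block(n, seed = 8)
  set.seed(9)
  Y <- scale(unclass(X)) %*% matrix(rnorm(10 * 3), 10, 3) + matrix(rnorm(n * 3), n, 3)
  r2 <- plsr_residualize(Y, X, n_components = 2)
  r_full <- plsr_residualize(Y, X)
  expect_gt(sum(r2^2), sum(r_full^2))
  expect_error(plsr_residualize(Y, X, n_components = 99), "rank")
})

test_that("adjustment is cohort-local: pooling cohorts first gives different residuals", {
  sp <- small_planted()
  co_a <- sp$pp$cohorts$cohortA
  co_b <- sp$pp$cohorts$cohortB
  ali_a <- gpa(symmetrize(co_a$configurations, sp$spec$template$mirror_map))
  ali_b <- gpa(symmetrize(co_b$configurations, sp$spec$template$mirror_map))
  Xa <- covariate_block(co_a$covariates, ali_a$centroid_sizes)
  Xb <- covariate_block(co_b$covariates, ali_b$centroid_sizes)
  Ya <- flatten_signal <- matrix(ali_a$aligned, nrow = dim(ali_a$aligned)[1])
  Yb <- matrix(ali_b$aligned, nrow = dim(ali_b$aligned)[1])
  local_res <- rbind(plsr_residualize(Ya, Xa), plsr_residualize(Yb, Xb))
  pooled_res <- plsr_residualize(rbind(Ya, Yb), rbind(unclass(Xa), unclass(Xb)))
  expect_gt(max(abs(local_res - pooled_res)), 1e-4)
})

test_that("PLS component extraction agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  n <- 60
  X <- make_block(n, seed = 10)
  set.seed(11)
  Y <- scale(unclass(X)) %*% matrix(rnorm(10 * 4), 10, 4) + matrix(rnorm(n * 4), n, 4)
  res <- plsr_residualize(Y, X, n_components = 10)
  fit <- mixOmics::pls(unclass(X), Y, ncomp = 10, scale = TRUE, mode = "regression")
  pred <- predict(fit, unclass(X))$predict[, , 10]
  expect_equal(res, Y - pred, tolerance = 1e-4, ignore_attr = TRUE)
})
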