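test_that("centroid size matches its closed form and invariances", {
  sq <- cbind(c(.5, .5, -.5, -.5), c(.5, -.5, .5, -.5), 0)
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  set.seed(1)
  cfg <- matrix(rnorm(30), 10, 3)
  expect_equal(centroid_size(cfg * 3.7), 3.7 * centroid_size(cfg), tolerance = 1e-12)
  shifted <- sweep(cfg, 2, c(5, -2, 11), "+")
  expect_equal(centroid_size(shifted), centroid_size(cfg), tolerance = 1e-10)
})

test_that("GPA exactly recovers copies of one shape under random similarity transforms", {
  set.seed(2)
  base <- matrix(rnorm(20 * 3), 20, 3)
  n <- 8
  configs <- array(0, c(n, 20, 3))
  for (i in 1:n) {
    R <- random_rotation(i)
    configs[i, , ] <- (base %*% R) * runif(1, 0.5, 2) +
      matrix(rnorm(3, sd = 10), 20, 3, byrow = TRUE)
  }
  fit <- gpa(configs)
  for (i in 2:n)
    expect_equal(fit$aligned[i, , ], fit$aligned[1, , ], tolerance = 1e-8)
  expect_lt(glance(fit)$procrustes_ss, 1e-16)
})

test_that("GPA output is invariant to a common rotation and to subject order", {
  sp <- small_planted()
  configs <- sp$pp$cohorts$cohortB$configurations[1:40, , ]
  fit1 <- gpa(configs)
  fit2 <- gpa(rotate_configs(configs, random_rotation(5), shift = c(3, -7, 2)))
  expect_equal(fit1$aligned, fit2$aligned, tolerance = 1e-8)
  ord <- rev(seq_len(dim(configs)[1]))
  fit3 <- gpa(configs[ord, , ])
  expect_equal(fit3$aligned[ord, , ], fit1$aligned, tolerance = 1e-8)
})

test_that("the consensus of two shapes is Procrustes-equidistant from both", {
  set.seed(3)
  configs <- array(rnorm(2 * 12 * 3), c(2, 12, 3))
  fit <- gpa(configs)
  d1 <- sqrt(sum((fit$aligned[1, , ] - fit$consensus)^2))
  d2 <- sqrt(sum((fit$aligned[2, , ] - fit$consensus)^2))
  expect_equal(d1, d2, tolerance = 1e-8)
})

test_that("symmetrization is an exact idempotent projection onto mirror symmetry", {
  tf <- generate_template_face(32)
  expect_equal(symmetrize(tf$coordinates, tf$mirror_map), tf$coordinates,
               tolerance = 0)
  set.seed(4)
  cfg <- tf$coordinates + matrix(rnorm(32 * 3), 32, 3)
  s1 <- symmetrize(cfg, tf$mirror_map)
  expect_equal(symmetrize(s1, tf$mirror_map), s1, tolerance = 0)
  refl <- s1; refl[, 1] <- -refl[, 1]
  expect_equal(refl[tf$mirror_map, ], s1, tolerance = 0)
  mid <- which(tf$mirror_map == seq_len(32L))
  expect_true(all(s1[mid, 1] == 0))
  expect_error(symmetrize(cfg, c(2, 3, 1, 4:32)), "involution")
})

test_that("Mahalanobis QC flags a grossly displaced subject and respects the threshold", {
  sp <- small_planted()
  configs <- sp$pp$cohorts$cohortA$configurations[1:60, , ]
  fit0 <- gpa(configs)
  sd0 <- sd(fit0$aligned)
  configs[1, , ] <- configs[1, , ] * 1.0
  configs[1, 1:10, 1] <- configs[1, 1:10, 1] + 40  # large localized distortion
  fit <- gpa(configs)
  qc <- qc_outliers(fit, z_threshold = 2)
  expect_true(qc$flagged[1])
  expect_false(any(qc_outliers(fit, z_threshold = Inf)$flagged))
})

test_that("homogeneous cohorts flag roughly the Gaussian upper-tail fraction", {
  set.seed(6)
  n <- 400
  base <- matrix(rnorm(15 * 3), 15, 3) * 10
  configs <- array(0, c(n, 15, 3))
  for (i in 1:n) configs[i, , ] <- base + matrix(rnorm(45, sd = 0.5), 15, 3)
  qc <- qc_outliers(gpa(configs), z_threshold = 2)
  expect_lt(abs(mean(qc$flagged) - pnorm(2, lower.tail = FALSE)), 0.02)
})
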