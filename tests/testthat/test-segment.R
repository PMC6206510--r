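test_that("RV coefficient: self-similarity, rotation invariance, and r^2 reduction", {
  set.seed(1)
  X <- matrix(rnorm(200 * 3), 200, 3)
  Y <- matrix(rnorm(200 * 4), 200, 4)
  expect_equal(rv_coefficient(X, X), 1, tolerance = 1e-12)
  R <- random_rotation(2)
  expect_equal(rv_coefficient(X, X %*% R), 1, tolerance = 1e-10)
  expect_equal(rv_coefficient(X %*% R, Y), rv_coefficient(X, Y), tolerance = 1e-10)
  x <- rnorm(100); y <- 0.6 * x + rnorm(100)
  expect_equal(rv_coefficient(cbind(x), cbind(y)), cor(x, y)^2, tolerance = 1e-12)
  expect_error(rv_coefficient(matrix(1, 10, 2), Y[1:10, ]), "zero-variance")
})

test_that("the landmark RV matrix is symmetric, unit-diagonal and detects duplicates", {
  sp <- small_adjusted()
  shapes <- sp$shapes[1:80, 1:20, ]
  shapes[, 20, ] <- shapes[, 19, ]  # duplicated landmark
  RV <- landmark_rv_matrix(shapes)
  expect_equal(max(abs(RV - t(RV))), 0, tolerance = 1e-10)
  expect_equal(diag(RV), rep(1, 20))
  expect_true(all(RV >= 0 & RV <= 1))
  expect_equal(RV[19, 20], 1, tolerance = 1e-10)
})

test_that("independent landmarks give near-zero off-diagonal RV at large n", {
  set.seed(3)
  shapes <- array(rnorm(1000 * 12 * 3), c(1000, 12, 3))
  RV <- landmark_rv_matrix(shapes)
  off <- RV[upper.tri(RV)]
  expect_lt(mean(off), 0.05)
})

test_that("spectral bisection recovers planted similarity blocks exactly", {
  S <- matrix(0.05, 12, 12)
  S[1:5, 1:5] <- 0.9
  S[6:12, 6:12] <- 0.9
  diag(S) <- 1
  halves <- spectral_bisect(S)
  expect_setequal(halves[[which(vapply(halves, length, 1L) == 5)]], 1:5)
  # permuting the index order permutes, but does not change, the partition
  perm <- c(3, 9, 1, 12, 5, 7, 2, 11, 4, 8, 6, 10)
  halves_p <- spectral_bisect(S[perm, perm])
  sets_p <- lapply(halves_p, function(h) sort(perm[h]))
  expect_setequal(sets_p[[which(vapply(sets_p, function(s) 1 %in% s, TRUE))]], 1:5)
  expect_identical(spectral_bisect(matrix(c(1, .2, .2, 1), 2)), list(1L, 2L))
})

test_that("disconnected similarity graphs fall back to component splits", {
  S <- diag(6)
  S[1:3, 1:3] <- 1
  S[4:6, 4:6] <- 1
  halves <- spectral_bisect(S)
  expect_setequal(halves[[1]], if (1 %in% halves[[1]]) 1:3 else 4:6)
})

test_that("hierarchical segmentation yields the full bifurcating module hierarchy", {
  sp <- small_adjusted()
  tree <- hierarchical_segment(sp$shapes, depth = 4, min_leaf = 3)
  expect_identical(nrow(tree), 31L)
  expect_identical(as.integer(table(tree$level)), c(1L, 2L, 4L, 8L, 16L))
  expect_silent(validate_module_tree(tree, 64))
  expect_true(all(lengths(tree$landmarks[tree$level == 4]) >= 3))

  tree0 <- hierarchical_segment(sp$shapes, depth = 0)
  expect_identical(nrow(tree0), 1L)
  expect_identical(tree0$landmarks[[1]], 1:64)

  expect_error(hierarchical_segment(sp$shapes, depth = 9), "lower the depth")
})

test_that("segmentation is deterministic and honours a contiguity mask", {
  sp <- small_adjusted()
  t1 <- hierarchical_segment(sp$shapes, depth = 3)
  t2 <- hierarchical_segment(sp$shapes, depth = 3)
  expect_identical(t1$landmarks, t2$landmarks)
  tf <- generate_template_face(64)
  t3 <- hierarchical_segment(sp$shapes, depth = 3, min_leaf = 3,
                             adjacency = knn_adjacency(tf, 8))
  expect_silent(validate_module_tree(t3, 64))
})

test_that("two independent covariance blocks are recovered at the first split", {
  set.seed(9)
  n <- 300
  z1 <- matrix(rnorm(n * 3), n, 3)
  z2 <- matrix(rnorm(n * 3), n, 3)
  shapes <- array(0, c(n, 10, 3))
  for (j in 1:5) shapes[, j, ] <- z1 + matrix(rnorm(n * 3, sd = .3), n, 3)
  for (j in 6:10) shapes[, j, ] <- z2 + matrix(rnorm(n * 3, sd = .3), n, 3)
  tree <- hierarchical_segment(shapes, depth = 1)
  kids <- tree$landmarks[tree$level == 1]
  expect_true(identical(sort(kids[[1]]), 1:5) || identical(sort(kids[[1]]), 6:10))
})
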