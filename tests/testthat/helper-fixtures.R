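# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small three-cohort simulation with one planted mandibular effect
small_planted <- function() fixture("small_planted", function() {
  spec <- simulation_spec(
    n_subjects = c(300, 200, 400), L = 64, tree_depth = 3,
    snp_specs = tibble::tibble(
      id = c("rs_planted", paste0("null", 1:9)),
      maf = c(0.2, seq(0.1, 0.5, length.out = 9)),
      beta = c(0.6, rep(0, 9)),
      target_module = c(4L, rep(NA_integer_, 9))),
    seed = 42)
  list(spec = spec, pp = preprocess_cohorts(spec))
})

# one small aligned/adjusted cohort for segmentation & phenotype tests
small_adjusted <- function() fixture("small_adjusted", function() {
  sp <- small_planted()
  list(spec = sp$spec, shapes = sp$pp$adj_shapes[[1]],
       dosages = sp$pp$dosage_residual[[1]], cohort = sp$pp$cohorts[[1]])
})

random_rotation <- function(seed = 1) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}

rotate_configs <- function(configs, R, shift = c(0, 0, 0)) {
  out <- configs
  for (i in seq_len(dim(configs)[1]))
    out[i, , ] <- configs[i, , ] %*% R + matrix(shift, dim(configs)[2], 3, byrow = TRUE)
  out
}
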