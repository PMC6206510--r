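#' Specification of a synthetic multi-cohort study
#'
#' Captures everything the simulator needs: three cohort sizes (defaults
#' mirror the 2297/1555/3566 asymmetry of a three-cohort facial study,
#' scaled by `scale`), a landmark count, per-SNP minor allele frequencies
#' and planted effect sizes with optional target modules, covariate effect
#' sizes, the residual noise level and its spatial correlation range, and a
#' master seed that fully determines the output.
#'
#' @param n_subjects Integer vector of 3 cohort sizes (before scaling).
#' @param scale Multiplier applied to `n_subjects` (rounded, min 20 each).
#' @param L Landmark count (even, >= 16).
#' @param snp_specs Tibble/data frame with columns `id`, `maf` in (0, 0.5],
#'   `beta` (mm displacement per allele at the effect peak, >= 0) and
#'   `target_module` (module id in the template tree, or `NA` for a null
#'   SNP). Default: 10 null SNPs with MAFs spread over (0.05, 0.5).
#' @param covariate_effect_sizes Named vector: RMS shape displacement in mm
#'   per SD of `age`, `age2`, `sex`, `height`, `weight`; `allometry` is the
#'   SD of log centroid size; `ancestry` the per-axis displacement.
#' @param noise_sd Marginal residual SD per landmark coordinate (mm).
#' @param residual_range Range (mm) of the spatially decaying residual
#'   correlation kernel; gives the modular covariance structure segmentation
#'   relies on.
#' @param tree_depth Depth of the geometric template tree used to resolve
#'   `target_module` ids.
#' @param dosage_mode `"hard"` (genotypes in {0,1,2}) or `"dosage"`
#'   (imputation-style values in `[0,2]`).
#' @param seed Integer master seed.
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(n_subjects = c(2297, 1555, 3566), scale = 1,
                            L = 128, snp_specs = NULL,
                            covariate_effect_sizes = c(age = 0.8, age2 = 0.3,
                                                       sex = 1.2, height = 0.3,
                                                       weight = 0.3, allometry = 0.04,
                                                       ancestry = 0.1),
                            noise_sd = 1, residual_range = 30,
                            tree_depth = NULL, dosage_mode = c("hard", "dosage"),
                            seed = 1L) {
  dosage_mode <- match.arg(dosage_mode)
  assert_that(length(n_subjects) == 3 && all(n_subjects > 0), "need 3 positive cohort sizes")
  n_subjects <- pmax(as.integer(round(n_subjects * scale)), 20L)
  assert_that(L >= 16 && L %% 2 == 0, "L must be even and >= 16")
  # deepest tree whose leaves stay Procrustes-alignable (>= 3 landmarks)
  if (is.null(tree_depth)) tree_depth <- max(min(5L, floor(log2(L / 3))), 1L)
  if (is.null(snp_specs)) {
    snp_specs <- tibble::tibble(id = sprintf("snp%02d", 1:10),
                                maf = seq(0.05, 0.5, length.out = 10),
                                beta = 0, target_module = NA_integer_)
  }
  snp_specs <- tibble::as_tibble(snp_specs)
  need <- c("id", "maf", "beta")
  assert_that(all(need %in% names(snp_specs)), "snp_specs needs columns id, maf, beta")
  if (!"target_module" %in% names(snp_specs)) snp_specs$target_module <- NA_integer_
  assert_that(all(snp_specs$maf > 0 & snp_specs$maf <= 0.5), "MAF must lie in (0, 0.5]")
  assert_that(all(snp_specs$beta >= 0), "effect sizes must be non-negative")
  assert_that(noise_sd > 0, "noise_sd must be positive")
  template <- generate_template_face(L)
  tree <- template_module_tree(template, tree_depth)
  tgt <- snp_specs$target_module[!is.na(snp_specs$target_module)]
  assert_that(all(tgt %in% tree$module_id),
              "every target_module must resolve in the template module tree")
  structure(list(n_subjects = n_subjects, L = as.integer(L),
                 snp_specs = snp_specs,
                 covariate_effect_sizes = covariate_effect_sizes,
                 noise_sd = noise_sd, residual_range = residual_range,
                 tree_depth = as.integer(tree_depth), dosage_mode = dosage_mode,
                 seed = as.integer(seed), template = template, tree = tree),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("<simulation_spec> cohorts %s, L = %d, %d SNPs (%d with planted effects), seed %d\n",
              paste(x$n_subjects, collapse = "/"), x$L, nrow(x$snp_specs),
              sum(x$snp_specs$beta > 0 & !is.na(x$snp_specs$target_module)), x$seed))
  invisible(x)
}

# smooth unit-RMS random displacement field over the template (L x 3)
smooth_field <- function(template, range_mm, seed) {
  coords <- template$coordinates
  L <- nrow(coords)
  K <- exp(-as.matrix(dist(coords))^2 / (2 * range_mm^2))
  K <- K / rowSums(K)
  F0 <- with_local_seed(seed, matrix(rnorm(L * 3), L, 3))
  Fs <- K %*% F0
  Fs / sqrt(mean(Fs^2))
}

# planted SNP displacement field confined to a module: a smooth radial
# deformation with opposite sign on the module's two halves (its children
# when known), with the module's similarity components (translation, scale,
# rotations) projected out. Within either half the field is close to a
# rigid push — absorbed by that half's own superimposition — so the module
# as a whole, not a descendant, is the natural detection unit; and the
# full-face superimposition cannot absorb it either. Peak landmark
# displacement normalized to 1, so beta is mm per allele.
snp_effect_field <- function(template, landmarks, halves = NULL) {
  coords <- template$coordinates
  sub <- coords[landmarks, , drop = FALSE]
  m <- length(landmarks)
  ctr_mod <- colMeans(sub)
  cen <- sweep(sub, 2, ctr_mod)
  r2 <- rowSums(cen^2)
  # kernel SD = 2 x module RMS radius: smooth decay, energy spread over the
  # whole module rather than a tight peak
  sig2 <- max(4 * mean(r2), 1e-6)
  k <- exp(-r2 / (2 * sig2))
  sgn <- rep(1, m)
  if (!is.null(halves)) {
    sgn[landmarks %in% halves[[2]]] <- -1
  } else if (m >= 2) {
    # split along the module's principal axis
    pc1 <- svd(cen, nu = 0, nv = 1)$v[, 1]
    sgn <- ifelse(as.numeric(cen %*% pc1) >= median(cen %*% pc1), 1, -1)
  }
  ctr_face <- colMeans(coords)
  dirs <- sweep(sub, 2, ctr_face)
  dirs <- dirs / pmax(sqrt(rowSums(dirs^2)), 1e-9)
  u <- as.vector(dirs * k * sgn)                 # stacked (x, y, z) columns
  # similarity-transform basis of the module: 3 translations, scale, 3 rotations
  zero <- numeric(m)
  B <- cbind(c(rep(1, m), zero, zero), c(zero, rep(1, m), zero),
             c(zero, zero, rep(1, m)), as.vector(cen),
             as.vector(cbind(-cen[, 2], cen[, 1], zero)),
             as.vector(cbind(-cen[, 3], zero, cen[, 1])),
             as.vector(cbind(zero, -cen[, 3], cen[, 2])))
  Q <- qr.Q(qr(B))
  u <- u - Q %*% crossprod(Q, u)
  Um <- matrix(u, m, 3)
  peak <- max(sqrt(rowSums(Um^2)))
  assert_that(peak > 0, "degenerate effect field")
  U <- matrix(0, nrow(coords), 3)
  U[landmarks, ] <- Um / peak
  U
}

#' Simulate three cohorts with the structure the pipeline assumes
#'
#' Per cohort: covariates are drawn from documented distributions (age ~
#' U(3, 40) yrs; sex ~ Bernoulli(0.5); sex-shifted normal height and weight;
#' four standard-normal ancestry axes), genotypes under Hardy–Weinberg
#' equilibrium at each SNP's MAF, and each subject's configuration is
#'
#' `size * (template + covariate fields + SNP bumps + ancestry fields +
#' spatially correlated residual)`,
#'
#' followed by a random rigid motion (so superimposition has real work to
#' do). Covariate and ancestry effects act through smooth, seed-fixed
#' displacement fields; planted SNP effects are radial Gaussian bumps
#' confined to their target module, `beta` mm per allele at the peak. The
#' residual has a distance-decaying covariance (range `residual_range` mm),
#' giving landmarks the spatial correlation structure that makes the
#' segmentation non-trivial. Each cohort gets its own sub-seed; everything
#' is reproducible from `spec$seed`.
#'
#' @param spec A [simulation_spec()].
#' @return Named list of three [cohort_dataset()] objects
#'   (`cohortA/B/C`), with the spec attached as attribute `spec`.
#' @export
simulate_cohorts <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  tpl <- spec$template
  L <- spec$L
  coords <- tpl$coordinates
  ces <- spec$covariate_effect_sizes
  field_range <- max(spec$residual_range, 15)

  shape_covs <- c("age", "age2", "sex", "height", "weight")
  fields <- lapply(seq_along(shape_covs), function(i)
    smooth_field(tpl, field_range, seed = spec$seed * 101L + i))
  names(fields) <- shape_covs
  anc_fields <- lapply(1:4, function(i)
    smooth_field(tpl, field_range, seed = spec$seed * 101L + 50L + i))

  snp_fields <- vector("list", nrow(spec$snp_specs))
  for (s in seq_len(nrow(spec$snp_specs))) {
    tm <- spec$snp_specs$target_module[s]
    if (!is.na(tm) && spec$snp_specs$beta[s] > 0) {
      lmk <- spec$tree$landmarks[[which(spec$tree$module_id == tm)]]
      ch <- c(2L * tm, 2L * tm + 1L)
      halves <- if (all(ch %in% spec$tree$module_id))
        lapply(ch, function(id) spec$tree$landmarks[[which(spec$tree$module_id == id)]])
      else NULL
      snp_fields[[s]] <- snp_effect_field(tpl, lmk, halves)
    }
  }

  # residual covariance factor (shared across cohorts)
  K <- exp(-as.matrix(dist(coords))^2 / (2 * spec$residual_range^2))
  Kc <- chol(K + diag(1e-6, L))

  cohort_names <- c("cohortA", "cohortB", "cohortC")
  out <- lapply(1:3, function(ci) {
    n <- spec$n_subjects[ci]
    with_local_seed(spec$seed + ci, {
      age <- runif(n, 3, 40)
      sex <- rbinom(n, 1, 0.5)
      height <- rnorm(n, ifelse(sex == 1, 177, 163), ifelse(sex == 1, 7, 6.5))
      weight <- rnorm(n, ifelse(sex == 1, 79, 66), ifelse(sex == 1, 12, 11))
      anc <- matrix(rnorm(n * 4), n, 4)
      covs <- tibble::tibble(
        subject = sprintf("%s_%04d", cohort_names[ci], seq_len(n)),
        age = age, sex = sex, height = height, weight = weight,
        pc1 = anc[, 1], pc2 = anc[, 2], pc3 = anc[, 3], pc4 = anc[, 4])

      S <- nrow(spec$snp_specs)
      G <- vapply(seq_len(S), function(s) rbinom(n, 2, spec$snp_specs$maf[s]),
                  numeric(n))
      if (spec$dosage_mode == "dosage")
        G <- pmin(pmax(G + matrix(rnorm(n * S, 0, 0.1), n, S), 0), 2)
      colnames(G) <- spec$snp_specs$id
      rownames(G) <- covs$subject

      zc <- cbind(age = scale(age)[, 1], age2 = scale(age^2)[, 1],
                  sex = (sex - 0.5) * 2, height = scale(height)[, 1],
                  weight = scale(weight)[, 1])
      size_fac <- exp(ces[["allometry"]] * (0.6 * zc[, "height"] + 0.8 * rnorm(n)))

      configs <- array(0, dim = c(n, L, 3))
      noise_z <- array(rnorm(n * L * 3), dim = c(n, L, 3))
      rot_small <- function(angles) {
        cx <- cos(angles[1]); sx <- sin(angles[1])
        cy <- cos(angles[2]); sy <- sin(angles[2])
        cz <- cos(angles[3]); sz <- sin(angles[3])
        Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
        Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
        Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
        Rx %*% Ry %*% Rz
      }
      angles <- matrix(runif(n * 3, -0.2, 0.2), n, 3)
      shifts <- matrix(rnorm(n * 3, 0, 10), n, 3)

      for (i in seq_len(n)) {
        shp <- coords
        for (cv in shape_covs)
          shp <- shp + ces[[cv]] * zc[i, cv] * fields[[cv]]
        for (a in 1:4)
          shp <- shp + ces[["ancestry"]] * anc[i, a] * anc_fields[[a]]
        for (s in seq_len(S)) {
          if (!is.null(snp_fields[[s]]))
            shp <- shp + spec$snp_specs$beta[s] * G[i, s] * snp_fields[[s]]
        }
        eps <- spec$noise_sd * crossprod(Kc, noise_z[i, , ])
        shp <- size_fac[i] * (shp + eps)
        configs[i, , ] <- shp %*% rot_small(angles[i, ]) +
          matrix(shifts[i, ], L, 3, byrow = TRUE)
      }

      emp_maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
      meta <- tibble::tibble(id = spec$snp_specs$id,
                             location = sprintf("1:%d", 10000L + 1000L * seq_len(S)),
                             alleles = "G>A",
                             maf = as.numeric(emp_maf),
                             maf_target = spec$snp_specs$maf)
      cohort_dataset(cohort_id = cohort_names[ci], configurations = configs,
                     covariates = covs, genotypes = G, snp_meta = meta)
    })
  })
  names(out) <- cohort_names
  attr(out, "spec") <- spec
  out
}
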