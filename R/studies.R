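#' Null-calibration study of the round-robin meta-analysis
#'
#' Simulates three cohorts with *no* genetic effects, runs the full
#' preprocessing/segmentation-tree phenotyping chain and the round-robin
#' CCA + projection + Stouffer meta-analysis for every (SNP, module,
#' rotation), and returns the meta-analysis table. Under this global null
#' the meta p-values should be Uniform(0, 1); the empirical rejection rate
#' at any alpha estimates the pipeline's type-I error.
#'
#' @param seed Master seed.
#' @param n_subjects Cohort sizes (default 300/200/400 — a deliberately
#'   modest desk-scale study).
#' @param L Landmark count.
#' @param depth Module-tree depth (template tree; default 4, 31 modules).
#' @param n_snps Number of null SNPs (MAFs spread over 0.1–0.5).
#' @param pa_iter Parallel-analysis permutations.
#' @return The `meta_result` tibble (`n_snps x modules x 3` rows).
#' @export
null_calibration_study <- function(seed = 1, n_subjects = c(300, 200, 400),
                                   L = 64, depth = 4, n_snps = 120,
                                   pa_iter = 50) {
  spec <- simulation_spec(
    n_subjects = n_subjects, L = L, tree_depth = depth,
    snp_specs = tibble::tibble(id = sprintf("null%03d", seq_len(n_snps)),
                               maf = rep(seq(0.1, 0.5, length.out = 30),
                                         length.out = n_snps),
                               beta = 0, target_module = NA_integer_),
    seed = seed)
  pp <- preprocess_cohorts(spec)
  phen <- phenotype_cohorts(pp$adj_shapes, spec$tree, pa_iter = pa_iter, seed = seed)
  round_robin_meta(phen, pp$dosage_residual)
}

#' Planted-effect recovery study
#'
#' For each seed: simulate three cohorts with one SNP whose effect (0.5
#' residual-SD per allele at the peak, MAF 0.2 by default) is planted on
#' the mandibular module (the level-2 template module containing gnathion),
#' run phenotyping and the round-robin meta-analysis over *all* modules of
#' the tree, and record (a) whether the planted module attains the best
#' meta-analysis evidence of all modules and (b) the fraction of the
#' recovered per-landmark displacement field's energy that falls inside the
#' planted module.
#'
#' @param n_seeds Number of independent replicates.
#' @param seed Base seed (replicate `i` uses `seed + i`).
#' @param n_subjects Cohort sizes (default 1000/700/1300).
#' @param L Landmark count (default 96).
#' @param beta Planted peak effect in units of the residual SD per allele.
#' @param maf Minor allele frequency of the planted SNP.
#' @param depth Tree depth (default 5: 63 modules).
#' @param target_level Tree level of the planted module (default 2).
#' @param pa_iter Parallel-analysis permutations.
#' @return Tibble: `seed`, `target_module`, `best_module`, `recovered`
#'   (best == target), `energy_concentration`.
#' @export
planted_recovery_study <- function(n_seeds = 50, seed = 1,
                                   n_subjects = c(1000, 700, 1300), L = 96,
                                   beta = 0.5, maf = 0.2, depth = 5,
                                   target_level = 2, pa_iter = 50) {
  res <- lapply(seq_len(n_seeds), function(i) {
    s <- seed + i
    base <- simulation_spec(L = L, tree_depth = depth, seed = s)
    tgt <- module_containing(base$tree, base$template, "gnathion", target_level)
    spec <- simulation_spec(
      n_subjects = n_subjects, L = L, tree_depth = depth,
      snp_specs = tibble::tibble(id = "rs_planted", maf = maf,
                                 beta = beta * 1,  # noise_sd = 1 mm
                                 target_module = tgt),
      seed = s)
    pp <- preprocess_cohorts(spec)
    phen <- phenotype_cohorts(pp$adj_shapes, spec$tree, pa_iter = pa_iter, seed = s)
    meta <- round_robin_meta(phen, pp$dosage_residual)
    by_mod <- vapply(split(meta$z_meta, meta$module_id), max, numeric(1))
    best <- as.integer(names(by_mod)[which.max(by_mod)])
    pooled <- do.call(abind3, pp$adj_shapes)
    dall <- unlist(lapply(pp$cohorts, function(co) co$genotypes[, 1]), use.names = FALSE)
    conc <- field_energy_concentration(
      effect_field(pooled, dall),
      spec$tree$landmarks[[which(spec$tree$module_id == tgt)]])
    tibble::tibble(seed = s, target_module = tgt, best_module = best,
                   recovered = best == tgt, energy_concentration = conc)
  })
  dplyr::bind_rows(res)
}

#' Symmetrize, superimpose and covariate-adjust simulated cohorts
#'
#' The shared preprocessing chain: per cohort, symmetrize with the template
#' mirror map, Procrustes-align, build the covariate block (with centroid
#' size), PLSR-adjust shapes and dosages.
#'
#' @param spec A `simulation_spec` (its template supplies the mirror map).
#' @param cohorts Optional pre-simulated cohorts (default: simulate from
#'   `spec`).
#' @return List: `cohorts`, `adj_shapes` (named list of arrays),
#'   `dosage_residual` (named list of matrices), `aligned` (per-cohort
#'   `aligned_set`s).
#' @export
preprocess_cohorts <- function(spec, cohorts = NULL) {
  if (is.null(cohorts)) cohorts <- simulate_cohorts(spec)
  mirror <- spec$template$mirror_map
  adj <- list(); dres <- list(); ali_all <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    ali <- gpa(symmetrize(co$configurations, mirror))
    X <- covariate_block(co$covariates, ali$centroid_sizes)
    adj[[cn]] <- adjust_shapes(ali, X)
    dres[[cn]] <- plsr_residualize(co$genotypes, X)
    colnames(dres[[cn]]) <- colnames(co$genotypes)
    ali_all[[cn]] <- ali
  }
  list(cohorts = cohorts, adj_shapes = adj, dosage_residual = dres, aligned = ali_all)
}
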