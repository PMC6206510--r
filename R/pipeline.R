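#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file path) controlling every
#' stage: data source, QC, adjustment, segmentation, phenotyping,
#' association and reporting. Unknown keys are rejected before any compute.
#'
#' @param config Named list or path to a YAML file.
#' @return Completed configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  assert_that(is.list(config), "config must be a list or a YAML file path")
  defaults <- list(
    simulation = NULL,      # args for simulation_spec()
    paths = NULL,           # named list of cohort directories
    subgroup = "all",       # all | male | female | postpubertal
    qc_z = 2, qc_strict = FALSE,
    plsr_components = NULL,
    maf_threshold = 0.05,
    depth = 5, min_leaf = 3, contiguity = FALSE, knn_k = 8,
    pa_iter = 200, pa_percentile = 95,
    weights = "equal",
    alpha = 0.05,
    out_dir = NULL, force = FALSE,
    seed = 1L)
  unknown <- setdiff(names(config), names(defaults))
  assert_that(length(unknown) == 0,
              paste("unknown config keys:", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, config)
  assert_that(cfg$subgroup %in% c("all", "male", "female", "postpubertal"),
              "subgroup must be one of all/male/female/postpubertal")
  assert_that(cfg$weights %in% c("equal", "sqrt_n"), "weights must be equal or sqrt_n")
  assert_that(cfg$alpha > 0 && cfg$alpha < 1, "alpha must lie in (0, 1)")
  assert_that(cfg$depth >= 0, "depth must be non-negative")
  assert_that(!is.null(cfg$simulation) || !is.null(cfg$paths),
              "config needs either a simulation block or cohort paths")
  class(cfg) <- c("pipeline_config", class(cfg))
  cfg
}

load_cohorts_from_paths <- function(paths) {
  out <- lapply(names(paths), function(cn) {
    dir <- paths[[cn]]
    lm <- read_landmarks(file.path(dir, "landmarks.tsv"))
    covs <- tibble::as_tibble(read.table(file.path(dir, "covariates.tsv"),
                                         header = TRUE, sep = "\t"))
    geno <- read_genotypes(file.path(dir, "dosages.tsv"), mode = "matrix",
                           subjects = covs$subject)
    meta_path <- file.path(dir, "snp_meta.tsv")
    meta <- if (file.exists(meta_path))
      tibble::as_tibble(read.table(meta_path, header = TRUE, sep = "\t"))
    else geno$snp_meta
    cohort_dataset(cohort_id = cn, configurations = lm$configurations,
                   covariates = covs, genotypes = geno$genotypes, snp_meta = meta)
  })
  names(out) <- names(paths)
  out
}

subgroup_filter <- function(cohort, subgroup) {
  keep <- switch(subgroup,
                 all = rep(TRUE, nrow(cohort$covariates)),
                 male = cohort$covariates$sex == 1,
                 female = cohort$covariates$sex == 0,
                 postpubertal = cohort$covariates$age > 15)
  cohort$configurations <- cohort$configurations[keep, , , drop = FALSE]
  cohort$covariates <- cohort$covariates[keep, ]
  cohort$genotypes <- cohort$genotypes[keep, , drop = FALSE]
  cohort
}

#' Run the full modular association pipeline
#'
#' Orchestrates simulate/load, symmetrization, Procrustes superimposition,
#' outlier QC, PLSR covariate adjustment of shapes and dosages (per
#' cohort), MAF filtering across cohorts, RV-based hierarchical
#' segmentation of the pooled adjusted shapes, per-module phenotyping with
#' parallel analysis, round-robin CCA/projection/Stouffer meta-analysis
#' with Li–Ji-corrected thresholds, and the facial-ratio association arm.
#' Deterministic given the config seed. If `out_dir` is set, result tables
#' are written as TSV plus a JSON manifest; a completed output directory is
#' not overwritten unless `force` is set.
#'
#' @param config A [pipeline_config()] (or list / YAML path coerced by it).
#' @return A `face_pipeline` result bundle: module tree, QC, meta-analysis
#'   tibble, thresholds, ratio results, and the config.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  t0 <- Sys.time()
  log_stage <- function(fmt, ...) message(sprintf(paste0("[facemods] ", fmt), ...))

  if (!is.null(cfg$out_dir)) {
    manifest_path <- file.path(cfg$out_dir, "manifest.json")
    if (file.exists(manifest_path) && !isTRUE(cfg$force)) {
      log_stage("output directory already complete; use force = TRUE to rerun")
      return(invisible(NULL))
    }
  }

  # --- data -----------------------------------------------------------
  if (!is.null(cfg$simulation)) {
    spec <- do.call(simulation_spec, c(cfg$simulation,
                                       if (is.null(cfg$simulation$seed)) list(seed = cfg$seed)))
    cohorts <- simulate_cohorts(spec)
    mirror_map <- spec$template$mirror_map
    template <- spec$template
    log_stage("simulated %d cohorts (n = %s, L = %d)", length(cohorts),
              paste(spec$n_subjects, collapse = "/"), spec$L)
  } else {
    cohorts <- load_cohorts_from_paths(cfg$paths)
    template <- generate_template_face(dim(cohorts[[1]]$configurations)[2])
    mirror_map <- template$mirror_map
    log_stage("loaded %d cohorts from disk", length(cohorts))
  }
  L <- dim(cohorts[[1]]$configurations)[2]
  assert_that(L >= cfg$min_leaf * 2^cfg$depth,
              sprintf("depth %d with min_leaf %d needs L >= %d but L = %d",
                      cfg$depth, cfg$min_leaf, cfg$min_leaf * 2^cfg$depth, L))

  if (cfg$subgroup != "all") {
    cohorts <- lapply(cohorts, subgroup_filter, subgroup = cfg$subgroup)
    log_stage("subgroup '%s': n = %s", cfg$subgroup,
              paste(vapply(cohorts, function(co) nrow(co$covariates), 1L), collapse = "/"))
  }

  # --- MAF filter (on hard/raw dosages, across all cohorts) ------------
  mf <- maf_filter(cohorts, cfg$maf_threshold)
  cohorts <- mf$cohorts
  if (nrow(mf$excluded)) log_stage("MAF filter dropped %d SNP(s)", length(unique(mf$excluded$id)))

  # --- shape preprocessing per cohort ---------------------------------
  qc_tables <- list(); adj_shapes <- list(); dos_resid <- list()
  for (cn in names(cohorts)) {
    co <- cohorts[[cn]]
    sym <- symmetrize(co$configurations, mirror_map)
    ali <- gpa(sym)
    qc <- qc_outliers(ali, z_threshold = cfg$qc_z)
    qc$cohort <- cn
    qc_tables[[cn]] <- qc
    if (isTRUE(cfg$qc_strict) && any(qc$flagged)) {
      keep <- !qc$flagged
      co$configurations <- co$configurations[keep, , , drop = FALSE]
      co$covariates <- co$covariates[keep, ]
      co$genotypes <- co$genotypes[keep, , drop = FALSE]
      sym <- symmetrize(co$configurations, mirror_map)
      ali <- gpa(sym)
      cohorts[[cn]] <- co
    }
    X <- covariate_block(co$covariates, ali$centroid_sizes)
    adj_shapes[[cn]] <- adjust_shapes(ali, X, cfg$plsr_components)
    dos_resid[[cn]] <- plsr_residualize(co$genotypes, X, cfg$plsr_components)
    colnames(dos_resid[[cn]]) <- colnames(co$genotypes)
    log_stage("cohort %s: aligned %d subjects (%d QC flags), adjusted shapes + dosages",
              cn, nrow(qc), sum(qc$flagged))
  }

  # --- segmentation on all cohorts combined ---------------------------
  pooled <- do.call(abind3, adj_shapes)
  adjacency <- if (isTRUE(cfg$contiguity)) knn_adjacency(template, cfg$knn_k) else NULL
  tree <- hierarchical_segment(pooled, depth = cfg$depth, min_leaf = cfg$min_leaf,
                               adjacency = adjacency)
  log_stage("segmented %d landmarks into %d modules (depth %d)", L, nrow(tree), cfg$depth)

  # --- phenotyping ----------------------------------------------------
  phenos <- phenotype_cohorts(adj_shapes, tree, pa_iter = cfg$pa_iter,
                              pa_percentile = cfg$pa_percentile, seed = cfg$seed)
  log_stage("phenotyped %d modules x %d cohorts", nrow(tree), length(cohorts))

  # --- multiple-testing correction ------------------------------------
  raw_dosages <- lapply(cohorts, function(co) co$genotypes)
  cors <- meff_correlations(phenos, raw_dosages)
  meff_mod <- li_ji_meff(cors$modules)
  meff_snp <- li_ji_meff(cors$snps)
  thr <- study_threshold(meff_mod, meff_snp, 3, cfg$alpha)

  # --- association ----------------------------------------------------
  meta <- round_robin_meta(phenos, dos_resid, weights = cfg$weights, threshold = thr)
  log_stage("meta-analysis: %d SNP x module x rotation tests, threshold %.3g",
            nrow(meta), thr)

  # --- ratio arm (first cohort, raw configurations) -------------------
  co1 <- cohorts[[1]]
  ratios <- compute_ratios(co1$configurations, named_landmarks = template$named_landmarks)
  ratio_res <- ratio_scan(ratios, co1$genotypes, co1$covariates,
                          subgroup = "all", alpha = cfg$alpha)
  ratio_thr <- attr(ratio_res, "threshold")

  bundle <- structure(list(
    config = cfg, tree = tree, qc = dplyr::bind_rows(qc_tables),
    excluded_snps = mf$excluded, meta = meta,
    meff_modules = meff_mod, meff_snps = meff_snp,
    threshold = thr, ratio_threshold = ratio_thr,
    ratios = ratio_res, phenos = phenos,
    template = template,
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "face_pipeline")

  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

# bind n x L x 3 arrays along subjects
abind3 <- function(...) {
  arrs <- list(...)
  n <- sum(vapply(arrs, function(a) dim(a)[1], 1L))
  out <- array(0, dim = c(n, dim(arrs[[1]])[2], 3))
  at <- 0L
  for (a in arrs) {
    out[at + seq_len(dim(a)[1]), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(as.data.frame(bundle$meta), file.path(dir, "meta_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(bundle$qc), file.path(dir, "qc_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(bundle$ratios), file.path(dir, "ratio_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(bundle$excluded_snps))
    write.table(as.data.frame(bundle$excluded_snps), file.path(dir, "maf_excluded.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  write_module_tree(bundle$tree, file.path(dir, "module_tree.tsv"))
  cfg <- bundle$config
  cfg$simulation <- NULL  # spec objects are not JSON; seeds recorded below
  jsonlite::write_json(
    list(seed = bundle$config$seed, threshold = bundle$threshold,
         ratio_threshold = bundle$ratio_threshold,
         meff_modules = as.integer(bundle$meff_modules),
         meff_snps = as.integer(bundle$meff_snps),
         config = cfg[!vapply(cfg, is.null, TRUE) & names(cfg) != ""],
         elapsed_sec = bundle$elapsed),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.face_pipeline <- function(x, ...) {
  cat(sprintf("<face_pipeline> %d modules, %d meta tests, threshold %.3g (%.1fs)\n",
              nrow(x$tree), nrow(x$meta), x$threshold, x$elapsed))
  invisible(x)
}

#' Summarize a pipeline result bundle
#'
#' Per-SNP, per-module rows sorted by meta-analysis p-value, with the
#' study-wide and ratio-arm thresholds echoed in the header attributes.
#'
#' @param bundle A `face_pipeline` from [run_pipeline()].
#' @param top Number of rows to print (all rows are returned).
#' @return Tibble of meta-analysis results sorted by `p_meta` (invisible
#'   columns: attributes `threshold`, `ratio_threshold`).
#' @export
report <- function(bundle, top = 10) {
  if (is.null(bundle) || nrow(bundle$meta) == 0) {
    warning("empty or incomplete result bundle; returning empty report")
    return(tibble::tibble(snp = character(), module_id = integer(),
                          rotation = character(), cc = numeric(),
                          p_discovery = numeric(), p_meta = numeric(),
                          significant = logical()))
  }
  tb <- dplyr::arrange(tibble::as_tibble(bundle$meta), .data$p_meta)
  cat(sprintf("Study-wide threshold: %.3g (Meff modules %d x Meff SNPs %d x 3 rotations)\n",
              bundle$threshold, as.integer(bundle$meff_modules),
              as.integer(bundle$meff_snps)))
  cat(sprintf("Ratio-arm threshold:  %.3g\n", bundle$ratio_threshold))
  print(head(tb, top))
  attr(tb, "threshold") <- bundle$threshold
  attr(tb, "ratio_threshold") <- bundle$ratio_threshold
  invisible(tb)
}

#' @method tidy face_pipeline
#' @export
tidy.face_pipeline <- function(x, ...) tibble::as_tibble(x$meta)

#' @method glance face_pipeline
#' @export
glance.face_pipeline <- function(x, ...) {
  tibble::tibble(n_modules = nrow(x$tree), n_tests = nrow(x$meta),
                 meff_modules = as.integer(x$meff_modules),
                 meff_snps = as.integer(x$meff_snps),
                 threshold = x$threshold,
                 n_significant = sum(x$meta$significant, na.rm = TRUE),
                 elapsed_sec = x$elapsed)
}
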