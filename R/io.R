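#' Bundle one cohort's shapes, covariates and genotypes
#'
#' Validates and canonicalizes a cohort: all tables must share subject count
#' and ordering (subjects are sorted by ID once, here, and never reordered
#' again), dosages must lie in `[0, 2]`, and for hard-called genotypes the
#' stored MAF must match the empirical folded allele frequency to 1e-6.
#'
#' @param cohort_id Cohort label.
#' @param configurations `n x L x 3` array (mm).
#' @param covariates Tibble with `subject`, `age`, `sex`, `height`,
#'   `weight`, `pc1`..`pc4`.
#' @param genotypes `n x S` dosage matrix, rownames = subject IDs.
#' @param snp_meta Tibble with `id`, `location`, `alleles`, `maf` (and
#'   optionally more columns).
#' @return A validated `cohort_dataset` list.
#' @export
cohort_dataset <- function(cohort_id, configurations, covariates, genotypes, snp_meta) {
  assert_that(length(dim(configurations)) == 3 && dim(configurations)[3] == 3,
              "configurations must be n x L x 3")
  n <- dim(configurations)[1]
  covariates <- tibble::as_tibble(covariates)
  assert_that(nrow(covariates) == n, "covariates row count must match configurations")
  assert_that("subject" %in% names(covariates), "covariates need a subject column")
  genotypes <- as.matrix(genotypes)
  assert_that(nrow(genotypes) == n, "genotype row count must match configurations")
  assert_that(!anyNA(genotypes), "missing dosages are not supported")
  assert_that(all(genotypes >= 0 & genotypes <= 2), "dosages must lie in `[0, 2]`")
  snp_meta <- tibble::as_tibble(snp_meta)
  assert_that(nrow(snp_meta) == ncol(genotypes), "snp_meta must have one row per SNP")
  assert_that(all(c("id", "maf") %in% names(snp_meta)), "snp_meta needs id and maf columns")

  # canonical subject order: sorted IDs, applied to every array
  ord <- order(covariates$subject)
  covariates <- covariates[ord, ]
  configurations <- configurations[ord, , , drop = FALSE]
  genotypes <- genotypes[ord, , drop = FALSE]
  if (!is.null(rownames(genotypes)))
    assert_that(identical(rownames(genotypes), covariates$subject),
                "genotype rownames do not match covariate subject IDs")

  hard <- all(genotypes %in% c(0, 1, 2))
  if (hard) {
    emp <- pmin(colMeans(genotypes) / 2, 1 - colMeans(genotypes) / 2)
    assert_that(max(abs(emp - snp_meta$maf)) < 1e-6,
                "stored MAF does not match empirical allele frequency (hard calls)")
  }
  structure(list(cohort_id = cohort_id, configurations = configurations,
                 covariates = covariates, genotypes = genotypes,
                 snp_meta = snp_meta),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  d <- dim(x$configurations)
  cat(sprintf("<cohort_dataset> %s: %d subjects, %d landmarks, %d SNPs\n",
              x$cohort_id, d[1], d[2], ncol(x$genotypes)))
  invisible(x)
}

#' Read a wide landmark table
#'
#' One row per subject, columns `x1,y1,z1,x2,...` (3 per landmark), tab- or
#' comma-separated with a header. Ragged rows, non-numeric cells and a
#' column count not divisible by 3 are rejected with diagnostics.
#'
#' @param path File path.
#' @return List with `configurations` (`n x L x 3`) and `subjects`
#'   (character IDs, from a leading `subject` column if present).
#' @export
read_landmarks <- function(path) {
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  assert_that(file.size(path) > 0, sprintf("empty landmark file: %s", path))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- tryCatch(read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                            colClasses = NA, fill = FALSE),
                 error = function(e) abort(sprintf("malformed landmark file %s: %s",
                                                   path, conditionMessage(e))))
  assert_that(nrow(df) > 0, sprintf("no data rows in %s", path))
  subjects <- NULL
  if (names(df)[1] %in% c("subject", "id")) {
    subjects <- as.character(df[[1]])
    df <- df[, -1, drop = FALSE]
  }
  p <- ncol(df)
  assert_that(p %% 3 == 0,
              sprintf("%s has %d coordinate columns, not divisible by 3", path, p))
  num_ok <- vapply(df, is.numeric, logical(1))
  assert_that(all(num_ok),
              sprintf("non-numeric coordinate columns in %s: %s", path,
                      paste(which(!num_ok), collapse = ", ")))
  M <- as.matrix(df)
  if (anyNA(M)) {
    bad <- which(is.na(M), arr.ind = TRUE)[1, ]
    abort(sprintf("NaN/NA coordinate in %s at row %d, column %d", path, bad[1], bad[2]))
  }
  if (is.null(subjects)) subjects <- sprintf("s%04d", seq_len(nrow(M)))
  list(configurations = unflatten_configs(M), subjects = subjects)
}

#' Write a wide landmark table
#'
#' @param configurations `n x L x 3` array.
#' @param path Output path (TSV).
#' @param subjects Optional subject IDs (written as first column).
#' @export
write_landmarks <- function(configurations, path, subjects = NULL) {
  flat <- flatten_configs(configurations)
  L <- ncol(flat) / 3
  colnames(flat) <- paste0(rep(c("x", "y", "z"), L), rep(seq_len(L), each = 3))
  df <- as.data.frame(flat)
  if (!is.null(subjects)) df <- cbind(subject = subjects, df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read genotype dosages from VCF or a plain matrix
#'
#' VCF mode uses the `DS` (dosage) FORMAT field when present, otherwise maps
#' diploid GT calls 0/0, 0/1, 1/1 to 0, 1, 2. Multi-allelic records are
#' rejected. Matrix mode expects a TSV with a `subject` column and one
#' column per SNP. Sample IDs must resolve against the supplied covariate
#' subject list when given.
#'
#' @param path File path.
#' @param mode `"vcf"` or `"matrix"`.
#' @param subjects Optional character vector of expected subject IDs.
#' @return List with `genotypes` (`n x S` matrix, rownames = subject) and
#'   `snp_meta` (tibble: id, location, alleles, maf).
#' @export
read_genotypes <- function(path, mode = c("vcf", "matrix"), subjects = NULL) {
  mode <- match.arg(mode)
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  if (mode == "matrix") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
    assert_that(names(df)[1] == "subject", "dosage matrix needs a leading subject column")
    ids <- as.character(df$subject)
    G <- as.matrix(df[, -1, drop = FALSE])
    rownames(G) <- ids
    meta <- tibble::tibble(id = colnames(G), location = NA_character_,
                           alleles = NA_character_,
                           maf = pmin(colMeans(G) / 2, 1 - colMeans(G) / 2))
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT)
    assert_that(!any(multi),
                paste("multi-allelic records not supported:",
                      paste(fix$ID[multi], collapse = ", ")))
    ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                   error = function(e) NULL)
    if (!is.null(ds) && !all(is.na(ds))) {
      G <- t(ds)
    } else {
      gt <- vcfR::extract.gt(v, element = "GT")
      code <- function(g) {
        g <- gsub("\\|", "/", g)
        out <- rep(NA_real_, length(g))
        out[g == "0/0"] <- 0; out[g %in% c("0/1", "1/0")] <- 1; out[g == "1/1"] <- 2
        out
      }
      Gt <- t(gt)  # subjects x SNPs
      G <- matrix(code(as.vector(Gt)), nrow = nrow(Gt), dimnames = dimnames(Gt))
    }
    assert_that(!anyNA(G), "missing or unparseable genotype calls")
    colnames(G) <- fix$ID
    meta <- tibble::tibble(id = fix$ID,
                           location = paste0(fix$CHROM, ":", fix$POS),
                           alleles = paste0(fix$REF, ">", fix$ALT),
                           maf = pmin(colMeans(G) / 2, 1 - colMeans(G) / 2))
  }
  if (!is.null(subjects)) {
    missing <- setdiff(subjects, rownames(G))
    assert_that(length(missing) == 0,
                paste("sample IDs missing from genotype file:",
                      paste(missing, collapse = ", ")))
    G <- G[subjects, , drop = FALSE]
  }
  list(genotypes = G, snp_meta = meta)
}

#' Write a minimal VCF 4.2 with GT and DS fields
#'
#' @param genotypes `n x S` dosage matrix, rownames = subject IDs.
#' @param snp_meta Tibble with `id`, `location` (`chrom:pos`), `alleles`
#'   (`REF>ALT`).
#' @param path Output path (plain text).
#' @export
write_vcf_minimal <- function(genotypes, snp_meta, path) {
  ids <- rownames(genotypes)
  assert_that(!is.null(ids), "genotype matrix needs subject rownames")
  loc <- strsplit(ifelse(is.na(snp_meta$location), "1:1", snp_meta$location), ":")
  al <- strsplit(ifelse(is.na(snp_meta$alleles), "G>A", snp_meta$alleles), ">")
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
                   "FORMAT", ids), collapse = "\t"))
  gt_of <- function(d) ifelse(d < 0.5, "0/0", ifelse(d < 1.5, "0/1", "1/1"))
  rows <- vapply(seq_len(nrow(snp_meta)), function(s) {
    d <- genotypes[, s]
    cells <- paste0(gt_of(d), ":", format(d, trim = TRUE, digits = 6))
    paste(c(loc[[s]][1], loc[[s]][2], snp_meta$id[s], al[[s]][1], al[[s]][2],
            ".", "PASS", ".", "GT:DS", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Drop SNPs below a minor-allele-frequency threshold in any cohort
#'
#' A SNP whose folded allele frequency falls below the threshold in *one or
#' more* cohorts is removed from every cohort; the report names each
#' exclusion with the offending cohort(s) and frequency.
#'
#' @param cohorts Named list of `cohort_dataset` objects (or a single one).
#' @param threshold MAF threshold in (0, 0.5); default 0.05.
#' @return List with `cohorts` (filtered) and `excluded` (tibble: id,
#'   cohort, maf).
#' @export
maf_filter <- function(cohorts, threshold = 0.05) {
  assert_that(threshold > 0 && threshold < 0.5, "threshold must lie in (0, 0.5)")
  single <- inherits(cohorts, "cohort_dataset")
  if (single) cohorts <- list(cohort = cohorts)
  freq <- lapply(cohorts, function(co)
    pmin(colMeans(co$genotypes) / 2, 1 - colMeans(co$genotypes) / 2))
  ids <- colnames(cohorts[[1]]$genotypes)
  excl <- dplyr::bind_rows(lapply(names(cohorts), function(cn) {
    f <- freq[[cn]]
    tibble::tibble(id = ids[f < threshold], cohort = cn, maf = f[f < threshold])
  }))
  drop_ids <- unique(excl$id)
  keep <- setdiff(ids, drop_ids)
  cohorts <- lapply(cohorts, function(co) {
    co$genotypes <- co$genotypes[, keep, drop = FALSE]
    co$snp_meta <- co$snp_meta[co$snp_meta$id %in% keep, ]
    co
  })
  list(cohorts = if (single) cohorts[[1]] else cohorts, excluded = excl)
}

#' Serialize / read a module tree as TSV
#'
#' Columns: `module_id`, `level`, `parent_id`, `landmarks` (comma-joined).
#'
#' @param tree A `module_tree`.
#' @param path File path.
#' @return `write_module_tree`: the path, invisibly. `read_module_tree`: a
#'   `module_tree` tibble.
#' @export
write_module_tree <- function(tree, path) {
  df <- data.frame(module_id = tree$module_id, level = tree$level,
                   parent_id = tree$parent_id,
                   landmarks = vapply(tree$landmarks, paste, character(1), collapse = ","))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_module_tree
#' @export
read_module_tree <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  mods <- lapply(seq_len(nrow(df)), function(i)
    list(id = df$module_id[i], level = df$level[i],
         parent = if (is.na(df$parent_id[i])) NA_integer_ else as.integer(df$parent_id[i]),
         lmk = as.integer(strsplit(df$landmarks[i], ",")[[1]])))
  new_module_tree(mods)
}

#' Write covariates as TSV
#' @param covariates Covariate tibble.
#' @param path File path.
#' @export
write_covariates <- function(covariates, path) {
  write.table(covariates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a dosage matrix as TSV (subject column + one column per SNP)
#' @param genotypes `n x S` matrix with subject rownames.
#' @param path File path.
#' @export
write_dosage_matrix <- function(genotypes, path) {
  df <- data.frame(subject = rownames(genotypes), genotypes, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort to disk
#'
#' Landmarks as a wide TSV, genotypes as minimal VCF (plus a dosage TSV),
#' covariates as TSV, and a JSON manifest recording the cohort id and seed
#' information.
#'
#' @param cohort A `cohort_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landmarks(cohort$configurations, file.path(dir, "landmarks.tsv"),
                  subjects = cohort$covariates$subject)
  write_covariates(cohort$covariates, file.path(dir, "covariates.tsv"))
  write_dosage_matrix(cohort$genotypes, file.path(dir, "dosages.tsv"))
  write_vcf_minimal(cohort$genotypes, cohort$snp_meta, file.path(dir, "genotypes.vcf"))
  write.table(cohort$snp_meta, file.path(dir, "snp_meta.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(cohort_id = cohort$cohort_id,
                            n = nrow(cohort$covariates),
                            L = dim(cohort$configurations)[2],
                            n_snps = ncol(cohort$genotypes)),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
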