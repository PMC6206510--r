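# facemods

Candidate-SNP association testing for dense-landmark 3D facial shape, built
around a hierarchical, modular decomposition of the face.

## The problem

Facial shape is a high-dimensional, spatially structured phenotype. Testing a
candidate variant against "the face" as a whole dilutes localized effects
(a SNP that reshapes the mandible barely moves a whole-face statistic), while
testing individual landmarks ignores the strong spatial correlation between
neighbouring points and multiplies the testing burden. `facemods` implements
the middle road: the facial surface is segmented into a hierarchy of
**facial modules** — nested groups of landmarks that co-vary strongly — and
each module becomes one multivariate shape phenotype tested against each SNP.

The pipeline, end to end:

1. **Symmetrization** — each configuration is averaged with its reflected,
   relabelled mirror image, removing asymmetry.
2. **Generalized Procrustes analysis (GPA)** — translation, orientation and
   scale are removed; centroid size is retained as the "facial size"
   covariate. Subjects unusually far from the mean face (Mahalanobis
   z-score > 2 in the shape PC space) are flagged for review.
3. **Covariate adjustment** — partial least-squares regression removes age,
   age², sex, weight, height, facial size and four ancestry axes from both
   the shape coordinates and the SNP dosages, separately per cohort.
4. **Segmentation** — Escoufier's RV coefficient between every pair of
   landmark blocks builds an L×L structural similarity matrix
   `RV(i,j) = tr(S_ij S_ji) / sqrt(tr(S_ii²) tr(S_jj²))`; recursive spectral
   bisection (sign of the Fiedler vector of the normalized graph Laplacian)
   of that matrix produces a strictly bifurcating tree — 63 modules at
   depth 5.
5. **Module phenotypes** — each module is aligned with its own GPA, reduced
   by PCA, and truncated by Horn-style parallel analysis (observed
   eigenvalues vs. the 95th percentile of column-permuted null eigenvalues).
6. **Association** — for a single SNP, canonical correlation analysis
   against the module PC scores reduces exactly to multiple regression: the
   canonical correlation CC is the multiple correlation, and Rao's F
   approximation to Wilks' Λ = 1 − CC² is the exact overall-regression F
   with (k, n−k−1) degrees of freedom (right-tailed).
7. **Round-robin replication and meta-analysis** — each cohort serves once
   as discovery; the other two cohorts' module shapes are mapped into the
   discovery Procrustes/PCA frame and projected onto the discovery canonical
   loadings, giving each replication subject a univariate **genetic effect
   score** that is regressed on dosage with a one-sided t test. The three
   p-values combine by Stouffer's method, `Z = Σ zᵢ / √3`, `zᵢ = Φ⁻¹(1−pᵢ)`.
8. **Multiple testing** — Bonferroni over Li–Ji effective test counts:
   `Meff = Σ [1(λᵢ ≥ 1) + (λᵢ − ⌊λᵢ⌋)]` over eigenvalues of the module and
   SNP correlation matrices, times the three meta-analysis rotations
   (e.g. 0.05/(37·30·3) = 1.5e−05).
9. **Facial ratios** — five width-to-height-style ratios computed from named
   landmarks are tested per SNP with ordinary linear models (two-sided),
   cut off at alpha divided by the SNP panel size (0.05/42 = 0.00119).

Because the cohort data such an analysis needs are access-controlled in
practice, the package ships a first-class **synthetic cohort generator**:
three unequal cohorts, Hardy–Weinberg genotypes at stated MAFs, covariate
effects acting through smooth displacement fields, spatially correlated
residuals, and SNP effects planted as spatially coherent deformations
confined to a chosen module of a symmetric template face. Every stage of the
pipeline is exercised and tested against that generator.

## Worked example

A desk-scale run: three cohorts (300/200/400 subjects, 64 landmarks), ten
SNPs of which one (`rs_planted`, MAF 0.2) deforms the mandibular module by
0.6 mm per allele at its peak:

```r
library(facemods)

cfg <- list(
  simulation = list(
    n_subjects = c(300, 200, 400), L = 64, tree_depth = 3,
    snp_specs = data.frame(id = c("rs_planted", paste0("null", 1:9)),
                           maf = c(0.2, rep(0.3, 9)),
                           beta = c(0.6, rep(0, 9)),
                           target_module = c(4L, rep(NA, 9))),
    seed = 5),
  depth = 3, pa_iter = 50, seed = 5)

res <- run_pipeline(cfg)
report(res, top = 3)
```

```
[facemods] simulated 3 cohorts (n = 300/200/400, L = 64)
[facemods] cohort cohortA: aligned 300 subjects (7 QC flags), adjusted shapes + dosages
[facemods] segmented 64 landmarks into 15 modules (depth 3)
[facemods] phenotyped 15 modules x 3 cohorts
[facemods] meta-analysis: 450 SNP x module x rotation tests, threshold 0.000185
Study-wide threshold: 0.000185 (Meff modules 9 x Meff SNPs 10 x 3 rotations)
Ratio-arm threshold:  0.005
# A tibble: 3 × 11
  snp     module_id rotation    cc     k p_discovery   p_rep1   p_rep2    p_meta
  <chr>       <int> <chr>    <dbl> <int>       <dbl>    <dbl>    <dbl>     <dbl>
1 rs_pla…         3 cohortA  0.817     8    3.99e-65 6.63e-37 4.55e-76 9.62e-170
2 rs_pla…         6 cohortC  0.756     6    3.24e-69 4.88e-57 1.16e-32 7.93e-151
3 rs_pla…         3 cohortC  0.736     8    1.15e-61 1.47e-62 2.67e-33 4.53e-150
```

Reading the output: every row is one (SNP, module, discovery rotation)
test. `cc` is the canonical correlation in the discovery cohort, `k` the
number of module PCs retained by parallel analysis, `p_discovery` the Rao-F
p-value, `p_rep1`/`p_rep2` the one-sided replication p-values of the
projected genetic effect score, and `p_meta` their Stouffer combination. The
planted SNP dominates; all of its meta p-values fall far below the Li–Ji
Bonferroni threshold of 1.85e−04 echoed in the header, while the nine null
SNPs reject at roughly the nominal rate. (The data-driven modules here are
segmented from the simulated shapes, so their numbering need not match the
generator's template tree.)

`tidy(res)` returns the full results tibble, `glance(res)` a one-row
summary, `autoplot(res$tree, res$template)` the module map, and
`autoplot(res$meta, threshold = res$threshold)` the per-module evidence
plot.

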