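---
title: "Modular facial-shape association: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modular facial-shape association: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its statistical machinery: the
models each stage assumes, the parameters that matter and why their defaults
are what they are, what the synthetic-data generator does and does not
emulate, and the places where the design was genuinely open and a choice had
to be made.

## Shape preprocessing

**Symmetrization.** A configuration $X \in \mathbb{R}^{L\times 3}$ is
averaged with its reflected, relabelled mirror image:
$\mathrm{sym}(X) = \tfrac12 (X + P\,\mathrm{refl}_x(X))$, where $P$ is the
permutation induced by the mirror-pairing map. The output is an exact fixed
point of reflect-and-relabel, and midline landmarks land exactly on $x=0$
(asserted exactly, not to a tolerance, in the tests). Working on symmetrized
shapes halves the effective residual variance and restricts attention to
symmetric variation, which is the component a bilateral anatomical effect
lives in.

**Generalized Procrustes analysis.** Each configuration is centered, scaled
to unit centroid size, and rotated onto the running consensus by
rotation-only orthogonal Procrustes; the consensus is the re-normalized mean
of the rotated set. Numerical choices:

* rotations come from the SVD $M = U\Sigma V^\top$ of the cross-product
  matrix with a determinant correction (last column of $U$ flipped when
  $\det(UV^\top)<0$), so reflections can never enter;
* the initial consensus is the mean of the centered, scaled inputs, which
  makes the fit invariant to subject order;
* after convergence the whole solution is rotated into a canonical frame —
  principal axes of the consensus, each axis signed so its
  largest-magnitude coordinate is positive, determinant forced to $+1$.
  This removes the global rotational gauge freedom, so a common rotation of
  all inputs leaves the output unchanged (to $10^{-8}$);
* convergence is declared when the consensus moves less than `tol`
  ($10^{-9}$ in Frobenius norm by default; two-shape problems approach
  their fixed point slowly, which is why the default is not tighter) and
  capped at 200 iterations, after which the fit aborts with the residual
  rather than returning silently.

"Facial size" in the covariate block is the centroid size of the raw
configuration before scaling — the standard geometric-morphometrics size
measure.

**Outlier QC.** Mahalanobis distance from the mean face is computed in the
PC subspace holding 98% of the aligned shape variance, because the
full-space covariance is singular whenever $3L > n$. Distances are
standardized over subjects and flagged at $z > 2$ by default. Flagging is
deliberately report-only: in real studies such faces are inspected, not
deleted, so automatic removal is an opt-in (`qc_strict`).

## Covariate adjustment

Shapes and dosages are both residualized on age, age², sex, weight, height,
facial size and four ancestry axes with partial least-squares regression,
separately per cohort (cohort-local adjustment is asserted to differ from
pooled adjustment in the tests). The PLS implementation extracts components
from the SVD of the cross-covariance $X_d^\top Y$ with $X$-deflation. Two
open choices were resolved as follows:

* **Number of components.** Default: the rank of the standardized covariate
  block. At full rank the PLS fit spans the covariate column space, so the
  residuals coincide with ordinary least-squares residuals (verified to
  $10^{-6}$ against `lm.fit`, and cross-checked against an independent PLS
  implementation). This is the maximal, reproducible adjustment; a smaller
  count remains available for under-determined settings.
* **Genotype correction.** The same operation with a one-column response.
  Maximal removal keeps the association test's both sides orthogonal to the
  covariates.

The intercept is handled by centering; residual columns therefore have mean
zero. Constant covariate columns (sex in a single-sex subgroup analysis)
are dropped from the block rather than causing a failure, since they carry
nothing to remove.

## Segmentation

The structural similarity between landmarks $i$ and $j$ is Escoufier's RV
coefficient between their $n\times 3$ coordinate blocks. The whole
$L \times L$ matrix is computed from one $(3L)^2$ cross-product; entries are
clamped into $[0,1]$ against floating drift. RV is invariant to rotation of
either block, which matters because aligned coordinate blocks carry an
arbitrary orientation.

Bisection uses the sign of the Fiedler vector of the symmetric normalized
Laplacian $I - D^{-1/2} S D^{-1/2}$, mapped back through $D^{-1/2}$
(the random-walk embedding). Deterministic conventions:

* eigenvector sign is fixed so the first index loads non-negatively;
* exact zeros join the smaller side;
* a numerically constant Fiedler vector falls back to connected components;
* an optional `min_size` rebalances a split by moving the indices with the
  smallest $|$Fiedler$|$ loadings — those least committed to either side —
  so that both children stay viable.

Recursion to depth 5 gives the strictly bifurcating 63-module hierarchy
(heap-numbered: children of module $i$ are $2i$ and $2i+1$). `min_leaf`
defaults to 1 (any non-empty module is a valid cluster); the pipeline uses
`min_leaf = 3`, the smallest landmark set a per-module Procrustes fit can
align, so that every module of the tree can be phenotyped. Whether spatial
contiguity should additionally constrain the graph is genuinely open; a
k-nearest-neighbour adjacency mask on the template (default off) implements
it, and both modes are tested.

Segmentation runs on the covariate-adjusted shapes of all cohorts pooled,
so all cohorts share one module definition.

## Module phenotypes

Each module is re-aligned from the symmetrized, adjusted module landmarks
with its own GPA — a module's shape space is its own, not a slice of the
full-face alignment. PCA is the eigendecomposition of the flattened,
centered coordinates (via the smaller Gram side); component signs follow the
largest-|loading|-positive convention.

Dimension selection is Horn-style parallel analysis: observed eigenvalues
are compared rank by rank with the 95th percentile of eigenvalues from
matrices whose columns are independently permuted — a distribution-free null
that keeps column variances and destroys correlation. Retention stops at the
first failing rank and never drops below one component. Settings: 200
permutations by default (50 in the heavy simulation studies; the retention
decision is empirically stable from a few dozen iterations), and a
subject-subsample cap (`pa_max_n = 500`) because the null eigenvalue
percentiles stabilize well below typical cohort sizes while their cost grows
linearly with $n$. The permutation loop runs compiled, drawing from R's RNG
so results stay reproducible under `set.seed`.

## Association and meta-analysis

**Single-SNP CCA.** With one genetic variable the canonical correlation
problem collapses: CC is the multiple correlation of dosage on the retained
module PCs, the canonical loadings are the normalized regression direction,
and Rao's F approximation to Wilks' $\Lambda = 1-\mathrm{CC}^2$ is the exact
overall-regression F with $(k, n-k-1)$ degrees of freedom (all standard
variants of the approximation coincide at $q=1$). The implementation runs on
a QR factorization of the centered score matrix, reused across the SNPs of a
scan; a unit test and the acceptance suite verify agreement with the `lm`
F-test to $10^{-10}$.

**Cross-cohort projection.** The replication cohorts must measure the trait
the discovery cohort found. The discovery module frame — consensus, center,
PC loadings — is applied to replication module shapes: align each
configuration to the discovery consensus (center, unit-scale, rotate),
project onto the discovery PC basis, then onto the canonical loadings. How
exactly replication shapes should be expressed in the discovery basis is not
fully determined by the method's description; this explicit
align-then-project construction is the package's resolution, and it
reproduces the discovery canonical variate exactly when applied to the
discovery cohort itself (tested).

**Orientation.** The discovery canonical variate is oriented so it
correlates positively with dosage (automatic for a regression direction),
which fixes the sense of the one-sided replication t-test: concordant
replication gives small p, discordant p near 1, and a sign-flipped score
gives exactly $1-p$.

**Stouffer combination.** All three p-values — the discovery F p converted
via $z = \Phi^{-1}(1-p)$ and the two replication p's — combine unweighted by
default ($\sqrt n$ weights are available by configuration). Conversion uses
the upper-tail quantile directly, which is exact for arbitrarily small p;
inputs are clamped at $10^{-300}$ first. The meta table also carries the
Stouffer $Z$, which remains informative where $p_{meta}$ underflows double
precision.

**Effective test counts.** The modules are nested and therefore correlated,
and so may be the SNP panel; Bonferroni over Li–Ji effective counts softens
the correction accordingly. Which statistic enters the Li–Ji correlation
matrix is unstated in most descriptions of the approach; the package exposes
both matrices it uses — correlations of the modules' first PC scores in a
reference cohort, and pooled dosage correlations — and rounds the resulting
$M_{eff}$ to an integer for threshold computation while returning the raw
sum. The eigenvalue floor is guarded at $10^{-9}$ so that integer
eigenvalues (a rank-one correlation block) do not pick up a spurious
fractional part.

## The synthetic-data generator

The generator is the package's study stand-in, not a fixture: three cohorts
of unequal size (defaults 2297/1555/3566, scalable), covariates from
documented distributions (age $\sim U(3,40)$ yr, sex Bernoulli(½),
sex-shifted normal height/weight, standard-normal ancestry axes),
Hardy–Weinberg genotypes at stated MAFs (hard calls, or imputation-style
dosages), and configurations built from a deterministic, exactly
mirror-symmetric template face (half-ellipsoid, 65×90×50 mm semi-axes, six
midline landmarks and mirror pairs, named anatomical points). Shape
structure:

* covariate and ancestry effects act through smooth, seed-fixed random
  displacement fields (distance-kernel smoothed, unit RMS), scaled by
  mm-per-SD coefficients (defaults: age 0.8, age² 0.3, sex 1.2,
  height/weight 0.3, ancestry 0.1 mm); allometry is a log-normal centroid
  size factor (SD 0.04) partially tied to height;
* the residual field has marginal SD `noise_sd` (1 mm) and a squared-
  exponential spatial correlation with 30 mm range — this is what gives the
  segmentation non-trivial structure to find;
* planted SNP effects are confined to a target module of the template's
  geometric tree. The displacement field is a radial Gaussian bump (kernel
  SD twice the module RMS radius) given *opposite sign on the module's two
  children*, with the module's similarity components — translation, scale,
  rotations — projected out, then normalized to peak displacement 1 so
  `beta` is mm per allele. Two failure modes of naive bumps motivated
  this: a spatially uniform push is mostly a rigid translation of the
  module, which the per-module Procrustes fit absorbs (the effect then
  surfaces in the parent instead); a narrow peak hands most of its energy
  to a single descendant. The child-contrast field is the same smooth,
  module-confined deformation, but the module itself is structurally its
  natural detection unit;
* each configuration finally receives a random rigid motion (rotations up
  to ±0.2 rad, 10 mm translations) so superimposition is exercised, and
  every cohort draws from its own sub-seed.

What the generator does **not** emulate: raw surface meshes and
registration error, missing landmarks, genotyping/imputation error and LD
between SNPs, relatedness, cohort-specific camera systems, or asymmetric
genetic effects. Passing tests therefore demonstrate the statistical
machinery under the model's own assumptions — multivariate-normal residuals
with stationary spatial correlation and additive, symmetric, module-local
genetic effects — not robustness to the full messiness of real imaging
genetics data.

## Study conditions used by the test and acceptance suites

Simulation sizes in the suites were chosen as the smallest configurations
that exercise each property cleanly: the null-calibration study uses
cohorts of 300/200/400 subjects, 64 landmarks, a depth-4 tree and 120 null
SNPs (11 160 meta tests); the recovery study uses 50 replicates at cohorts
of 1000/700/1300, 96 landmarks, depth 5 (63 modules), one SNP of MAF 0.2
with a 0.5 mm-per-allele peak effect (0.5 residual SD) on the level-2
mandibular module — the module of the template tree containing gnathion.
Parallel analysis runs at 50 permutations in these studies.

## Known limitations

* The two-stage ratio adjustment (residualize, then regress on dosage with
  ancestry axes) is not identical to the one-stage joint model; the tests
  assert rank-order agreement on simulations, not equality.
* Li–Ji effective counts depend on the summary entering the correlation
  matrix; first-PC module summaries understate dependence between modules
  whose association lives in later PCs.
* The cross-cohort projection assumes the discovery PC basis is meaningful
  in the replication cohorts; with very small modules and very small
  cohorts the basis itself is noisy, and replication power degrades
  accordingly.
* Mean-imputation of missing dosages, PLINK-format input, genotype
  imputation and mesh-level processing are out of scope by design.
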