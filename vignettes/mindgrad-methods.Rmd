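---
title: "Morphometric similarity gradients: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity gradients: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindgrad)
```

This vignette documents the statistical models implemented in `mindgrad`,
the assumptions behind them, the tunable parameters with their defaults,
and the design decisions taken where several defensible choices existed.

## 1. MIND similarity networks

A subject's cortex is represented as a set of regions, each holding a
sample of vertices with five morphometric features (CT, GM, SA, MC, SD).
The features are z-scored across **all** vertices of the subject — not per
region — using the population SD (`ddof = 0`); per-region scaling would
erase exactly the between-region differences the method quantifies. The
population-SD convention is stated explicitly because with it a two-vertex
feature `(1, 3)` standardizes to `(−1, +1)`.

Similarity between two regions is an inverse transform of the symmetrized
Kullback–Leibler divergence between their feature distributions,

$$\mathrm{MIND}(A,B) = \frac{1}{1 + \hat D(A\Vert B) + \hat D(B\Vert A)} \in (0, 1],$$

with each divergence estimated nonparametrically from k-nearest-neighbour
distances:
$\hat D(A\Vert B) = \tfrac{d}{n_a}\sum_i \log(\nu_k(i)/\rho_k(i)) +
\log\!\big(n_b/(n_a-1)\big)$,
where $\rho_k$ is the k-NN distance of a point of $A$ within $A$ (self
excluded) and $\nu_k$ its k-NN distance into $B$.

Numerical choices:

* **k = 1** by default (the reference MIND formulation); configurable.
* **Negative estimates are clipped at 0** before symmetrization. The
  estimator is asymptotically unbiased but can dip slightly negative at
  finite n; clipping keeps MIND ≤ 1.
* **Duplicate points**: nearest-neighbour distances are floored at
  1e-12 inside the compiled kernel, keeping the logarithms finite without
  perturbing the data or consuming random numbers. (An alternative is to
  jitter all coordinates; the floor has the same effect at data scale and
  is exactly deterministic.)
* The diagonal is zero by policy; self-similarity is excluded from the
  weighted degree, which is the mean off-diagonal entry of each row.

The whole matrix is computed by one compiled pass that reuses each
region's self-NN distances across all pairs and scans each region pair
once, updating both directions' neighbour minima simultaneously; the
exported per-pair functions (`kl_divergence_knn()`, `mind_similarity()`)
implement the identical estimator and the test suite checks the two routes
agree to machine precision.

Estimator accuracy is validated against closed-form Gaussian divergences
(1-D N(0,1)‖N(1,1), truth 0.5; 2-D N(0,I)‖N(0,4I), truth ≈ 0.636): at
n = 5000 the median absolute error stays below 0.1, and the error shrinks
monotonically with n.

## 2. Diffusion-map gradients

Per subject (and for the group mean matrix):

1. **Row thresholding**: keep the top `ceiling(fraction·(R−1))` entries of
   each row (default `fraction = 0.1`); ties at the cutoff go to the lower
   region index so the operation is deterministic. The result is
   deliberately left asymmetric.
2. **Normalized-angle affinity** between thresholded rows:
   $a_{ij} = 1 - \arccos(\cos(r_i, r_j))/\pi$, which maps nonnegative
   profiles into [0.5, 1]. The diagonal column of the thresholded matrix
   (zeros) enters the cosine as-is.
3. **Diffusion embedding** with density normalization
   $W_\alpha = D^{-\alpha} W D^{-\alpha}$, $\alpha = 0.5$ (balances the
   influence of sampling density), Markov operator
   $P = D_\alpha^{-1} W_\alpha$, eigendecomposition via the symmetric
   conjugate. The trivial constant eigenvector (eigenvalue 1) is dropped;
   component $i$ is $\lambda_i \psi_i$ (diffusion-time-0 scaling, the
   default of the standard gradient toolbox); variance explained is
   $\lambda_i / \sum_j \lambda_j$ over the retained nontrivial
   eigenvalues.

The **group template** embeds the element-wise mean MIND matrix across all
subjects, cases and controls pooled. (The alternative — averaging
individual embeddings — is not used; the mean-matrix route is the standard
toolbox behaviour.) Ten components are computed and aligned by default;
only gradient 1 is analysed downstream.

**Sign convention.** Eigenvectors are defined up to sign. The template is
oriented so that each component's mean over an anchor set — the
highest-degree decile of regions in the mean matrix — is positive;
individual embeddings inherit the orientation through Procrustes
alignment (orthogonal rotation after column centering, no scaling, with
the template's column means restored). This yields a reproducible
orientation without requiring reference data.

The embedding is validated against a dense eigensolver on a ring-graph
affinity (first gradient a sinusoid in node index; variance-explained
ratios equal to eigenvalue ratios within 1e-8) and Procrustes alignment
recovers a random orthogonal rotation of a template within 1e-6 in
Frobenius norm.

## 3. Group contrasts

Each region's principal-gradient score is regressed on
`[intercept, group, age, sex, education, age×sex]` with group coded
control = 0, case = 1 (positive t = case > control). Age and education are
mean-centered before forming the interaction so the main effects stay
interpretable. Two-sided p-values use the t distribution with n − 6 df;
BH-FDR is applied across the 308 (or R) regions, and separately across
the 7 labels when scores are averaged within network or cytoarchitectonic
class atlases. Distributional differences of subject-level mean scores use
the two-sample Kolmogorov–Smirnov test. (The covariate GLM is the primary
contrast; a simple two-sample t-test on the same scores is a degenerate
special case of the design.)

## 4. Spin-permutation nulls

Spatial correlations between parcellated maps are tested against spin
nulls: each spin draws a Haar-uniform rotation (QR of a Gaussian 3×3 with
sign correction, determinant +1), applies it to the left-hemisphere
centroids and its x-mirrored version to the right, and reassigns every
region to the nearest rotated centroid within its hemisphere, duplicates
permitted (the original formulation of the method; exact bijective
variants exist but are not used). Conventions fixed for reproducibility:

* the **first** map argument (the statistical map) is permuted, the
  annotation held fixed;
* tests are **two-sided by |r|**;
* $p = (1 + \#\{|r_\text{null}| \ge |r_\text{obs}|\})/(1 + n_\text{spins})$,
  so p is never exactly 0.

Because reassignment permits duplicates, the identity "spinning both maps
by the same spin leaves r unchanged" holds for the underlying rotation and
for bijective relabellings, but only in distribution for individual
snapped index maps. Similarly, at coarse parcellations (R ≤ 68) a small
rotation occasionally snaps back to the identity, so a map correlated with
itself can receive p slightly above the minimal $1/(n_\text{spins}+1)$;
at R = 308 this does not occur at practical ensemble sizes.

## 5. What the synthetic generator emulates

The generator provides every input of the pipeline with known truth:

* **Parcellation**: Fibonacci lattices of `R_per_hemisphere` centroids per
  hemisphere (default 154, i.e. a 308-region cortex), right hemisphere
  mirrored in x so spins can rotate in mirrored pairs; 7 network labels
  (latitude bands) and 7 class labels (longitude sectors), spatially
  contiguous; vertex counts uniform in [200, 500] per region (real ~5 cm²
  parcels contain a few hundred vertices, and hundreds of points keep the
  k-NN divergence estimate stable).
* **Cohorts**: each region has a fixed 5-D Gaussian whose mean vector and
  per-feature scales vary smoothly over the sphere (squared-exponential
  GP on chordal distance, length-scale 0.5), sharing one cross-feature
  correlation matrix; subjects add a global per-feature offset
  (SD 0.2 of the regional scale); cases shift all feature means in the
  effect regions by `effect_size` regional SDs. Covariates: age uniform
  21–50, sex Bernoulli(0.5) coded 0/1, education N(14, 2) truncated at 8.
  Because the region parameters are drawn on mirrored coordinates,
  homotopic region pairs share identical distributions; a perturbation
  planted in a region therefore expresses itself in the gradient partly
  through its homotopic twin, whose similarity profile it disrupts most —
  a useful reminder that gradient contrasts are network-level, not local,
  statistics.
* **Annotation maps**: GP draws with squared-exponential kernel
  (length-scale = `smoothness`, default 0.5 in chordal units), z-scored
  across regions. **All whole-brain GP draws use mirrored coordinates**
  (the right hemisphere reflected onto the left), so generated maps are
  bilaterally mirror-symmetric. This mirrors the strong homotopic
  correlation of real molecular and morphometric maps and is required for
  the mirrored-pair spin null to be exchangeable: a single GP over both
  hemispheres' interleaved positions has cross-hemisphere structure that
  spinning destroys, which we measured to inflate the spin test's type-I
  error to ≈0.18; with mirrored draws the measured rate is ≈0.05–0.06.
* **Expression**: a left-hemisphere regions × genes matrix in which a
  fraction of genes (default 0.3) track a target map with gene-specific
  signed coefficients plus noise (SD 0.5), the rest being smooth spatial
  noise; genes carry 7 synthetic class labels with loaded genes placed in
  designated classes with probability 0.8; z-scored per gene.
* **Gradient-level cohorts** (`simulate_gradient_cohort()`): subjects ×
  regions principal-gradient scores with a smooth base map, linear age and
  sex effects, i.i.d. subject noise, and a planted case shift. Power and
  calibration studies of the contrast stage use this generator because the
  quantity under test is defined on gradient scores; running the full
  vertex → MIND → gradient chain for hundreds of simulated cohorts would
  add nothing but cost to those specific questions.

What the generator does **not** emulate: cortical folding geometry,
scanner/site effects, heavy-tailed or skewed feature distributions,
hemispheric asymmetries, donor-sampling sparsity of real expression
atlases, and realistic gene–gene correlation beyond the shared spatial
mode. Passing tests therefore demonstrate the pipeline's statistical
machinery — estimator accuracy, calibration, planted-truth recovery,
determinism — not robustness to those real-data complications.

## 6. PLS decoding

SIMPLS with a univariate response: predictors are z-scored (population
SD), the response centered; components maximize covariance with the
response under orthonormal score constraints. Variance explained by
component $i$ is the incremental fraction of Var(y) captured by regressing
y on components 1..i. Every component is oriented so its score map
correlates nonnegatively with the response (applied before the bootstrap),
matching the convention of reporting a positively correlated PLS1 score
map. Defaults: 20 components for full-scale analyses, 10 in the small
synthetic studies (the response has only 34–154 regions there).

Component-1 significance spins the **response** and recomputes the
first component's variance explained (one-sided: larger = more structure).
Bootstrap weight Z-scores resample regions with replacement, refit,
sign-align each bootstrap component 1 to the original by the sign of the
weight correlation (the standard alignment in this literature, though
rarely stated), and divide the original weight by its bootstrap SD;
two-sided normal p-values are BH-FDR corrected and the retained predictors
split by weight sign into positive/negative sets. Resamples with fewer
distinct regions than components are rejected and redrawn (bounded
retries). An independent NIPALS implementation in the test helpers
cross-checks the one-component fit.

## 7. Enrichment and relative importance

**Null-ratio enrichment**: the observed statistic is the fraction of a
gene set falling in a class; the null redraws size-matched sets from the
background (default: all genes in the expression matrix, the PLS
background). Enrichment and depletion tails are both reported (with the
`+1` convention) and BH-FDR corrected across classes; the toy case is
validated against the exact hypergeometric tail.

**LMG relative importance**: the regression R² is decomposed into
per-predictor shares by averaging each predictor's sequential R² increment
over all orderings — computed exactly by enumerating all $2^p$ subsets
with the appropriate factorial weights (hence the p ≤ 10 guard; the
reference model has p = 4). Shares are reported raw (summing to R² within
1e-9) and as percentages (summing to 100). Fit significance spins the
response and recomputes the **unadjusted** R² (monotone in fit; the
adjusted version would subtract a constant at fixed p and n). Percentage
shares get percentile CIs from resampling regions (default 1,000
iterations).

## 8. Pipeline, problem sizes, and determinism

`pipeline_config()` fixes every parameter and derives one explicit seed
per stage from the master seed; `run_pipeline()` executes
simulate → mind → gradient → contrast → spatial → pls → enrich →
importance, writes headered delimited text with region-id columns for
join safety, and records an md5 hash of every output in a JSON manifest —
two runs from the same config are verifiably identical. Skipped stages are
listed as stale, and a stage whose upstream output is missing aborts with
the stage named.

The default synthetic study uses 68 regions, 12 + 12 subjects, 500 genes,
500 spins, and 500 bootstrap iterations — sizes chosen so a complete run
takes about half a minute on one CPU while every stage still operates far
from its small-sample edge cases. The test suite additionally runs the
contrast power study at the reference cohort size (49 cases / 119
controls) and the KL oracle at n = 5000, where the estimator's bias is
comfortably below the 0.1 tolerance.

## 9. Known limitations

* The within-region feature covariance model (Gaussian with a shared
  correlation structure) is a stand-in; real vertex features are not
  Gaussian and their covariance is not characterized by the reference
  analyses.
* The duplicates-permitted spin variant slightly deviates from exact
  exchangeability at coarse parcellations (see §4).
* SIMPLS component-1 dominance of incremental variance explained is an
  empirical property checked on all runs, not a theorem.
* Exact LMG is exponential in the number of predictors; beyond p = 10 a
  sampling approximation would be needed (not implemented).
* E/I ratio denominators near zero are flagged (`unstable`) rather than
  dropped; interpretation of flagged regions is left to the analyst.
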