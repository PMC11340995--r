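---
title: "Harmonizing structural connectomes across acquisition parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing structural connectomes across acquisition parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connharmony)
```

## The problem

Structural connectomes (SCs) — symmetric matrices of streamline counts
between parcellated gray-matter regions — are strongly shaped by two
diffusion-MRI acquisition parameters: the maximal b-value (s/mm²) and the
spatial resolution (mm, taken as the cube root of the voxel volume so that
anisotropic voxels get a scalar summary). Pooling SCs acquired under
different settings therefore mixes biology with scanner protocol. This
package models that acquisition bias per connection and removes it, so
that connectomes acquired at one setting can be mapped to another — for
unseen subjects, and even to settings never observed during training.

## The model

For connection $i$, the fiber count is modeled as a linear function of the
acquisition parameters with an interaction,

$$y_i = \beta_{0i} + \beta_{1i} X_r + \beta_{2i} X_b + \beta_{3i} X_r X_b + \varepsilon_i,$$

with $X_r$ the resolution, $X_b$ the b-value, and Gaussian, independent
errors. Each of the $n(n-1)/2$ connections gets its own coefficient vector
$[\beta_{0i},\dots,\beta_{3i}]^\top$, estimated by ordinary least squares
over all training observations. Three modeling choices matter:

* **No subject covariates.** Subject identity is deliberately absent, so
  the model can correct data from subjects it has never seen. With
  traveling subjects (each observed at every setting), subject baselines
  are orthogonal to the acquisition columns and are absorbed by the
  intercept.
* **Continuous covariates.** Because $X_r$ and $X_b$ are continuous, the
  model is generative: it can produce SCs at parameter values absent from
  training (interpolation works; far extrapolation is risky, see below).
* **Shared design.** The design matrix is common to all edges, so one QR
  factorization solves all mass-univariate fits at once. A design whose
  distinct settings give rank < 4 is an error, never a silent
  pseudo-inverse.

Correction of a connectome observed at $AP_1$ toward $AP_2$ adds the
fitted difference,

$$y_i^{AP_2} = y_i^{AP_1} + \hat\beta_{1i}\,\Delta X_r + \hat\beta_{2i}\,\Delta X_b + \hat\beta_{3i}\,\Delta(X_r X_b),$$

then rounds to the nearest integer and clamps negative values to zero, in
that order, because fiber counts are non-negative integers. Ties at .5 are
rounded away from zero; this is configurable in spirit (a continuous,
unrounded mode exists) but the integer default matches everyday
"round off" semantics, where round-half-to-even would silently differ.

Covariates enter in raw physical units. The prediction is invariant under
affine reparameterization of either covariate (the span of
$\{1, X_r, X_b, X_r X_b\}$ is preserved), which the test suite verifies
numerically; only the printed magnitudes of individual coefficients depend
on units.

## Graph metrics

Four weighted nodal metrics quantify how acquisition settings distort
network topology: strength, closeness centrality (integration), clustering
coefficient and local efficiency (segregation). They are implemented as
literally printed: clustering for node $i$ is
$\frac{1}{k_i(k_i-1)}\sum_{j \ne h}(w_{ij}w_{ih}w_{jh})^{1/3}$ over
ordered neighbor pairs, path lengths are reciprocal weights
$l_{ij} = 1/w_{ij}$, closeness divides the number of reachable nodes by
the summed shortest distances to them, and local efficiency replaces the
closing weight with the inverse shortest distance inside the subgraph
induced by the node's neighbors (excluding the node itself).

Numerical conventions: a zero count means *no edge* (length `Inf`), not a
zero-length edge; degree-< 2 nodes get clustering and local efficiency 0
(avoiding 0/0); unreachable neighbor pairs contribute 0 (the
$1/\infty$ limit); the ordered-pair summation matches the $k_i(k_i-1)$
normalizer so a unit-weight triangle scores exactly 1. Because weights are
raw counts, clustering values can exceed 1 and all three weight-bearing
metrics scale linearly under uniform weight rescaling — a documented
consequence of using the printed formulas. Some toolkits normalize weights
by the graph-wide maximum before the cube root; `normalize = TRUE`
reproduces that convention for cross-checking, but the literal formula is
the default and the one the tests pin to brute-force oracles.

## Acquisition-effect mapping

`edgewise_anova()` and `nodal_anova()` run a balanced two-way
fixed-effects ANOVA (b-value × resolution, with interaction) independently
per edge or per node over a 2 × 2 grid of settings, then Bonferroni-correct
within each factor by the number of units — $0.05/37{,}401$ for edges of a
274-region parcellation, $0.05/274$ for nodes. Conventions: significance
requires strictly $p < \alpha/m$; zero-variance units (absent connections)
are flagged degenerate with $F = 0$, $p = 1$; `-log10` of the corrected
p-value is reported for significance maps (base 10 chosen as the
neuroimaging convention; the significance decision is base-independent);
percentages print rounded to the nearest integer, or to two decimals below
1%. Subjects are treated as independent replicates within cells — the
plain two-way layout applied in the original analyses — not as a
repeated-measures factor; with traveling subjects this is conservative for
main effects (subject effects cancel from cell-mean contrasts but inflate
the within-cell variance). Unbalanced tables are rejected rather than
silently resolved, which also makes the Type-I/II/III distinction moot.

## Evaluation machinery

Harmonization quality is measured in fiber units as the mean absolute
connection difference (mean L1). From cross-scan distance matrices the
package computes **fingerprinting accuracy** (fraction of subjects whose
diagonal entry is the strict row minimum; ties count as failure, a
conservative choice that matters after integer rounding) and the
**differential identifiability** $I_{diff}$ = mean(off-diagonal) −
mean(diagonal). Row-wise matching is the default; a flag transposes it,
since the matching direction is a free choice. Distribution comparisons
use the two-sample Kolmogorov–Smirnov test (asymptotic p-values).
`pca_embed()` z-scores edges by training-set mean and SD (zero-variance
training edges are excluded rather than zero-filled, keeping the transform
linear), fits the PCA on the training set only, and projects both sets on
the first two components with signs fixed by the largest-magnitude
loading.

## The synthetic cohort generator

Real multi-setting cohorts at this scale are access-restricted, so
validation runs on simulated cohorts with known ground truth:

* a **group skeleton** (default 35% of edges present) with log-normal
  group-mean counts (median 50, sdlog 0.75) mimicking heavy-tailed fiber
  counts;
* **subject fingerprints**: Gaussian per-(subject, edge) offsets (SD 5
  fibers) constant across settings — the stable individual signal
  fingerprinting relies on;
* **acquisition effects** on 30% of skeleton edges: per-edge
  $\beta_1 \sim N(0, 10)$ fibers/mm, $\beta_2 \sim N(0, 0.01)$ fibers per
  s/mm², $\beta_3 \sim N(0, 0.002)$ for the interaction, applied relative
  to a reference setting (the higher-bval higher-res corner, 1.25 mm /
  3000 s/mm²). Across the default grid these produce cross-setting shifts
  of roughly 10–25 counts on affected edges — several times the noise —
  while the remaining edges stay null so false-positive control is
  testable in the same cohort;
* optional **quadratic b-value nonlinearity**
  $\gamma (X_b - X_{b0})^2$ on the affected edges
  ($\gamma = 2 \times 10^{-6}$ in the extrapolation preset: ~2 fibers at
  1000 s/mm² from the reference, ~50 at 5000), emulating the regime where
  linear harmonization to very high b-values fails;
* **observation**: Gaussian noise (SD 2 fibers) on skeleton edges, then
  the same round-half-away/clamp rule the corrector uses. A continuous
  pre-rounding mode exists solely for exact-recovery checks.

All draws derive from one seed in a documented order (skeleton, group
means, effect edges, effects, fingerprints, noise), so identical configs
give bit-identical cohorts. The generator emulates the *statistical*
structure the harmonization model assumes — additive linear effects,
shared skeleton, stable fingerprints — plus controlled violations; it does
not attempt tractography realism (SNR-dependent streamline counts, gyral
bias, distance-dependent density). Passing tests therefore demonstrate
correctness of the machinery and qualitative reproduction of the method's
behavior, not performance on real scanners.

The magnitudes above are choices, not calibrations: no quantitative
noise or effect sizes are available for the real cohorts, so defaults were
fixed once to give realistic orderings (acquisition shifts ≫ noise;
fingerprints detectable but not trivial) and all downstream checks run at
those fixed conditions.

## What the validation shows

The test suite (`tests/testthat/`) and `scripts/acceptance.R` recompute,
at fixed problem sizes chosen for desk-scale runs:

* **analytic combinatorics** — 274 regions give 37,401 possible
  connections;
* **oracle equivalence** — the four metrics against Floyd–Warshall +
  explicit-sum brute force on 100 random graphs (n ≤ 12) to 1e-10; ANOVA
  sums of squares against direct enumeration to 1e-10; KS statistics
  against the pooled-ECDF sup;
* **exact recovery** — on noiseless generative cohorts (10 traveling
  subjects), fitted coefficients equal truth to ~1e-13 and corrected
  low-quality scans reproduce the high-quality scans exactly after
  rounding;
* **error-control** — on 200 null cohorts (30 subjects, 210 edges) the
  per-factor family-wise error stays at the nominal 0.05 within binomial
  slack;
* **harmonization quality** — with 150 traveling training subjects and 30
  test subjects (60 regions, 20 replicate cohorts), the median
  within-subject error after correction falls below the between-subject
  distance; the error is non-increasing in training size over 20→600
  observations; and 600 single-setting subjects match 150 traveling
  subjects within 10%, so traveling subjects are not required;
* **identifiability** — correction raises fingerprinting accuracy and
  $I_{diff}$ (20 replicate cohorts), and a no-fingerprint negative control
  (subject SD 0) sits at chance accuracy;
* **extrapolation failure** — under the quadratic misspecification,
  harmonizing to b = 8000 s/mm² errs far more than to the in-hull
  b = 2000, in every replicate. Accordingly, `harmonize()` warns whenever
  the target lies outside the convex hull of the training settings but
  still proceeds, because near extrapolation is demonstrably useful.

## Known limitations

* Only linear (plus interaction) acquisition terms: no quadratic b-value
  term, no regularization or shrinkage across edges, no harmonization of
  covariance structure.
* No biological covariates (age, diagnosis) — deliberately, to keep the
  corrector applicable to unseen data.
* The per-edge ANOVA ignores within-subject correlation across settings;
  it reproduces the published analysis rather than improving on it.
* Cross-dataset transfer assumes label-identical parcellations; no
  cross-atlas region mapping is attempted.
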