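---
title: "Methods: salt-tolerance evaluation and mini-core selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: salt-tolerance evaluation and mini-core selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salttol)
```

# The problem

Screening a large germplasm panel for salt tolerance at the seedling stage
produces, for every genotype, a bundle of heterogeneous measurements:
growth rates under control and saline conditions, leaf senescence scores,
tissue water contents, and shoot/root Na⁺ and K⁺ concentrations. No single
trait ranks genotypes reliably — tolerance is polygenic and the traits
disagree — so the field's standard workflow is (i) reduce each trait to a
stress index, (ii) fuse the indices into one comprehensive score per
genotype by fuzzy membership functions, (iii) classify genotypes into
tolerance grades, (iv) fit a reduced regression model so future material
can be scored from a few cheap traits, and (v) distill the panel into a
small *mini-core collection* that preserves the panel's variability for
downstream genetics. `salttol` implements this workflow end to end for
panels of the *Miscanthus sacchariflorus* / *M. lutarioriparius* type,
with a seeded synthetic generator so every stage is testable without the
original raw data.

# Trait derivation

Growth is measured as time series: plant height at 2, 7 and 17 days after
starting the stress treatment (DAS), leaf counts at 1 and 17 DAS, and the
marked youngest leaf's length at 2, 7 and 12 DAS. The derived rates are

* GR (cm/day) = mean of (h₇ − h₂)/5 and (h₁₇ − h₂)/15,
* NIL (leaves) = leaves₁₇ − leaves₁,
* LER (cm/day) = mean of (L₇ − L₂)/5 and (L₁₂ − L₂)/10,

i.e. the denominators are the literal interval lengths between the stated
measurement days. For each growth trait the **salt tolerance index** STI =
stress/control and the **salt injury index** SII = 1 − STI. Replicates are
averaged within genotype × treatment *before* the ratio is taken
(ratio-of-means); this is robust to a single replicate with a zero control
value, and a genotype whose control mean is zero gets `NA` for that index
rather than an infinite ratio. Genotypes missing an entire treatment arm
are excluded with a warning and an exclusion report.

The 14-trait table holds RGR, RNIL, RLER (stress indices), the stress-arm
traits Sen (1–9 senescence scale), SWC, RWC (water contents, %), SNC, RNC,
SKC, RKC (ion concentrations, mg/g dry mass) and the four ratios SN/RN,
SK/RK, SK/N, RK/N, computed from the replicate-averaged base
concentrations so the ratio identities hold exactly row-wise.

**Water content.** The default formula is the fresh-mass basis
(fresh − dry)/fresh × 100. Published shoot water contents in this crop's
screening literature (means near 15%) are not consistent with that formula
for living tissue, and the underlying protocol is external; the basis is
therefore configurable (`basis = "dry"` gives (fresh − dry)/dry × 100) and
the fresh-mass default is documented as an assumption rather than a fact.

# Choosing the screening concentration

A pilot panel is exposed to a concentration ladder (0, 100, 150, 200,
250 mM NaCl in the canonical design). Per-genotype SII values are averaged
with equal genotype weights ([average_sii()]), and mean SII is regressed
on concentration by ordinary least squares. Solving the fitted line at
SII = 0.5 gives the concentration producing 50% injury for each growth
trait. `recommend_concentration()` then picks, among the levels actually
applied, the one minimizing the mean absolute distance to those
50%-injury concentrations, breaking ties toward the level with the
largest senescence-score variance — a level that spreads the senescence
response widest discriminates genotypes best. Whether the 0 mM control
point enters the regression is left to the caller: the fit uses exactly
the points supplied. Nonlinear (4PL) dose–response models are out of
scope; the linear fit is the method this pipeline codifies.

# Membership scoring and the D value

For trait *j* with observed minimum X_jmin and maximum X_jmax, the
membership of genotype *i* is

F_ij = (X_ij − X_jmin)/(X_jmax − X_jmin)

for positive-direction traits and 1 minus that for negative-direction
traits. The default direction map marks Sen, SNC, RNC, SN/RN, SKC and RKC
negative and the remaining eight positive. Including the K⁺
concentrations among the negative set follows the empirical observation
that K⁺ rises together with Na⁺ under stress in this material, even
though K⁺ retention is mechanistically protective; the map is a plain
user-overridable configuration (`directions.yaml`) precisely because this
assignment is a modeling choice. The comprehensive score is the plain
mean, D_i = (1/n) Σ_j F_ij, so D ∈ [0, 1] with higher D = more tolerant.

Numerical details: min/max are always taken over the table actually
supplied (not some fixed reference panel); a degenerate trait with zero
range is set to membership 0.5 everywhere with a warning (it carries no
ranking information and should not drag D toward either end); D is
invariant to increasing affine rescaling of any trait, and flipping one
trait's direction maps its column F → 1 − F and shifts each D by exactly
the column delta divided by the trait count — both properties are tested.

# Tolerance grades

Genotypes are clustered on their one-dimensional D values (Euclidean
distance, agglomerative clustering) and the tree is cut at height 0.12,
the grade resolution used for this crop. The linkage is unstated in the
source methodology; `complete` is the package default (a ubiquitous
default that bounds within-cluster diameter), with `single`, `average`
and `ward.D2` selectable, and the cut height is exposed because cluster
counts depend on both. Clusters are ranked by mean D and mapped to the
five grades HST, ST, MST, SS, HSS in descending order. When the cut
yields fewer than five clusters the grades are spread evenly across the
five-point scale (three clusters → HST/MST/HSS; one cluster → MST, with a
warning when all D are identical), which keeps the extreme grades
meaningful; more than five clusters are merged — closest mean-D pair
first — until five remain, preserving the five-level taxonomy.

# The predictive regression model

Measuring 14 traits is laborious; the workflow therefore fits D on a
seven-trait subset (SNC, RNIL, RWC, RGR, RKC, Sen, RNC) by ordinary least
squares, giving an affine scoring model Y = μ + Σ β_i X_i usable on new
material. `fit_tolerance_model()` offers two modes: `fixed_predictors`
(default, reproduces the published model structure exactly) and
`stepwise` forward selection, adding the candidate with the largest
partial F until none enters at p < 0.05 — the exact selection procedure
behind the published equation is unstated, so the entry rule is a
documented assumption and the fixed mode is the reproducible route.
Diagnostics include R², per-coefficient standard errors/t/p, and a
collinearity flag raised when the standardized design's condition number
exceeds 30. Predicted Y is reported both at full precision and rounded to
4 decimals, the precision of the published tables.

The package ships the published coefficient set
(`reference_tolerance_model()`: μ = 0.6895; SNC −0.0012; RNIL 0.1242;
RWC 0.0057; RGR 0.0516; RKC −0.0023; Sen −0.0202; RNC −0.0010) and the
15-genotype verification panel (`verification_panel()`); the test suite
and `scripts/acceptance.R` confirm that `predict_tolerance()` reproduces
every printed verification Y value to the 4-decimal rounding tolerance.

# Mini-core selection

Distances between genotypes are Gower's coefficient, which for
all-numeric interval traits reduces to the range-normalized Manhattan
distance d(i,k) = (1/m) Σ_j |x_ij − x_kj|/range_j ∈ [0, 1]; all 14 traits
enter with equal weight, and categorical traits are not supported. Two
objectives drive selection:

* **E-NE** (entry-to-nearest-entry): mean distance from each selected
  entry to its nearest other selected entry — maximized, spreading the
  core across trait space;
* **A-NE** (accession-to-nearest-entry): mean distance from every
  accession to its nearest core entry — minimized, making the core cover
  the collection.

The combined objective is 0.5·E-NE − 0.5·A-NE on the raw Gower scale.
Both objectives already live on [0, 1], so no internal renormalization is
applied (an optional min–max normalization against random-subset
baselines can be layered on by the caller); tooling in the Core Hunter
family normalizes internally, so objective *values* are not comparable
across implementations even when the selected cores agree.

The search is parallel tempering: `replicas` (default 4) chains at a
geometric temperature ladder (defaults 10⁻⁴ to 5·10⁻²), each proposing
swaps of one selected with one unselected genotype under Metropolis
acceptance, with adjacent-replica state exchanges every 50 sweeps.
Termination is after `patience` (default 5000) consecutive sweeps without
improving the best combined objective — a deterministic surrogate for a
wall-clock stopping rule, chosen so that identical seed and inputs give
bit-identical selections. The core size is round-half-up of
fraction × N (default fraction 0.20, so a 318-genotype panel yields 64).
`exhaustive_core()` enumerates all k-subsets on small instances and is
the search's independent oracle in the tests: on 20 seeded 10-genotype
instances with k = 3 the tempering search attains the exhaustive optimum
in at least 19.

# Core validation

Per trait, with CV = sd/mean:

* MD% = |mean_core − mean_entire|/mean_entire × 100 — should stay below 20;
* CR% = range_core/range_entire × 100 — should exceed 80 (a strict subset
  can never exceed 100);
* VR% = CV_core/CV_entire × 100;
* VD% = |CV_core − CV_entire|/CV_core × 100.

The VD definition deserves emphasis because the core-collection
literature uses several conventions: defined this way, VD =
(VR − 100)/VR × 100 whenever the core is the more variable set, and this
identity reproduces all 14 published (VR, VD) pairs for the reference
64-of-318 core to within rounding (e.g. VR 175.87 → VD 43.14), which is
how the package's definition was pinned down.

Diversity is the Shannon–Weaver index H = −Σ p ln p. The default class
scheme treats each distinct trait value as its own class, so H ≤ ln(n)
with equality for all-unique values; this is the only scheme consistent
with published entire-set values clustering just below ln 318 = 5.762 and
core values just below ln 64 = 4.159. A conventional equal-width
`fixed_bins` scheme is provided as the alternative. Ties are counted as
shared classes; the original computation's tie handling is unknown, which
is why the per-trait H values scatter slightly below the ln(n) ceiling.

Distribution agreement is tested three ways per trait: the Newman–Keuls
studentized-range procedure specialized to two groups (q = t√2 with the
pooled-variance t, so its p-value equals the pooled t-test's), the
Brown–Forsythe variant of Levene's test (one-way F on absolute deviations
from group medians), and the Wilcoxon rank-sum test (exact for both
samples ≤ 25, normal approximation with continuity correction otherwise).
Correlation preservation compares Pearson matrices (constant columns
masked) via the maximum absolute element-wise difference and the
off-diagonal sign-agreement fraction. PCA comparison standardizes within
each set and eigendecomposes the correlation matrix — invariant to affine
trait rescaling — ordering components by eigenvalue and orienting each
loading vector so its largest-magnitude entry is positive.

# The synthetic generator

`simulate_trait_table()` draws a Gaussian copula at a target correlation
matrix and maps each margin through a location-scale gamma quantile
transform matched to the trait's target mean, CV and skewness, truncating
to the trait's [min, max]. The transform is kept monotone increasing in
the underlying normal even for negative-skew margins, so the copula's
correlation signs survive. The default specification encodes the
descriptive statistics published for a 318-genotype panel (e.g. SNC mean
126.00 mg/g, CV 0.21; RGR mean 0.49, CV 0.53, skew +1.09) and only the
eight strong published correlations (SWC–RWC +0.73, Sen–SNC +0.66,
SN/RN–SNC +0.58, SN/RN–Sen +0.55, SN/RN–RK/N +0.53, Sen–SK/N −0.54,
Sen–RNIL −0.52, Sen–RLER −0.45), zeros elsewhere, repaired to the nearest
positive semi-definite matrix (`Matrix::nearPD`) with a warning. A
Gaussian copula with skew-matched gammas was chosen over a raw
multivariate normal because the published marginals are visibly skewed;
only the skew is matched, not kurtosis.

What the generator does *not* emulate: genotype replicate structure
within the trait table (it draws genotype-level values directly), any
genetic relatedness among genotypes, measurement error structure of the
ion assays, and the weaker unreported correlations. Tests passing on
synthetic panels therefore demonstrate the pipeline's arithmetic and its
statistical behavior under the stated moments and strong-correlation
structure — not that the original raw data would be reproduced.

`simulate_raw_trial()` plants known STI profiles into raw growth series
so `assemble_trait_table()` can be validated by exact recovery at zero
noise; `simulate_dose_response()` plants a known injury line; and
`simulate_clustered_panel()` plants separated cluster geometry in Gower
space for the core-selection tests. All generators are pure functions of
(spec, seed).

# Problem sizes and numerical choices

The test suite exercises panels of 10–300 genotypes: membership/D
properties on ten 20–50 row panels, parameter recovery on one 300-row
panel with σ = 0.01 observation noise on D, C50 recovery over 100 seeded
replicates at noise 0.02, oracle-equivalence on twenty 10-genotype
instances, and null calibration of the distribution tests over 400
replicates at the 300/64 sample-size pattern. These sizes give each
statistical check comfortable power while keeping the whole suite fast.
Tolerances: exact identities are asserted at 10⁻⁹–10⁻¹² relative;
published-value reproductions at the printed precision (4 decimals for Y,
±0.01 on the VD/VR identity); stochastic recoveries at 2–3 standard
errors with seeds pinned.

# Known limitations

* Only numeric interval traits are supported in Gower distances; mixed
  categorical germplasm descriptors are out of scope.
* The dose–response stage is strictly linear in concentration.
* The tempering schedule is this package's own design; it does not claim
  equivalence to any external core-selection tool's schedule, and
  objective values are only comparable within this package.
* The 50%-injury reference concentrations and the published per-trait
  core metrics depend on raw data not distributed with the original
  study; the package verifies its definitions against the published
  summary tables and planted-parameter simulations instead.
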