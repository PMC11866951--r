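---
title: "Methods: penalized maximum-entropy SDM and climate-change range analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized maximum-entropy SDM and climate-change range analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nichecast)
```

## The model

`nichecast` fits a presence/background species distribution model from the
maximum-entropy (Maxent) family. Given presence cells $x_1,\dots,x_{n_p}$ and
a background sample $B$ of landscape cells, the model is the Gibbs
distribution

$$ q_\lambda(x) \;=\; \frac{\exp\!\big(\sum_j \lambda_j f_j(x)\big)}{Z_\lambda},
\qquad Z_\lambda = \sum_{x \in B} \exp\!\Big(\sum_j \lambda_j f_j(x)\Big), $$

whose features $f_j$ are basis expansions of min–max normalized environmental
variables: linear (L), quadratic (Q), pairwise products (P), forward and
reverse hinges (H) and step thresholds (T), with hinge/threshold knots evenly
spaced strictly inside $(0,1)$. Coefficients minimize the L1-regularized
negative presence log-likelihood

$$ J(\lambda) = -\frac{1}{n_p}\sum_i \eta(x_i) + \log Z_\lambda
   + \sum_j \mathrm{RM}\,\beta_j s_j |\lambda_j|, $$

where $s_j$ is the feature's presence-sample standard deviation (floored at
$10^{-4}$ so features constant on presences stay penalized), $\beta_j$ a
per-class base penalty, and RM the regularization multiplier that scales all
penalties at once. The per-class base penalties follow the Maxent convention
in simplified form: linear/quadratic/product penalties interpolate against
the presence count through the anchors $(10, 1.0)$, $(30, 0.2)$,
$(100, 0.05)$ (clamped outside), hinge features use $0.5$ and thresholds
$1.0$. This is a deliberate, fixed rendering of the well-known
sample-size-dependent defaults, not a re-derivation of them.

Predictions come in three transforms. `raw` is the normalized Gibbs weight
$e^{\eta(x)}/Z$ (it sums to 1 over the training background). `cloglog`, the
default output of Maxent v3.4.4 and of this package, is
$1 - \exp(-e^{H} \cdot \mathrm{raw}(x))$ with $H$ the entropy of the fitted
background distribution; `logistic` is available behind a flag. Variables
outside their training range are clamped to it at prediction time;
extrapolation is instead surfaced explicitly by the MESS analysis below.
Which transform the source workflow used for its suitability maps is
ambiguous in the literature this package follows; cloglog is the v3.4.4
default and is therefore ours.

### Solver

The objective is convex. It is minimized by cyclic coordinate descent (in
compiled code): each coordinate takes a Newton step using the background
moments of its feature, soft-thresholded by its penalty, followed by an
*exact* backtracking line search on the true objective, so every accepted
update strictly decreases $J$ and the per-sweep objective trace is monotone —
a property the test suite asserts. Active-set sweeps (nonzero coefficients
only) alternate with full sweeps; convergence requires a *full* sweep to
improve by less than `tol` (default $10^{-7}$), with a cap of `max_iter`
(default 10,000) sweeps. Degenerate features (constant over presences plus
background) are dropped before fitting, and exact duplicate expansions
(e.g. Q of a binary layer) are deduplicated by hashing their expanded
columns. On small linear problems the solution matches a generic
derivative-free minimizer of the same objective to $10^{-4}$, and at the
optimum every feature satisfies the KKT box
$|E_q f_j - \bar f_j^{pres}| \le \mathrm{RM}\,\beta_j s_j$.

## Tuning by AICc

Candidate models cross RM $\in \{0.5, 1.0, \dots, 4.0\}$ with feature
classes $\{$L, LQ, H, LQH, LQHP, LQHPT$\}$ — 48 candidates. Every candidate
is fitted on the full presence set and scored by the small-sample corrected
AIC with the likelihood renormalized over *all* valid landscape cells (the
ENMeval / Warren–Seifert convention):

$$ \mathrm{AICc} = 2k - 2\ln L + \frac{2k(k+1)}{n-k-1}, $$

with $k$ the number of nonzero coefficients and $n$ the presence count;
AICc is undefined when $k \ge n-1$ and such candidates are excluded from
selection. The selected candidate minimizes AICc (its delta is 0 by
definition); exact ties go to the smaller RM, then the shorter feature-class
string — a parsimony rule that makes selection deterministic. Supporting
diagnostics per candidate come from repeated 75/25 train/test splits
(default 10 repeats): test AUC (Mann–Whitney pair counting, ties half),
the train−test AUC difference (mean and sd), and the 10% training omission
rate, whose threshold excludes the `ceiling(0.1 n)` lowest training scores
and counts test presences *strictly* below it.

Candidate discrimination depends on the information available to the
likelihood: with a landscape of only a few hundred cells or a background
sample much smaller than 1,000, AICc can prefer an over-flexible feature
class even when the generating density is exactly linear. The package's
default study condition (50×50 landscape, 1,000 background cells) recovers
the linear class in ≥ 8 of 10 seeded replicates.

## Variable screening

Collinearity screening works on values extracted at the occurrence cells
(configurable to landscape-wide; which of the two the upstream workflow used
is not documented, so both are provided). The Spearman matrix uses midranks
for ties; constant variables are flagged and their undefined correlations
set to 0. Selection is greedy: variables are visited in descending
importance (default: each variable's solo presence/background discrimination,
$\max(\mathrm{AUC}, 1-\mathrm{AUC})$) and retained only when below the
correlation threshold (default 0.7) against everything already retained.
Greedy retention is deterministic and auditable, but *not* monotone in the
threshold: a variable admitted at a higher threshold can block several
variables that a lower threshold would have admitted, so raising the
threshold can occasionally shrink the selected set. VIF is the conventional
$1/(1-R^2)$ of each variable regressed on the rest (`Inf` under perfect
collinearity); an anchored report layout (each variable regressed on a named
anchor plus the rest) is available for comparability with published tables.

## Suitability classes, areas, change matrices

Suitability maps are classified with fixed bands by default —
$[0, 0.10)$ unsuitable, $[0.10, 0.30)$ low, $[0.30, 0.60)$ moderate,
$[0.60, 1]$ high — half-open with the top class closed, so boundary values
classify reproducibly. Jenks natural breaks (exact Fisher dynamic
programming on the within-class sum of squares, with breaks reported as the
minimum of each upper class so the same interval convention reproduces the
optimal partition) are available as an alternative the same workflow names.
Cell areas are spherical: $R^2\,\Delta\lambda\,(\sin\varphi_t -
\sin\varphi_b)$ with $R = 6371.0088$ km, exact on the sphere, within 0.3% of
ellipsoidal values and platform-identical. Area tables report each class in
$10^4$ km² and percent; "total suitable" is low+moderate+high (the ≥ 0.10
definition used by published area tables), while change matrices binarize at
0.30 (the presence-probability threshold the change analysis defines); both
thresholds are exposed because the two definitions genuinely differ in the
source workflow. Change maps assign each non-missing cell exactly one of
new (0→1), lost (1→0), retained (1→1), unsuitable (0→0); the four classes
partition the landscape, a conservation law the tests assert exactly.

## MESS and MoD

For reference values of variable $V_i$ with minimum $min_i$, maximum
$max_i$, and $f_i$ the percentage of reference values *strictly* less than
the projection value $p_i$ (ties not counted — this makes the boundary
branches reachable exactly at the reference minimum and strictly above the
maximum):

- $f_i = 0$: score $= 100\,(p_i - min_i)/(max_i - min_i)$
- $0 < f_i \le 50$: score $= 2 f_i$
- $50 < f_i < 100$: score $= 2\,(100 - f_i)$
- $f_i = 100$: score $= 100\,(max_i - p_i)/(max_i - min_i)$

MESS at a cell is the minimum score across variables and MoD the variable
attaining it (ties resolved to the lowest variable index). Negative MESS
flags a climate anomaly — at least one variable outside its reference range;
a point at the empirical median of every reference variable scores exactly
100. A degenerate envelope ($min_i = max_i$) divides by zero in the boundary
branches; the package defines the score there as 0 at the reference value
and $-100\,|p - min_i| / \max(|min_i|, 1)$ elsewhere, a scale-guarded
penalty that preserves "negative means novel". The reference set defaults to
the occurrence cells, with a landscape-wide mode available; the upstream
workflow does not state which it used, so neither is asserted as "the"
choice. Mean MESS is reported over all non-missing cells of the projection
extent.

## Centroids and migration

The suitable-area centroid is the area-weighted mean of suitable-cell
centers (binary at threshold 0.30 by default; a suitability-weighted mode is
provided since the source procedure does not specify). Longitudes are
averaged as unit vectors so the centroid is well-defined across the
antimeridian; latitude is the weighted arithmetic mean. Distances between
period/scenario centroids are haversine great circles on $R = 6371.0088$ km
(1° of arc = 111.195 km), with initial bearings in degrees clockwise from
north added for testability; the haversine agrees with the spherical law of
cosines and with an independent geodesic library (flattening set to zero) to
numerical precision.

## The synthetic-scenario generator

Because the real inputs of the motivating analysis (global 30 arc-second
climate, soil and terrain rasters plus curated herbarium records) cannot be
bundled, every stage is exercised on synthetic scenarios with known truth:

- **Layers** are Gaussian white noise smoothed by a separable Gaussian
  kernel (`autocorr_range` = kernel sd in cells), standardized to zero mean
  and unit variance. A target inter-layer correlation matrix, when given, is
  imposed exactly by whitening the empirical correlation and re-coloring
  through the target's (PSD-tolerant) Cholesky-type factor. An optional
  latitudinal trend (`lat_gradient`, units per degree latitude) makes a
  layer track latitude the way real temperature fields do; the warming
  experiments use slope 1.5, making latitude explain roughly three quarters
  of the temperature variance, comparable to the strong meridional structure
  of real annual-temperature fields over multi-degree extents.
- **Species truth** is a log-linear density — exactly the model family — so
  sign recovery and AUC benchmarks are well-posed; presences are sampled at
  cell centers (no sub-cell jitter) so grid snapping is exact, and sampling
  satisfies the defining property that the density ratio of two cells is
  $\exp(\Delta\eta)$.
- **Future scenarios** are additive mean shifts plus standard-deviation
  multipliers per layer, applied as $x' = (x-\bar x)\,m + \bar x + \delta$ so
  the mean moves by exactly $\delta$, the sd scales by exactly $m$, and the
  perturbation is exactly invertible.

What the generator does *not* emulate: categorical variables, spatial
sampling bias in occurrences, dispersal limitation and biotic interactions,
non-stationary (regionally varying) climate change, and observation error in
coordinates. Passing tests therefore demonstrate correctness of the
machinery and qualitative climate-response behaviour (poleward centroid
shifts of a cool-adapted species under warming; area loss under strong
warming), not predictive skill on real species data.

## Occurrence cleaning

Cleaning applies, in order: removal of off-grid or masked-cell records
("unclear geography"), one-record-per-grid-cell thinning (standard practice
against pseudo-replication), and robust z-score outlier removal on the
environmental values ($|x - \mathrm{med}|/(1.4826\,\mathrm{MAD}) >$ 4 by
default), iterated to a fixed point so cleaning is idempotent. The retained
count plus the per-rule exclusion counts always equals the input count. The
published workflow reports only that 84 records were filtered to 73 without
stating the per-rule breakdown, so the report format here is the package's
own.

## Problem sizes and numerical choices

The test suite and the acceptance script run entirely on synthetic data at
desk scale, chosen to keep a full run within a few minutes on one CPU while
leaving each statistical check well-powered: 50×50–60×60 landscapes,
120–500 presences, 1,000 background cells, 10 hinge knots for full-grid
tuning, and 10-seed replication for the stochastic claims (sign tests at
$\alpha = 0.05$). Solver tolerance is $10^{-7}$ on the objective;
equality-type assertions use $10^{-9}$–$10^{-12}$; Monte-Carlo frequency
ratios use 5% relative tolerance at $n = 10^5$. Seeds are explicit
everywhere; a run is reproducible bit-for-bit from its configuration.

## Known limitations

- The per-class penalty schedule is a simplified rendering of the Maxent
  defaults; absolute coefficient values will differ from the Java
  implementation even where signs and fits agree.
- AICc uses the landscape-renormalized likelihood; with very large
  landscapes the renormalization constant is the dominant cost of tuning.
- Greedy correlation screening is order-dependent by design (importance
  ranking) and non-monotone in its threshold (above).
- Areas are spherical, not ellipsoidal (< 0.3% bias, stated above).
- The raster interchange format is the plain-text ESRI ASCII grid; there is
  no GeoTIFF reader/writer, and grids must be co-registered in geographic
  coordinates (WGS84 decimal degrees).
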