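---
title: "Methods: spatially explicit multi-threat assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially explicit multi-threat assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices, numerical
conventions and known limitations behind `threatmapr`. It is the package's
own account of its science; every number quoted here is computed by the
test suite or by `scripts/acceptance.R`, not asserted from memory.

## 1. The analysis grid

All stages operate on one geographic (longitude/latitude) raster,
`grid_spec`, with row 1 northernmost and cell centers at
`origin + (i - 0.5) * cell_size`. The default cell size is 2.5 arc-minutes
(1/24 degree), roughly 4.5 km at the equator; the "nominal" pixel area used
for site-level threats is therefore 4.5 x 4.5 = 20.25 km2, while the
geodesic mode scales the east-west side by `cos(latitude)` (111.32 km per
degree). Layers with other resolutions are brought onto the analysis grid
by bilinear interpolation of the four surrounding source cell centers;
target cells whose center falls outside the source center hull are masked
out rather than extrapolated.

Conventions worth making explicit:

* **Point-in-cell membership is half-open** — `[west, east)` in longitude,
  `(south, north]` in latitude — so a point on a shared edge lands in
  exactly one cell. This makes rasterization deterministic and
  weight-conserving.
* **Min–max normalization** is computed over the study-area mask, per
  layer. A constant layer normalizes to all zeros with a warning instead of
  erroring, so degenerate synthetic inputs flow through the pipeline. The
  operation is idempotent on non-degenerate output.
* **Square-root transform** is applied to the overgrazing and fire layers
  before normalization because their raw distributions are heavily
  right-skewed; without it the top few pixels would compress everything
  else into the lowest magnitude classes.
* I/O uses ESRI ASCII grids (plain text) for rasters and CSV for point
  tables, so synthetic and real runs are interchangeable and all fixtures
  remain human-readable.

## 2. Ensemble species distribution models

### Variable screening

Collinear predictors are pruned by stepwise VIF elimination: regress each
variable on the others over masked cells, `VIF = 1/(1 - R^2)`, drop the
largest while it exceeds the ceiling (default 20). A perfectly collinear
variable has infinite VIF and is dropped first; ties cannot occur with
continuous data but would resolve by first index. The retained set is
verified in tests by brute-force recomputation of all VIFs.

### Calibration protocol

`calibrate_ensemble()` uses defaults of 2000 background cells per repeat
(sampled without replacement, *excluding* presence cells — the sources the
protocol emulates are silent on exclusion, and at desk scale including
known presences as background only adds label noise), 4 random subsets for
train/test splitting, 5 repeats, and a minimum of 30 unique presence cells
(violations raise a classed `species_rejected` error naming the rule).
Twelve candidate submodels are registered by default: logistic regression
(linear and quadratic), a spline additive model, a classification tree,
random forest, gradient-boosted trees, k-nearest neighbours, naive Bayes, a
rectilinear (BIOCLIM-style) climate envelope, a Mahalanobis-distance
envelope, linear discriminant analysis, and a lasso-regularized exponential
model with quadratic features (max-entropy flavoured). The registry is
pluggable: any object with `fit(x, y)` and `predict(model, x)` returning
scores in [0, 1] can be swapped in via `sdm_config(candidates = ...)`.

Per repeat and fold, every candidate is fitted on the training folds and
scored on the held-out fold by Mann–Whitney AUC (average ranks give tied
scores half a win, so `auc(pos, neg) + auc(neg, pos) = 1` identically). A
candidate that errors receives AUC 0 for that fold and cannot enter the
kept set; if fewer than 10 candidates survive, all survivors are used and
weights renormalize, with a message. Ties at the 10th rank break by
registry order. The ensemble weight of a kept candidate is its mean AUC
divided by the kept candidates' total, so weights are non-negative and sum
to one with exactly 10 nonzero entries when all candidates fit.

The final suitability layer is the mean over repeats of the weighted
ensemble prediction from candidates refitted on each repeat's full data.
Thresholds are computed *on this averaged map* (not per repeat and then
averaged — averaging first keeps the threshold consistent with the map it
will actually cut).

### Thresholds

Two presence thresholds are derived from suitability at the presence
cells: `minimum` (the smallest presence score, guaranteeing 100% training
coverage) and `tpr90`, the largest threshold retaining at least 90%
coverage. The latter is the `floor(0.1 n) + 1`-th smallest presence score:
for ten scores 0.1, 0.2, ..., 1.0 it returns 0.2, with exactly 9/10 scores
at or above it. `tpr90 >= minimum` always holds (order-statistic
inequality), so the tpr90 presence map is nested inside the minimum-
threshold map.

### Novel climate

A cell is climatically novel under a future stack when at least one
variable falls outside the **closed** min–max envelope of current
conditions over the reference mask; a value exactly equal to the current
extreme is not novel. The reference mask defaults to the full calibration
extent.

### Four candidate maps per species

The assessment produces four alternative current distribution maps per
species: {stepwise-VIF-selected variable set, the annual temperature +
annual rainfall pair} x {`minimum`, `tpr90`}. These are deliberately
different-looking candidates for expert comparison, not competing "best"
models; the expert consensus stage picks one.

## 3. Cultural-consensus analysis

Experts rate items on a 1–5 scale with missing entries allowed. The chain
is: (1) drop experts with fewer than two usable ratings; (2) pairwise
Spearman concordance over pairwise-complete items (pairs with under two
shared items, and zero-variance experts, yield missing entries); (3) impute
missing correlations from the two experts' mean observed correlations; (4)
fit a single-factor maximum-likelihood factor analysis to the correlation
matrix; the first-factor loadings are the competence weights and the
first-factor variance share is the consensus rate. Loadings (not squared
loadings) are used, matching standard consensus analysis; the factor's sign
is fixed so the loading sum is positive, and negative loadings are floored
at zero — an "anti-consensus" expert gets no voice rather than a negative
one. On non-convergence the first principal eigenvector (scaled into
[0, 1]) substitutes; with fewer than three experts the fallback is each
expert's mean correlation with the others, floored at zero.

Weighted item scores are `S_j = sum_i w_i r_ij / sum_i w_i` over the
experts who rated item j, invariant to positive rescaling of the weights
and confined to [1, 5]. The best item is the argmax, ties broken by lowest
index with a warning. The reported `average_concordance` is the mean weight
over valid experts.

For the compound-symmetry correlation matrix (all off-diagonals equal to
rho) the one-factor solution has loadings `sqrt(rho)` for every expert;
this closed form anchors the factor-analysis tests.

**Sensitivity normalization.** Weighted threat-sensitivity scores on the
1–5 scale are mapped to a [0, 1] multiplier. The default is
`(S - 1)/4` — the natural linear map of the printed scale, under which a
score of 1 ("no sensitivity") contributes zero threat. Because observed
scores rarely approach 5, this compresses products toward lower classes;
`S/5` and within-species min–max are available as configuration options
for analysts who prefer a hotter calibration. The choice is recorded in
the run manifest.

## 4. Threat layers

* **Overexploitation**: human-footprint index (0–100), resampled and
  min–max normalized. One composite proxy stands in for several harvest
  pressures; it cannot separate fuelwood from fodder collection.
* **Overgrazing**: tropical livestock units `0.7*cattle + 0.1*goats +
  0.1*sheep` (the standard 250-kg-ruminant equivalents), then square root
  and min–max.
* **Fire**: detections with confidence strictly greater than 30 are kept
  ("exceeded 30%" is read as a strict inequality; 30.0001 passes, 30.0
  does not). Late-season fires — January to March, the peak of the dry
  season — receive double weight, reflecting roughly doubled tree
  mortality in late burns; all other months count as early (conservative
  for months outside the core fire season). Per cell, the weighted count
  is divided by the number of years in the window and the cell area in
  km2, then square root and min–max. Frequency is computed directly on the
  2.5-arc-minute grid; computing on a finer detection grid first and
  resampling would smooth hotspots slightly but is not what the per-cell
  count semantics require.
* **Cotton**: each province's production total is split equally over its
  producing cells, then min–max normalized. The layer is flagged `capped`:
  the source mapping cannot resolve production peaks, so Very high is
  never assigned — classification tops out at High. Allocation conserves
  province totals exactly (tested).
* **Mining**: cells containing at least one active or prospective site are
  rated Very high outright — a single nominal 20.25-km2 pixel covers the
  site and its degraded surroundings; inactive sites are ignored; there
  are no intermediate classes.
* **Climate change**: classified from four boolean layers (presence under
  the intermediate and high pathways, novelty under each) by an ordered
  rule list: (1) absence under the moderate scenario already ⇒ Very high;
  (2) presence under both but in novel climate under both ⇒ High; (3)
  presence in novel climate under the moderate scenario ⇒ Medium; (4)
  presence under the moderate scenario only ⇒ Low; (5) presence under
  both, no novelty ⇒ No threat. Narrative definitions of such rules
  overlap (a cell absent under the high scenario fits both "one scenario
  predicts absence" and "only the moderate scenario predicts presence");
  the ordered list resolves this, anchored to the reading that losing
  habitat under the *moderate* scenario is the worst case. The full
  16-case truth table is exercised in the tests and is total and
  single-valued.

## 5. Magnitude classes and combination

The five-class scale is defined by printed two-decimal intervals
(No threat ≤ 0.01; Low 0.01–0.1; Medium 0.11–0.3; High 0.31–0.7; Very high
0.71–1). The gaps between printed bounds (0.10 vs 0.11, etc.) are resolved
by midpoint boundaries at 0.105, 0.305 and 0.705 with lower-exclusive /
upper-inclusive intervals, preserving the printed semantics: any value
rounding to 0.71 is Very high, any value rounding to 0.70 is High.
`classify_magnitude` is a total monotone step function on [0, 1], and its
capped variant never returns Very high.

Species-specific threats multiply normalized sensitivity by normalized
intensity pixel-by-pixel before classification; generic threats use
sensitivity 1; mining and climate classes bypass the multiplication
entirely ("severity" for them is categorical, not a 0–1 intensity). The
geographic-scope side of magnitude is carried by the reported area
percentages, not by a per-pixel multiplier.

The combined map takes the per-pixel maximum over the six classes, then
applies the 3–5 rule: three or more Highs upgrade to Very high, else five
or more Mediums upgrade to High. `combine_threats` is verified against an
independently coded literal transcription of this rule on all 5^6 = 15 625
input combinations, and monotonicity (raising any single input class never
lowers the output) is property-tested. Area summaries are restricted to
each species' distribution mask; combined-class rows sum to 100% and the
severe percentage equals High + Very high by construction (both tested).
Hotspot maps count species whose combined class is severe per cell, so the
count is bounded above by species richness everywhere.

## 6. Synthetic data: what it emulates, and what it does not

The generators reproduce the *statistical structure* the pipeline assumes:

* Climate: north–south gradients (warmer, drier, longer dry season
  northwards) with smooth low-amplitude noise; future stacks shift by
  +1.5 °C / −10% rainfall (intermediate pathway) and +3.0 °C / −20%
  (high pathway) by default, exactly and deterministically per seed.
* Occurrences: cells drawn with probability proportional to a known
  Gaussian-response niche (responses multiply across variables — simple
  and monotone-recoverable), then deduplicated to unique cells. Retaining
  the generating truth lets tests score suitability recovery directly.
* Threats: footprint with urban hotspots; right-skewed lognormal livestock
  heavier in the north; fire events spanning November–March with uniform
  confidences; cotton confined to a south-western block of axis-aligned
  synthetic provinces (only per-province totals matter downstream); sparse
  mining points with an activity status.
* Expert panels: rating = round(clamp(truth + noise, 1, 5)) with noise SD
  `sigma0 * (1 - competence)`, `sigma0 = 2` by default. Note the clamped,
  rounded scale means even a zero-competence expert retains a weak
  association with the truth (the theoretical attenuation for uniform
  truth is about 0.5); competence *ordering* is still recoverable, which
  is what the consensus stage needs.

What the generators do **not** emulate: realistic spatial autocorrelation
of any particular country, road networks, seasonally varying detection
effort, or inter-expert response-style differences. Passing tests
therefore demonstrate correctness of the algorithms and recoverability
under the assumed structure — not predictive skill on real landscapes.

Test and acceptance problem sizes are chosen to exercise the full default
protocol at desk scale: a 60 x 80 grid with 200 occurrence draws for the
ensemble (all 12 candidates, 2000 background, 4 folds, 5 repeats), 50
panels of 15 experts x 12 items for consensus recovery, and a reduced
30 x 40 / 2-species configuration for end-to-end runs.

## 7. Known limitations

* The twelve default candidates are standard R implementations, not
  re-implementations of any particular SDM toolbox; numerical outputs are
  not expected to match other software, only the protocol semantics.
* Geographic lat/lon grids only; no projections, no vector geoprocessing
  beyond point-in-cell and mask burning.
* Expert-survey and magnitude-rating constants (class cut-offs, the 3–5
  rule, double late-fire weight) are field conventions taken as given;
  their calibration against field mortality data is outside scope.
* The threshold on cotton (cap at High) and the direct Very-high rating of
  mining pixels encode source-data resolution limits, not biology.
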