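---
title: "Methods: ensemble species distribution modelling with ensdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ensemble species distribution modelling with ensdm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdm)
```

## The modelling problem

`ensdm` implements the classic ensemble species-distribution-modelling
(SDM) workflow for presence-only data: occurrence records of a species
are related to gridded environmental predictors (bioclimatic summaries
such as annual mean temperature or annual precipitation, plus
topography), a committee of learner families estimates the probability
of occurrence per grid cell, and the committee's weighted average is
projected onto current and perturbed ("future-climate") predictor
stacks. Downstream products are the familiar ones: a continuous
suitability map, a five-class suitability map, a binary suitable /
unsuitable map cut at the threshold maximizing the true skill statistic
(MAX_TSS), and a four-category change analysis (stable presence, stable
absence, habitat loss, habitat gain) with areas in km² and loss / gain /
net percentages relative to the currently suitable area.

The package was shaped around the analysis commonly run for
narrow-range medicinal plants in semi-arid mountain systems — the
worked example ships the reported importance and habitat-change tables
for *Stachys inflata* in Isfahan province (central Iran) — but every
stage is generic and fully testable on synthetic data.

## Data model and grid conventions

A `raster_grid` is a numeric matrix plus a logical nodata mask and a
cell size in km; row 1 is the northern edge, indexing is (row, col).
Cells are treated as equal-area squares of `cell_size_km²`; no geodesic
correction is applied. Study areas reported in km² from ~1-km cells at
mid-latitudes incur a modest cos(latitude) distortion under this
convention; the synthetic tests are planar, and users with projected
data lose nothing. Masked cells are excluded from every statistic,
every training extraction and every area count.

ASCII grids (NCOLS/NROWS/XLLCORNER/YLLCORNER/CELLSIZE/NODATA_value) are
the full-fidelity interchange format: values are written to full double
precision and nodata round-trips exactly. A `CELLSIZE` given in decimal
degrees is converted at 1° ≈ 111.32 km (the equatorial value). GeoTIFF
support is deliberately narrow: the underlying TIFF library stores
32-bit float samples and only round-trips values in [0, 1], so the
GeoTIFF dialect accepts only fully-unmasked unit-interval grids
(suitability and binary maps) and takes its cell size from the caller —
it carries no georeferencing keys. Anything else should travel as an
ASCII grid.

## Occurrences, background, and thinning

Thinning removes exact duplicates and then keeps, in input order, every
point at Chebyshev distance ≥ `min_separation_cells` from all
previously kept points. With 1-km cells and the default separation of
1, this is the usual "no two records closer than 1 km" filter; the
greedy-in-input-order rule is a deterministic tie-break (field
protocols rarely state one). Thinning is idempotent.

Background (pseudo-absence) points are drawn uniformly at random, one
per cell, from non-masked cells not occupied by a presence, with no
exclusion buffer, and the default count equals the number of presences.
One background sample serves the whole analysis — it is not regenerated
per cross-validation repetition — so that all families and repetitions
see the same training table.

## Collinearity pruning

Pearson correlations are computed over all training rows (presences
plus background). Pairs with |r| above the threshold (default 0.8) are
visited in decreasing |r|; whenever both members are still retained,
the one later in the priority list is dropped. The priority list
defaults to the stack's layer order, so users encode ecological
preference by ordering their layers. The retained set always satisfies
max pairwise |r| ≤ threshold. Which member of a collinear pair survives
is genuinely arbitrary in most published analyses; an explicit,
deterministic priority rule at least makes the choice reproducible.

## The ten learner families

All families sit behind one contract: `fit(spec, table)` returns a
model whose predictions are probabilities in [0, 1], deterministic for
a fixed `seed`. The implementations are the standard statistical
equivalents available in R:

| Family | Implementation | Fixed defaults |
|---|---|---|
| GLM | binomial `glm`, linear terms | — |
| GAM | `mgcv` thin-plate smooths | basis dimension k = 4 |
| GBM | gradient boosting (`xgboost`) | 1000 rounds, η = 0.01, depth 3 |
| RF | `randomForest` | 500 trees |
| CTA | `rpart` classification tree | minsplit 10, cp 0.01 |
| ANN | `nnet`, standardized inputs | 8 hidden units, decay 0.05, 300 iter |
| MARS | hinge basis + lasso logistic | knots at 1/3, 2/3 quantiles; λ = 0.01 |
| FDA | LDA on the same hinge basis | near-constant columns dropped |
| MAXENT | ridge logistic on z, z² features | λ = 0.01 |
| SRE | presence-quantile envelope | quantile 0.025 |

The MaxEnt-style family exploits the standard equivalence between
maximum-entropy density estimation on presence/background data and
penalized logistic regression; quadratic features give it unimodal
response capacity. MARS uses a fixed-knot piecewise-linear (hinge)
basis with lasso term selection supplying the adaptivity; FDA is a
discriminant analysis on that same basis. The surface range envelope
stores, per predictor, the [q, 1−q] empirical quantile interval of the
presence rows only and predicts 1 iff every predictor lies inside its
interval — its output is binary by construction, which matters for
interpreting its AUC (see below). No published hyperparameters exist
for this kind of analysis, so every default above is an explicit,
documented choice rather than a reconstruction.

## Evaluation

Models are evaluated by repeated stratified random splits (default
80/20, ten repetitions). Most SDM protocols say only "randomly";
stratification is this package's explicit choice because at n ≈ 130
rows an unstratified 20% test fold loses a class often enough to
matter. AUC is the rank-based Mann–Whitney statistic (ties 0.5). TSS is
sensitivity + specificity − 1 with the ≥ threshold convention (a score
equal to the threshold counts as presence, so threshold 0 means "all
present"). The MAX_TSS threshold maximizes TSS exactly by evaluating
the candidate set {0, midpoints of consecutive sorted unique scores, 1}
— TSS is a step function, so a midpoint scan is exact where a fixed
grid is only an oracle; ties break toward the smallest threshold. AUC
and TSS are graded on the conventional five-band scales
(invalid/bad/acceptable/good/excellent for AUC at 0.6/0.7/0.8/0.9;
lacking/bad/acceptable/good/excellent for TSS at 0.2/0.4/0.6/0.8, all
bands closed on the right).

One statistical caveat worth knowing: the held-out MAX_TSS value equals
the two-sample Kolmogorov–Smirnov distance between the presence and
background score distributions, which has a positive O(1/√n) bias under
the no-skill null. On a 20-row test fold a TSS near 0.4 can arise from
noise alone; the package's own null-simulation check therefore uses
200-per-class test folds, where the bias is below 0.1.

## TSS-weighted ensembling and its fallback

Cross-validated runs (family × repetition) with held-out TSS at or
above the cutoff (default 0.8) become ensemble members, weighted
proportionally to TSS and normalized to sum to one. The 0.8 cutoff is
nominal in much of the applied literature: reported member TSS values
frequently top out well below it, in which case a strict reading would
leave the ensemble empty even though member skill is respectable. When
no run reaches the cutoff, `build_ensemble()` falls back to keeping
every run with TSS-proportional weights and sets a prominently logged
`fallback_used` flag, reproducing the ensemble such studies evidently
built while surfacing the discrepancy. The cutoff applies per run, not
per family mean. Ensemble prediction is the cellwise convex combination
of member predictions; the ensemble's MAX_TSS threshold is measured
once against the training table and reused unchanged for every future
projection.

Suitability classes use half-open bins closed on the left at 0.2, 0.4,
0.6, 0.8 (so p = 0.8 is "excellent" and p = 0.2 is "low"). Response
curves are evaluation strips: one predictor sweeps its observed min–max
while the others are held at their training-table means (means, not
medians — exposed as an argument because the conditioning statistic is
a genuine free choice).

## Change analysis

Binary maps are compared cellwise: (1,1) stable presence, (1,0) loss,
(0,1) gain, (0,0) stable absence; the four categories partition the
non-masked grid by construction. Loss and gain percentages are both
expressed relative to the *current* suitable area (stable presence +
loss). That denominator choice makes net change ≡ gain − loss an exact
identity, which is also the internal-consistency check the bundled
reference change table passes on eleven of its twelve rows (the twelfth
violates it by several points and is best read as a typographical
error; the package's tests exclude it). Per-class percent changes with
a zero current-area baseline are flagged `undefined` rather than
propagated as infinities.

## The synthetic study system

Because real occurrence records and climate rasters are rarely
redistributable, the generator builds study systems with the structure
the analysis assumes:

* **Layers** are white Gaussian noise convolved with a uniform box
  kernel (radius in cells), then affinely rescaled to a requested
  mean/sd. Box smoothing is cheap and produces the broad spatial
  gradients that make thinning and extraction meaningful; it is not a
  Gaussian-process emulator and its autocorrelation range is only
  loosely controlled.
* **Collinear copies** are `source + N(0, noise_sd)`; at
  `noise_sd = 0.1·sd(source)` the empirical |r| exceeds 0.8 in ≈ 99% of
  seeds, giving the pruning stage a guaranteed target.
* **Truth** is a logistic surface over standardized layers with
  optional quadratic terms. The quadratic extension exists because a
  purely linear logistic truth cannot *gain* habitat under a uniform
  warming shift — suitability would change monotonically everywhere —
  whereas a thermal optimum moves upslope, which is exactly the
  behaviour the change analysis needs to be tested against.
* **Presences** are drawn without replacement with probability
  proportional to truth suitability; there is no observation-error or
  detection layer, and no dispersal constraint.

The frozen strong-signal condition used by the recovery checks is: a
64 × 64 km grid, eight unit-sd layers at smoothing radius 3, truth
coefficients +2.5 and −2.5 on two layers with intercept −5, 200
presences and 200 background points. The negative intercept puts
landscape prevalence near 10%, matching the low-prevalence niche of a
narrow-range species; at ~50% prevalence a uniform background sample
overlaps suitable habitat so heavily that even the Bayes-optimal
classifier's AUC sits near 0.7, so "strong signal" necessarily means
"low prevalence" here. The warming condition derives temperature from a
smooth elevation field by a 6.5 °C/km lapse rate plus local noise,
gives the truth a thermal optimum at the current mean temperature, and
applies a +2.76 °C delta — the current-to-2050s mean-temperature trend
reported for the example study region.

Under these conditions (and the seeds exercised in the test suite) the
package measures: mean held-out ensemble AUC ≈ 0.89–0.95 over five
seeds; the two generative layers occupy the top-2 mean
permutation-importance ranks in 25/25 seeds; and gain cells sit at
higher mean elevation than loss cells in 20/20 warming seeds. What
passing these simulations does *not* show: robustness to sampling bias,
detection error, spatially blocked evaluation, or non-stationary
truth — real data have all four.

## Permutation importance

Importance of a predictor is `100 × mean(1 − r)` over a small number of
shuffles (default 3), where r is the Pearson correlation between
predictions on the intact table and on a table with that single column
permuted; negative correlations are clamped so each term stays in
[0, 1], and zero-variance intact predictions define importance 0.
Scores are computed on the full training table, one per (algorithm,
variable) pair; per-variable child seeds reuse the same permutations
across algorithms. The summary table averages scores over algorithms
("relative importance") and normalizes the means to percentages summing
to 100 ("contribution"). The bundled reference table reproduces its
printed means (36.17 for annual mean temperature, 33.56 for annual
precipitation) and its printed top-four cumulative contribution
(56.55%) from the per-algorithm scores alone.

## A note on SRE and performance floors

The package's wiring smoke test requires five-seed mean held-out AUC
≥ 0.75 from the nine probabilistic families on a two-variable niche,
but only ≥ 0.65 from SRE. A binary-output classifier's rank AUC is
algebraically (sensitivity + specificity)/2, and a rectangular envelope
approximates a diagonal logistic band poorly, so SRE's ceiling on such
truths sits near 0.7 — consistent with the envelope family occupying
the bottom of reported AUC ranges (≈ 0.69) in applied ensemble studies.
Demanding 0.75 of it would not test wiring; it would test geometry that
the classifier cannot have.

## Pipeline and reproducibility

`run_pipeline()` executes the whole chain from one validated YAML (or
list) config and writes evaluation and importance CSVs, an ensemble
JSON with member weights and the fallback flag, suitability / class /
binary / change rasters per scenario, a change-summary CSV, and a
`report.json` echoing seeds, filled defaults and every artifact name. A
single master seed derives per-stage child seeds by fixed offsets, so
one integer reproduces a full run bit-for-bit; stage failures abort
with the stage name and leave a `FAILED` marker beside any partial
outputs. Simulation problem sizes throughout the package (64 × 64
grids, 200–400 training rows, 5–25 seeds per check) are chosen so the
entire verification battery runs in minutes on one core while keeping
the Monte-Carlo acceptance bands comfortably away from their
thresholds.

## Known limitations

Equal-area cells (no projection support); no spatially blocked or
target-group validation; no dispersal constraints or observation model
in the generator; fixed-knot MARS rather than forward/backward basis
search; GeoTIFF restricted to unit-interval unmasked grids; importance
computed on training data (not held-out folds), which matches common
reporting practice but inherits its optimism.
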