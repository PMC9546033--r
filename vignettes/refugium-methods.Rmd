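---
title: "Methods: presence-background models and climate refugia for alpine birds"
author: "refugium authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-background models and climate refugia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refugium)
```

## Overview

`refugium` implements an end-to-end pipeline for assessing how climate
change may displace the suitable range of high-elevation bird species
(rock ptarmigan, water pipit, alpine accentor, white-winged snowfinch are
the motivating examples): quality control of citizen-science occurrence
records, presence-background maximum-entropy modelling on a 1-km grid,
spatial-block cross-validation, projection under four alternative future
climate conditions, classification of in-situ and ex-situ climate
refugia, and a protected-area gap analysis.  Because the real inputs
(climate reanalyses, land-cover inventories, multi-portal occurrence
databases) cannot be redistributed, the package ships a seeded synthetic
alpine landscape generator with a known ground-truth species, so that
every stage is testable and the statistical behaviour of the pipeline can
be verified against truth.

## The model

The core estimator is a presence-background maximum-entropy model
(`maxent()`).  Given presence points $P$ (one per occupied 1-km cell,
$m = |P|$) and background points $B$ drawn inside 2-km buffers around the
presences, the model places a probability distribution
$q(x) = e^{\lambda \cdot f(x)} / Z(\lambda)$ over the finite point set
$S = P \cup B$ and maximizes the penalized presence log-likelihood

$$\frac{1}{m}\sum_{x \in P} \lambda \cdot f(x) \;-\; \ln Z(\lambda)
  \;-\; \sum_j \beta_j |\lambda_j|, \qquad
  Z(\lambda) = \sum_{x \in S} e^{\lambda \cdot f(x)}.$$

Features $f$ are restricted to linear and quadratic transforms of the
min-max-scaled predictors (scaling bounds learned on $S$ and stored for
projection), a deliberately simple feature space that limits overfitting
when models are projected into future climates.  The per-feature penalty
is $\beta_j = \mathrm{rm} \cdot s_j / \sqrt{m}$, where $s_j$ is the
feature's standard deviation over $S$ and rm is the regularization
multiplier.  This replaces the tabulated per-feature-class defaults of
the original MaxEnt software, which are not recoverable in closed form;
the $1/\sqrt{m}$ scaling preserves their qualitative behaviour (weaker
penalty with more presences) and is exposed in the configuration.

Two modelling conventions matter downstream:

* **Normalization over $S$, not over raster cells.**  Both the fitted
  distribution and the model-selection criterion are computed on the
  presence + background points only.  This keeps fitting and AICc
  mutually consistent and restricts every likelihood statement to the
  environments that were actually sampled.
* **Cloglog output.**  Reported suitabilities are
  $1 - \exp(-e^{H} q(x))$ with $H$ the entropy of $\hat q$ over the
  training points; this is the standard monotone transform onto $(0,1)$,
  and all thresholds operate on this scale.

### Optimization

The objective is concave with an L1 penalty, so the contract is the
global optimum, not a particular algorithm.  The implementation uses
proximal-gradient iterations (FISTA with backtracking line search and a
monotone restart safeguard); soft-thresholding produces exact zeros,
which the variable-removal rule ("drop variables whose coefficients are
all zero") keys on.  Convergence is declared when the objective changes
by less than `tol` (default $10^{-8}$, relative) between iterations; the
iteration cap is a tunable (`iter_cap`, grid {240, 260, 300, 500}).  The
test suite checks the optimum against an independent dense grid-search
oracle on all small instances (two variables or fewer, twelve points or
fewer) to $10^{-6}$ in the objective.

### Model selection

`aicc()` computes a small-sample-corrected AIC from the presence
log-likelihood over $S$, with $k$ = the number of nonzero feature
coefficients, returning an invalid marker (`NA`) when $m - k - 1 \le 0$.
`tune_maxent()` mirrors a three-step selection procedure: (A) pick the
regularization multiplier from {0.25, 0.5, 1, 2, 4} by AICc on the full
linear+quadratic model; (B) remove all variables with zero coefficients;
(C) a greedy loop over single moves — change rm, toggle linear-only
versus linear+quadratic features, change the iteration cap, or drop the
variable with the lowest permutation importance — accepting the move
with the largest AICc decrease until no move decreases it.  The original
description names the ingredients but not the search; a deterministic
greedy search with a fixed candidate order was chosen so tuning traces
are exactly reproducible.  One subtlety: iteration-cap moves are skipped
when the current fit converged below the smallest candidate cap, since
they provably cannot change the optimum.

Permutation importance permutes a variable's raw values jointly across
$S$ (rebuilding both its features), and reports the mean drop in
training AUC over `n_perm` permutations (default 10), clipped at zero
and normalized to percentages.  AUC-drop was chosen as the metric
because it is directly testable (a variable with zero coefficients has
exactly zero importance) and rank-equivalent to gain-based importance in
practice.

## Evaluation

* AUC uses the rank (Mann-Whitney) formulation with ties counted ½.
* TSS is maximized over thresholds scanned at midpoints between
  adjacent distinct pooled scores; background points act as
  pseudo-absences for specificity, the standard presence-background
  surrogate.  The source procedure does not state its TSS threshold
  convention; maximization is our documented choice.
* Thresholds: the 10th-percentile training-presence threshold uses the
  linear-interpolation empirical quantile (R's type-7); the minimum
  training presence is the 0th percentile.  Omission counts scores
  strictly below the threshold, so training omission at the minimum
  training presence is exactly zero.
* `evaluate()` flags a model when the train-test AUC gap exceeds 0.05.

Spatial cross-validation uses the two-scale checkerboard with
aggregation factors (4, 2) on the 1-km grid: parities of
$\lfloor (x - x_0)/c_k \rfloor + \lfloor (y_0 - y)/c_k \rfloor$ at 4-km
and 8-km block sizes combine into four spatially interleaved partitions;
three train the model and the fourth tests it.  The parity origin is
anchored at the grid origin — the anchoring of the original
implementation is not recoverable, so tests assert statistical
properties (balance, periodicity) rather than label identity.

## Projection, refugia, and the gap analysis

Projection applies the stored feature map to a climate + static raster
stack; clamping is off by default, so features extrapolate linearly
beyond the training range — appropriate here because the species'
niches sit well below the warm edge of the sampled climate, making
non-analogue extrapolation risk minimal.  A single per-species
threshold (the 10th percentile of training-presence cloglog scores on
the current-climate model) binarizes the current and all four future
maps.

Refugia codes per cell: type 1 (in-situ) = suitable now and under all
four future conditions; type 2 = unsuitable now, suitable under all
four; type 3 = unsuitable now, suitable under exactly three of four
(types 2 and 3 together form the broad ex-situ set).  Cells suitable
now but suitable under only three futures receive no code under the
strict reading of the definitions; they can be recovered from the
binary masks if needed.  Multispecies refugia are cells that are type-1
refugia for at least three species.  The gap analysis counts a refugium
cell as protected if the (synthetic) protected-area mask marks it,
overall and per country, with a variant restricted to IUCN categories
1-4 plus a designation keep-list (Natura 2000 sites and selected
national designations).

## The synthetic landscape

`synthetic_landscape()` generates, from one seed: smoothed-random-field
terrain (mean 1500 m, relief SD 800 m, 15-km correlation length — an
alpine massif at 1-km resolution), slope and a south-facing radiation
index from central differences; temperature following a -6.5 °C/km
lapse rate from a 14 °C sea-level baseline (so a ~1300-m mean elevation
gives a ~5-6 °C regional mean); twenty per-year temperature layers
(2000-2019) whose cell-wise mean is the background layer; precipitation,
temperature range and seasonality as smooth fields with moderate
elevation correlation; ten CORINE-like fractional land-cover classes as
elevation-banded weights with strong independent spatial variation;
random rectangular protected areas with IUCN categories and
designations; and a Voronoi country partition.

Choices worth stating explicitly:

* **Predictor collinearity.**  The land-cover wobble (log-normal smooth
  field, strength 1.6) is deliberately strong so that no predictor pair
  exceeds |r| = 0.7, matching the variable-screening rule applied to
  the real predictor set before modelling.  With weak wobble the cover
  classes become near-deterministic functions of elevation and the
  temperature signal is no longer attributable.
* **Interannual anomalies are mean-zero by default.**  Per-year
  temperature layers add a scalar interannual anomaly (SD 0.15 °C) and
  a smooth spatial field (SD 0.3 °C); the linear warming trend
  parameter defaults to zero.  A nonzero common-mode trend interacts
  with the most-recent-year rule used when deduplicating records to
  cells: presences would carry systematically warmer measurements than
  the period-mean background, a real and transferable signal that a
  virtual species placed uniformly at random would also exhibit.  The
  reference study reports that its uniform virtual species retained no
  variables; reproducing that property requires the common-mode
  anomaly to be negligible.  This interaction is a genuine limitation
  of per-record-year extraction worth knowing about when applying the
  pipeline to real data.
* **Future conditions.**  Four named conditions mirror the reported
  GCM anomalies over the Alps under the high-emission pathway:
  +2.54 °C (MRI-ESM2-0, mildest) to +4.19 °C (UKESM1-0-LL, most
  extreme) relative to the 2000-2019 reference, with the two
  intermediate models at +3.1 and +3.6 °C (the source reports them
  only as intermediate; the ordering matches the relative contraction
  they produce).  Precipitation and seasonality deltas are small fixed
  values; land cover and topography are held constant.
* **Occurrence records.**  Cells are drawn multinomially with
  probability proportional to $e^{\text{score}}$ of the ground-truth
  species (log-linear with linear + quadratic terms on standardized
  predictors); positions are uniform within cells, dates uniform within
  a configured season, and independent Bernoulli corruption produces
  the four rejection classes the QC filters must catch (pre-2000 year,
  accuracy > 1 km, out-of-season date, implausible habitat), 5% each by
  default.

What the generator does **not** emulate: sampling-effort gradients and
observer bias, spatial autocorrelation of residual suitability beyond
the smooth fields, interacting species, land-cover change, and real
orography.  Passing tests therefore demonstrate that the pipeline's
statistics behave correctly under known conditions — not that any
particular real-world dataset would yield reliable models.

## Record quality control

Retention requires: year ≥ 2000; known accuracy ≤ 1000 m; breeding code
above `none`; plausible habitat (a flag standing in for expert
orthophoto inspection, which is not implementable in code); and a date
in the species' core breeding window, or in an extended shoulder window
with breeding evidence at least `probable`.  Core windows: 1 May-31 Jul
(rock ptarmigan), 15 May-31 Jul (water pipit, alpine accentor),
1 Jun-31 Jul (snowfinch); extended windows are April and August for the
ptarmigan, 1-14 May ("early May", read as the complement of the core
window) and August for pipit and accentor, and 1-15 August for the
snowfinch.  Rejections are logged with the first failing rule in the
fixed order year → accuracy → breeding → habitat → season, so logs are
deterministic even though the source applies the filters without
stating an order.  Deduplication keeps one presence per occupied cell
at the cell centre with the most recent record year (the source does
not state which record's year feeds per-year extraction; most-recent is
deterministic).

## Numerical and interface conventions

* Cells are 1-km squares in projected metres; point-in-cell uses floor
  arithmetic on `(x - origin_x)/cell_size` and
  `(origin_y - y)/cell_size` everywhere (row 1 at the top).  On exact
  top-edge coordinates this floor convention decides membership.
* Rasters are stored as ESRI ASCII grids — a plain-text single-band
  format with an explicit nodata value, readable by GDAL, QGIS and
  terra.  Tables are CSV; models and reports are JSON written at full
  (17 significant digit) precision so serialization round-trips are
  bit-exact.
* Every stochastic operation takes an explicit integer seed and
  restores the caller's RNG state, so pipeline reruns are byte-identical.
* Degenerate inputs fail loudly: 1x1 grids (no slope), empty year
  lists, all-zero sampling intensity, missing per-year temperature
  layers, missing predictor layers at projection, orphan protected-area
  ids, and zero-presence splits are all errors, not warnings.

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the
statistical assertions sharp while keeping a full run inside a few
minutes of CPU: ground-truth recovery on a 200 x 200-km landscape with
~2,400 presence cells and 10,000 background points over ten record
seeds; the virtual-species null check with 10,000 uniform records and
10,000 background points over ten seeds on a 50 x 50-km landscape;
omission calibration with ~2,000 presence cells split 3:1 into i.i.d.
partitions; and warming-response monotonicity across the four
condition anomalies on an 80 x 80-km landscape.  `scripts/acceptance.R`
re-runs the same computations from scratch and emits the headline
numbers as JSON.

## Known limitations

* Background buffering restricts the model's evidence to sampled
  environments; with dense occurrences the background distribution
  approaches the presence distribution and discrimination statistics
  (AUC/TSS) are structurally modest.  This is inherent to the design,
  not a defect.
* Permutation importance under correlated predictors divides credit;
  the tuning loop's variable dropping mitigates but does not eliminate
  this.
* The ad-hoc AICc is a model-selection heuristic on a non-standard
  likelihood; its small-sample correction treats nonzero coefficients
  as free parameters, which over-counts weakly-shrunk coefficients.
* Type-2/3 refugia identified at 1-km resolution say nothing about
  whether species can disperse to them; no connectivity modelling is
  included.
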