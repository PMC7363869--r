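---
title: "Hierarchical presence-only SDMs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical presence-only SDMs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it
implements: the two-tier model and its assumptions, every tunable
parameter that matters, what the virtual-species simulator does and
does not emulate, the numerical conventions, and the places where the
design was genuinely open and a choice had to be made.

## The model and its assumptions

Presence-only invasion data violate two assumptions of classical
distribution modelling. First, niche transferability: a species'
environment–occurrence relationship in the native range need not hold
where it was introduced. Second, pseudo-equilibrium: in the invaded
range an empty cell may be suitable but unreached, so background cells
are unreliable absences. The hierarchical design addresses both:

1. A **global, climate-only ensemble** is fitted on records from all
   ranges, deliberately maximizing the sampled climatic niche (the
   `certain_plus_NA` dataset variant keeps records whose coordinate
   uncertainty is unknown). Climate is assumed to be the sole
   constraint at this scale.
2. The global committee average `projG` (per cell, the fraction of
   selected members voting "suitable") re-weights the **regional**
   pseudo-absences through
   `Weight(p) = 1 / (1 + (p / (p − 1))²)` with `Weight(1) = 0`.
   The function equals 1 at `p = 0`, 0.5 at `p = 0.5`, is strictly
   decreasing on (0, 1), and satisfies the complement symmetry
   `Weight(p) + Weight(1 − p) = 1` (the squared odds of `p` and
   `1 − p` are reciprocal). A regional pseudo-absence therefore only
   counts as an absence to the degree the global model deems its cell
   climatically hostile — precisely the cells where "no record" is
   informative.
3. The **regional full-predictor ensemble** (climate plus habitat
   descriptors, `certain` records only, prioritizing coordinate
   precision) estimates the realized regional niche, not the
   fundamental one: its output is an environmental-suitability map
   conditional on the data available.

Weights enter every learner as multiplicative case weights in the
fitting criterion; presences always carry weight 1. Evaluation
(70/30 held-out splits, TSS) is deliberately **unweighted**: skill is
judged against the nominal presence/pseudo-absence labels, weighting
only expresses fitting-time confidence.

## Ensemble mechanics

Each tier fits `algorithms × nPaSets × nCvRuns` members (default
5 × 3 × 4 = 60). Learners: quadratic-polynomial logistic GLM; spline
GAM (`mgcv`, k = 5 per smoother); an FDA-style discriminant implemented
as weighted least squares of the class indicator on natural-spline
bases with a logistic calibration on the score (for two classes,
optimal scoring reduces to exactly this regression); gradient-boosted
trees (`xgboost`, depth 3, 1000 trees, shrinkage 0.01 by default); and
a regularized-logistic "maxent-like" learner on linear + squared
features (`glmnet`, lasso, fixed penalty 0.01). Equivalence with any
particular SDM toolbox's internals is a non-goal; the roster spans the
same model families.

Members with held-out TSS ≥ `tssMin` (default 0.7) enter the
committee; if none qualifies, the `ceiling(0.10 N)` best members do,
so an ensemble always exists. Each member votes with its own
TSS-maximizing cutoff; the committee average is the vote fraction
(values on the `k/N` lattice) and the per-cell coefficient of
variation of the votes (population sd / mean, 0 where the mean is 0),
rescaled by the map maximum, is the agreement map. The ensemble's own
binary map comes from re-optimizing TSS on the committee average
against the full presence/pseudo-absence data — optimizing on all data
rather than a held-out share is a deliberate choice (the cutoff is a
reporting convention, not a tuned parameter; a flag could expose the
held-out alternative).

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `cellSize` | 0.25 | degrees; ~30 km cell, matches coarse land-use data |
| `maxUncertaintyM` | 15,000 | m; inclusive coordinate-precision filter, ~cell circumradius |
| `vifThreshold` | 4 | stepwise VIF removal threshold |
| `nPseudoAbsences` | 20,000 global / 5,000 regional | cells per set |
| `nPaSets`, `nCvRuns` | 3, 4 | pseudo-absence sets, 70/30 repetitions |
| `tssMin`, `fallbackQuantile` | 0.7, 0.10 | member selection |
| `cutoffStep` | 0.01 | cutoff lattice resolution |
| `minPresences` | 30 | cells; below this a species is skipped |
| `cvThreshold` | 0.5 | zoning: central value of the CV range [0, 1] |
| `richnessThreshold` | `floor(nSpecies/2)` | zoning: central value of 0..nSpecies |
| `ignoranceHalfSaturation` | 1 | records/cell at which ignorance = 0.5 |

## What the simulator emulates — and what it does not

`generateEnvironment()` produces standardized Gaussian random fields
smoothed to a chosen autocorrelation range, tagged `climate`/`habitat`,
with optional planted near-duplicate layers (r > 0.99) so the VIF
screen has real work. `trueSuitability()` is a logistic
linear–quadratic response; with a prevalence target the intercept is
re-solved by bisection (tolerance 0.005 on mean suitability).
`sampleOccurrences()` draws cells with replacement proportionally to
suitability times an optional effort bias, places a uniform point in
the cell, attaches log-normal coordinate uncertainty (default log-mean
`log(5000)` m, log-sd 1 — chosen so a realistic minority of records
fails the 15,000 m filter), hides the uncertainty with a configurable
probability, and corrupts a configurable fraction of records into the
three cleanable error classes (zero coordinates, longitude = latitude,
exact duplicates), labelling them in a column the pipeline never
reads.

What this does **not** emulate: dispersal limitation and spread
dynamics (records are an i.i.d. draw given the truth), temporal
structure, taxonomic mislabelling, gazetteer-type errors at country
centroids or institutions (the cleaning step exposes a configurable
exclusion-point list instead of bundling gazetteers), and the
two-scale climate structure of real continents unless you build it in
(see the study scenarios below). Passing tests on these data therefore
demonstrate correctness of the machinery and recoverability under the
stated sampling model — not performance on any real species.

## Study scenarios and problem sizes

Two seeded scenarios are used by the test suite; both were fixed at
design time from first principles, not adjusted afterwards.

**Parameter recovery.** With presences drawn proportionally to
suitability, the achievable TSS is bounded by the overlap between the
presence distribution and the uniform background — a bound one can
compute by scoring cells with the *truth itself*. For a diffuse
one- or two-gradient logistic species that bound sits near 0.6: no
model, however good, should be asked to exceed it. A "strong signal"
scenario therefore has to be a climatically *restricted* species with
a steep envelope: four climate gradients with coefficients of
magnitude 2 and a prevalence of 0.10 on a 40 × 40 grid, 500 clean
records, two pseudo-absence sets of 1,000 cells. The "true suitable
area" used for overlap scoring is the truth map binarized under the
pipeline's own TSS-maximizing rule — necessary because a flat-topped
niche need not cross any fixed probability such as 0.5.

**Two-tier contraction.** The regional-range-contraction property
(regional suitable area smaller than the climate-only area) is not an
artefact of the machinery; it reflects a geometry in which the region
is climatically pre-suitable while the wider world spans large climate
contrast. The scenario builds exactly that: a wide world whose first
climate layer carries a longitudinal trend, a region at the favorable
end, and a species additionally constrained by two habitat layers the
global tier never sees. On a spatially homogeneous world the
inequality still holds in most replicates but is exposed to
committee-size and threshold noise.

Problem sizes throughout (40 × 40 to 48 × 96 grids, hundreds of
records, 10–60 members) are the package's demonstration scale: large
enough for every mechanism to operate, small enough that the whole
suite and the demonstration run complete in minutes on one CPU.

## Numerical choices and conventions

* **Grid**: half-open, lower-inclusive cells, row 1 at the southern
  edge; a boundary point belongs to the cell whose lower edge it
  touches. Aggregation to coarser grids is an unweighted mean of valid
  fine cells (no latitude weighting; downstream zoning is invariant to
  monotone aggregation choices at this scale), and a coarse cell is
  valid if any contributor is (avoids coastline loss).
* **Raster IO** is a plain-text grid format (header
  `n_rows n_cols min_lon min_lat cell_size nodata`, then the name and
  south-first rows at 17 significant digits, round-tripping to 1e-9).
  Binary geospatial formats are rejected with an explicit error.
* **Thresholds**: the uncertainty filter is inclusive (≤ 15,000 m);
  zoning "high" is strictly greater than the threshold, so the central
  values themselves classify as "low"; cutoff ties take the smallest
  cutoff.
* **VIF** is computed on raw (unstandardized) values — it is
  scale-invariant — over all valid cells of the modelling extent, once
  per tier before any fitting; ties on the maximal VIF remove the
  earliest column.
* **Standardization for learners** uses weighted means and standard
  deviations of the training rows (presence weight 1, pseudo-absence
  case weights), so zero-weight cases leave no trace anywhere in the
  fit — a property the tests check exactly.
* **Degenerate inputs**: a saturated global projection (`projG = 1`
  everywhere) zeroes all regional weights; the run warns and
  completes. An empty predicted range makes range filling `NA` rather
  than an error. Constant reference variables are skipped by MESS with
  a warning. Species under the presence minimum are skipped, not
  fatal.
* **Half-ignorance index**: of the "inverse of record count" family,
  the saturating form `h/(n+h)` is used — it is 1 at `n = 0` and, as
  the name requires, exactly 0.5 at the half-saturation count `h`
  (default 1 record per cell, configurable). Counts pool all reference
  groups by default; per-group maps are available. A min–max rescaled
  copy is kept alongside the raw index for cross-map comparability.
* **MESS** uses the species' presence-cell predictor values as the
  reference set (training conditions), the per-variable similarity
  branches on the percentage of reference values strictly below the
  target, and the cell value is the minimum over variables.
* **Seeds**: every stochastic stage derives its seed from the master
  seed via a documented polynomial hash of stage labels
  (`childSeed()`), making full runs bit-reproducible and every stage
  independently re-runnable.

## Known limitations

The learners are deliberately compact re-implementations of the model
families, not drop-in replacements for any specific SDM toolbox; the
committee's CV is computed on member *binaries* (votes), so it
measures agreement, not continuous spread; geographic distance in the
exclusion-point cleaner is haversine on a sphere; and the plain-grid
format stores no CRS beyond an identifier string. The pipeline runs
species sequentially — at the intended scale a loop is simpler and
reproducible, and parallel frameworks are out of scope.
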