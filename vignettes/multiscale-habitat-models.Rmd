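---
title: "Multi-scale habitat models and niche overlap: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale habitat models and niche overlap: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scalehab)
```

This vignette is the package's own account of the statistics it implements:
the model, its assumptions, the parameters that matter, what the synthetic
generator does and does not emulate, and the choices we made where the
methodology literature leaves the design open.

## The modelling problem

Habitat selection is scale-dependent: the covariate value *at* an occurrence
point is often less informative than its average over a neighbourhood, and the
best neighbourhood radius differs between covariates. The package therefore
models presence/absence as a random-forest classification on *scale-tagged*
features: every covariate enters as its circular focal mean at each radius of
a scale ladder, one radius is chosen per covariate by out-of-bag (OOB) error,
and a Model Improvement Ratio (MIR) pass prunes the multivariate model.

Random forests are used deliberately: they are non-parametric, tolerate many
correlated candidates, capture non-linear and interacting responses, and their
bagging structure yields the OOB error that drives both scale selection and
model comparison without a holdout set. The cost is that fitted responses are
piecewise-constant and noisy in data-sparse regions — see "Limitations".

Assumptions worth stating explicitly:

* coordinates are projected metres and distances Euclidean (no geodesic
  support);
* the response is binary presence / pseudo-absence with roughly balanced
  classes (pseudo-absence generation enforces balance by default);
* pseudo-absences are a background sample, so "suitability" is a relative
  vote fraction, not an occupancy probability.

## The estimator, stage by stage

**Occurrence preparation.** Spatial rarefaction is a greedy pass in input
order keeping each point only if at least `min_dist` (default 1,000 m) from
every point already kept. Greedy-in-input-order is a design choice: the
retention rule when point clusters admit several maximal subsets is not
determined by the distance criterion alone, and a deterministic rule makes
runs reproducible (a seeded random order is available). Thinning is
idempotent. Pseudo-absences start from `n_candidates` uniform points (default
500) and survivors must lie *strictly* farther than the buffer (default
500 m) from every presence; if more survive than the target (default: one per
presence, i.e. exact class balance — "approximately equal" resolved exactly,
which keeps OOB errors interpretable), a seeded subset is drawn, and too few
survivors is a hard error that names the achieved count.

**Focal means.** Windows are circular — a cell belongs to the window when its
*centre* lies within the radius of the focal cell's centre — matching the
"search radius" idiom of moving-window GIS tools; the inclusion rule is
stated because tool documentation rarely is. A radius of one cell size gives
the 5-cell plus window; a radius under half a cell is the identity. Edges
average the available cells only, and nodata cells are excluded (an
all-nodata window is nodata). The implementation is FFT convolution of the
zero-filled values and of the validity mask, with the count matrix rounded to
kill floating-point fuzz; it is exact to ~1e-15 against brute-force window
enumeration.

**Scale ladders.** The field ladder is 3,500–28,000 m in eight steps, with
line-density radii {1,000, 2,000, 3,000, 4,000} m — the 4,000 m rung is
included because density variables are used at it in practice even where the
narrative text stops at 3,000 m. The desk-scale default for the synthetic
landscape is 270–2,430 m (radii of 3–27 cells at 90 m), preserving the
~8-fold span of the field ladder while keeping windows small enough for quick
tests; both ladders are plain arguments.

**Scale optimization.** One univariate forest (500 trees, `mtry = 1`) per
variable per scale; minimum OOB error wins; exact ties break toward the
smaller scale (parsimony) and are flagged. OOB error is the proportion of
training points misclassified by majority vote of the trees not containing
them.

**Collinearity filter.** Iterative pairwise elimination: find the worst pair
over |r| = 0.50, drop its member with the larger mean absolute correlation,
repeat. This enforces the same post-condition as QR-decomposition-based
redundancy removal (all retained pairwise |r| ≤ 0.50) while being trivially
verifiable by brute force; the tests re-check the post-condition on every
output.

**MIR selection.** Permutation importance is the unscaled mean decrease in
OOB accuracy — the classification analogue of %IncMSE, chosen because the
response is binary and OOB class error is the currency of every other step.
MIR divides by the maximum importance (negatives floored at zero), so the top
variable is exactly 1. Thresholds 0.0–0.9 in 0.1 steps subset the variables;
the subsets are nested because MIR is always taken from the *original* full
model — recomputing importance after each drop invites overfitting drift
(recomputation per step deliberately not default). Winner: lowest OOB error,
then lowest maximum within-class error (the larger of the two class-specific
OOB rates), then fewest variables.

**Evaluation and binarization.** AUC is the rank statistic with midrank tie
correction (equivalent to brute-force pair counting with half credit for
ties); TSS is maximized over observed score thresholds with "suitable" meaning
score ≥ threshold. The default binarization threshold is the max-TSS
threshold on the training data: no threshold is canonical in the literature,
so the package picks a defensible one, reports it, and accepts overrides.
Honest training-set evaluation should use the fit's out-of-bag votes
(`fit$votes`), not resubstitution predictions, which are near-perfect by
construction.

**Scenario projection and change accounting.** Scenario layers replace their
raw counterparts, focal means are recomputed at each variable's fitted scale,
non-climate layers pass through untouched; a scenario identical to the
current layers reproduces the current surface bit-for-bit. Change accounting
classifies cells stable (1→1), gain (0→1), loss (1→0), never (0→0); areas are
cell counts times cell area (0.81 ha at 90 m); the identities
stable + loss = current and stable + gain = scenario hold exactly in counts.
All percentages are referenced to the *current* suitable area — this is the
convention that reproduces published stable/gain/loss percentage columns
exactly from their hectare columns. Net change is reported as
net% = (gain − loss)/current × 100; published "net %" columns that cannot be
reproduced under any stated convention are not imitated.

## Niche overlap in environmental space

The E-space is the plane of the first two principal components of the pooled,
standardized background environments; the density grid (default R = 100)
spans the pooled score range plus a 10% margin, and later scores outside it
are clamped with a warning. Occurrence and background densities are
product-Gaussian kernel estimates normalized to sum 1; the default bandwidth
is Scott's rule for two dimensions, n^(−1/6)·sd per axis, computed on the
pooled background scores — neither the grid size nor the bandwidth is
canonical in the niche-overlap literature, so both are stated and tunable.
Degenerate inputs are handled explicitly: spatially constant variables are
centred but not scaled, zero-width score ranges are padded, and bandwidths
are floored at a thousandth of the grid span, so a constant environment
yields a point-mass E-space instead of an error.

Overlap is Schoener's D = 1 − ½Σ|p₁ − p₂| and Warren's I =
1 − ½Σ(√p₁ − √p₂)²; I ≥ D always (the tests prove it on random surfaces).
The equivalency test pools and reshuffles occurrences preserving group
sizes; the background test rigidly translates species 2 with toroidal wrap
and re-extracts environments, with nodata-hitting translations redrawn (25
attempts, then an error). Both use p = (1 + k)/(reps + 1) — the +1 convention
keeps p in (0, 1] and makes p = 1 attainable, which matters because "no
translation changes anything" (a constant environment) must give exactly
p = 1. One tail each: equivalence is rejected when observed D is *small*
against the reshuffled null; background similarity is declared when observed
D is *large* against the shifted null. Default 199 replicates; seeds are
explicit arguments everywhere.

An isopleth at level q is defined as the smallest set of grid cells holding
1 − q of total mass (so the "5% isopleth" bounds 95% of the density); the
convention is inherited from kernel home-range practice but rarely written
down, hence stated here. PNTI is the fraction of the species' 5%-isopleth
boundary cells (region cells with a 4-neighbour outside the region) lying
outside the background's 10% isopleth region, classed low (< 0.15), moderate
(0.15–0.3), high (> 0.3). NECI is formalized as the Pearson correlation of
the two flattened background densities with a strict > 0.5 trigger for
prevalence correction; the index is described operationally rather than by
formula in the literature, so this definition is a documented stand-in.

## The synthetic generator: what it emulates, and what it does not

`gaussian_field()` smooths white noise with a Gaussian kernel on a torus and
re-standardizes, giving stationary fields with a controlled autocorrelation
length; `true_suitability()` is the logistic of a linear combination of focal
means at known "true" scales; presences sample cells proportional to
suitability with uniform within-cell jitter; `two_species_scenario()` gives
species 2 the coefficients `coef × (1 − δ)`, so δ = 0 duplicates species 1,
δ = 1 is an indifferent species, and δ = 2 places the optima at opposite
covariate extremes. All randomness descends from a master seed through fixed
arithmetic (`child_seed`), so every stage is independently reproducible and
whole scenarios are bitwise repeatable.

Default study conditions, chosen once and used by the tests:

* landscape 300 × 300 cells at 90 m (a 27 km reserve-sized square), four
  covariates of which two are influential (`bio1` +40 at 1,350 m, `forest`
  −30 at 810 m), intercept −3 so suitable habitat is a minority fraction of
  the landscape, as in real reserves;
* the scale-recovery condition uses a single influential covariate with a
  90 m correlation length and coefficient 200 at 1,350 m — the short
  correlation length is what makes focal means at neighbouring radii
  distinguishable, and the coefficient is set so the univariate forest at the
  true scale sits near 0.25–0.3 OOB error, a realistic signal strength
  (coefficients act on raw focal means, whose variance shrinks with window
  size — hence the large numerals);
* niche scenarios are analysed on the *habitat axes* (`truth_env_stack()`:
  focal means of the influential covariates at their true scales). Raw point
  values decorrelate from the focal means that actually drive occupancy, and
  a 2-PC projection of many incidental axes can lose the separation
  direction; analysing the axes the species select on makes the δ dial behave
  as designed (D ≈ 0.9 at δ = 0, ≈ 0.12 at δ = 2, monotone between).

The generator emulates the *statistical* structure the analysis assumes —
autocorrelated continuous covariates, scale-dependent selection, presence
sampling, divergent niches — and nothing else. It does not produce real
land-cover geometry (patches, roads, rivers as networks), seasonal NDVI
composites, realistic bioclim covariance, detection error, or dispersal
constraints. Passing tests therefore certify the machinery (scales are
recoverable, tests are calibrated, accounting is exact), not that any
particular field system satisfies the assumptions.

## Problem sizes and runtime

Tests and the acceptance script size simulations to what the statistics need:
scale recovery uses 20 replicates of the 300 × 300 landscape with 300
presences (the modal-scale criterion stabilizes well below that);
equivalency calibration and power use 40 replicates of 200 + 200 occurrences
with 199-permutation tests on a 150 × 150 landscape; overlap means use 10
replicates; the demo pipeline runs a 150 × 150 landscape with a five-step
ladder. The full suite runs in a few minutes on one core.

## Limitations

* Pseudo-absences make the vote fraction a relative index; calibrated
  occupancy probabilities would need a different design.
* Forest responses are not monotone even when the generating process is;
  in data-sparse covariate extremes the fitted response can dip, so scenario
  projections far outside the training range extrapolate leaf values.
* The OOB error of a forest is itself stochastic; exact invariance under
  non-linear monotone feature transforms holds only up to floating-point tie
  handling in the split search (linear maps are exactly invariant).
* E-space truncation (PNTI) is resolution-dependent at coarse grids; R ≥ 60
  is advisable before interpreting boundary fractions.
* One E-space, two dimensions: temporal niche axes and >2 components are out
  of scope.
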