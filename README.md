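# scalehab

Multi-scale random-forest habitat suitability models and environmental-space
niche overlap, for ecologists studying how sympatric species (the motivating
case: large felids sharing a reserve) select habitat across spatial scales and
how their ranges shift under climate scenarios.

Species respond to their environment at different spatial scales — a predator
may avoid settlements within a few kilometres while tracking forest cover over
tens of kilometres. Single-scale distribution models miss this. `scalehab`
implements the scale-explicit workflow end to end, and ships a
synthetic-landscape generator with known ground truth so every stage can be
validated without any GIS downloads.

## The method

Given presences and pseudo-absences with a stack of covariate rasters:

1. **Occurrence preparation.** Presences are spatially rarefied (greedy
   thinning at a minimum inter-point distance, default 1,000 m). Pseudo-absences
   are uniform random points, discarded within a 500 m buffer of any presence
   and subsampled to balance the classes.
2. **Multi-scale features.** Every covariate is summarised by its circular
   focal mean at each radius of a scale ladder (field default 3,500–28,000 m in
   eight steps; desk-scale default 270–2,430 m); linear features become line
   densities (length per unit neighbourhood area). Columns are named
   `var@scale`.
3. **Scale optimization.** For each variable, a univariate random forest is fit
   at every scale; the scale with minimum out-of-bag (OOB) misclassification
   error wins (ties to the smaller scale).
4. **Variable selection by Model Improvement Ratio.** After a collinearity
   filter (pairwise |r| ≤ 0.50), the multivariate forest's unscaled permutation
   importance is rescaled as MIR_i = imp_i / max(imp). Variables are subset at
   MIR thresholds 0.0, 0.1, …, 0.9 (always from the *original* model's
   importance), each subset refit, and the model with lowest OOB error (ties:
   lowest maximum within-class error, then fewest variables) is final.
5. **Prediction, evaluation, projection.** Suitability surfaces are ensemble
   vote fractions; models are scored by AUC (rank statistic with tie
   correction) and the True Skill Statistic TSS = sensitivity + specificity − 1
   maximized over thresholds; scenario climate layers replace their current
   counterparts (focal means recomputed at the fitted scales) and binary maps
   are compared cell-by-cell into stable / gain / loss areas, with the exact
   identities stable + loss = current and stable + gain = scenario.
6. **Niche overlap in E-space.** A PCA of pooled background environments spans
   a 2-D environmental space; kernel occurrence densities on an R×R grid give
   Schoener's D = 1 − ½Σ|p₁ − p₂| and Warren's I = 1 − ½Σ(√p₁ − √p₂)²; a
   pooling-and-reshuffling equivalency test and a toroidal-shift background
   test give one-tailed p-values; PNTI (the fraction of the species' 5%
   density isopleth boundary outside the background's 10% isopleth) measures
   niche truncation, and NECI (correlation of background densities) flags when
   prevalence correction is advisable.

The synthetic generator draws spatially autocorrelated Gaussian covariate
fields, builds a true suitability surface as a logistic function of focal
means at known scales, samples presences proportional to suitability, and can
offset a second species' coefficients by δ to dial niche divergence from
identical (δ = 0) to opposite extremes (δ = 2).

## Worked example

```r
library(scalehab)

## 1. a landscape with known ground truth (300 x 300 cells at 90 m)
truth <- landscape_truth(seed = 7)
raw   <- simulate_landscape(truth)
suit  <- true_suitability(raw, truth)

## 2. occurrences: presence sampling, 1,000 m rarefaction, buffered absences
occ  <- sample_occurrences(suit, 500, seed = 11)
occ  <- spatial_thin(occ, min_dist = 1000)
pa   <- generate_pseudo_absences(grd_extent(suit), occ, n_candidates = 6000,
                                 buffer = 500, seed = 12)
dat  <- assemble_dataset(occ, pa)

## 3. multi-scale features and the scale-optimized, MIR-selected forest
stack <- build_multiscale_stack(raw, truth$scales)
feats <- extract_features(stack, dat)
model <- msrf(feats, truth$scales, ntree = 500, seed = 13)
model
#> Multi-scale random forest habitat model
#>   4 base variable(s) scale-optimized over ladder {270, 540, 810, 1080, 1350, 1620, 1890, 2430} m
#>   final model: 2 variable(s), OOB error 0.2405
#>   MIR winner threshold: 0.1

## 4. evaluation (out-of-bag votes) and a +1 degree warming scenario
met <- evaluate_model(model$fit$votes, feats$presence)
met
#> AUC 0.8314 | TSS 0.5459 at threshold 0.2079 (sens 0.9676, spec 0.5784)
current <- predict_surface(model, stack)
future  <- project_scenario(model, raw,
                            list(bio1 = grd(raw$bio1$values + 1, 90)))
change_accounting(binarize(current, met$threshold),
                  binarize(future, met$threshold))
#> current 40834.53 ha -> scenario 65966.40 ha
#> stable 40073.94 ha (98.14%) | gain 25892.46 ha (63.41%) | loss 760.59 ha (1.86%)
#> net 25131.87 ha (61.55% of current)
```

The model recovers a compact variable set from the 32 scale-tagged candidates,
discriminates presences from background at AUC 0.83 on out-of-bag votes, and
— because the warmed layer (`bio1`) enters the truth with a positive
coefficient — warming expands the suitable area: 25,892 ha gained against 761
ha lost relative to the 40,835 ha currently suitable.

`run_pipeline()` drives the same stages from a single YAML configuration (see
`demo_config()`), persisting grids as ESRI ASCII rasters, tables as CSV and a
JSON run report. The niche module is exercised the same way:
`two_species_scenario()` → `build_espace()` → `equivalency_test()` /
`background_test()` / `pnti()` / `neci()`.

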