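---
title: "Methods: the ensdm ensemble habitat-modelling pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ensdm ensemble habitat-modelling pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the modelling protocol and its assumptions, the tunable parameters and
why their defaults are what they are, what the synthetic-landscape
generator does and does not emulate, and the numerical choices a
maintainer would otherwise have to reverse-engineer from the code.

## The modelling protocol

`ensdm` implements the classic ensemble species-distribution-modelling
(SDM) workflow for presence-only data on a gridded landscape:

1. **Thinning.** Presence records are reduced to at most one per raster
   cell (first record in input order wins). Records clustered within one
   cell are duplicates at the modelling resolution; keeping them inflates
   spatial autocorrelation and overfits the local neighbourhood. The
   thinning distance is the cell itself; a coarser, kilometre-based rule
   can be emulated by supplying a coarser grid.
2. **Pseudo-absences.** With no true absences, 1000 background points are
   drawn uniformly without replacement from unmasked cells not occupied
   by a presence and treated as absences by every learner. No exclusion
   buffer is applied by default (`min_distance_cells = 0`): a buffer
   assumes the species is absent near its records, which is exactly what
   the model is supposed to estimate. The count 1000 is the conventional
   background size for committee SDMs at this landscape size.
3. **Splits.** Four independent stratified 70/30 calibration/evaluation
   splits. The evaluation count per label is `round(0.3 n)` rounded half
   up, so small presence sets still contribute an evaluation point.
4. **Screening.** Covariates are screened by pairwise Pearson `|r| > 0.8`
   with greedy worst-pair-first elimination: the pair with the largest
   offending `|r|` is located and its lower-contribution member dropped,
   until no kept pair offends. Contributions come from permutation
   importance of a preliminary equal-weight committee fitted on all
   candidates. Contribution is used *only* relationally — to decide which
   member of a pair survives — never as an absolute cutoff, because no
   defensible universal cutoff exists. When exact ties occur among worst
   pairs, the globally lowest-contribution candidate is dropped first
   (then lexicographically later names), making the procedure
   deterministic and order-invariant. Flat-aspect sentinel values (−1)
   are set to missing before correlation: a circular variable's sentinel
   would otherwise manufacture correlation.
5. **The committee.** Nine learners behind one fit/predict contract
   (probabilities in [0, 1], variables matched by name):
   GLM (binomial, linear + quadratic), CTA (depth-limited `rpart` tree),
   RF (500 trees), GBM (gradient boosting, 2500 trees, depth 3, learning
   rate 0.01 — the conventional committee defaults), ANN (single hidden
   layer of 5, weight decay 0.01, standardised inputs), FDA (linear
   discriminant on the quadratic basis), MARS (an in-package
   forward-selection hinge-basis learner, degree 2, with a
   ridge-penalised logistic final fit — the light ridge keeps
   coefficients finite when the basis separates the classes), a
   MaxEnt-style learner (L1-penalised logistic regression on linear +
   quadratic + pairwise-product features, λ by internal 5-fold CV), and
   SRE (the surface range envelope: per-variable [q, 1−q] presence
   quantiles, q = 0.025, linear-interpolation quantiles; suitable iff
   inside every envelope). A GAM is deliberately absent from the
   committee. All fits are deterministic given the model seed.
6. **Evaluation.** Per model × repeat: AUC as the tie-aware rank
   statistic (identical to the trapezoidal ROC integral, but
   unambiguous), and KAPPA/TSS at the max-TSS threshold of that repeat's
   evaluation scores. The threshold search evaluates every midpoint
   between adjacent distinct scores plus the endpoints {0, 1}; ties go to
   the smallest threshold. Reporting KAPPA and TSS at max-TSS rather than
   at 0.5 is declared in all outputs. A learner that fails to fit yields
   a record flagged `failed` — the committee continues without it, and
   its ensemble weight is zero.
7. **Ensemble.** Weights are the mean TSS per model across repeats
   (configurable to AUC or KAPPA; negative means floored at 0; members
   below `inclusion_cutoff`, default 0, excluded). One refit per model on
   the full data provides the projected members — a 9-member committee of
   full models rather than a 36-member committee of split models, for
   parsimony and stabler maps. The combined prediction is
   `Σ Wᵢ Pᵢ / Σ Wᵢ`, a convex combination.
8. **Projection and binarisation.** The ensemble is projected onto any
   period stack carrying the same layer names; no recalibration. Binary
   maps use the max-TSS threshold of the *pooled* per-repeat evaluation
   scores, combined with the ensemble weights — the standard companion
   rule when no explicit binarisation threshold is prescribed.
9. **Classification and areas.** Each period's suitability map is cut
   into four classes (no/low/medium/high) by exact Fisher–Jenks natural
   breaks (the dynamic program, not the heuristic), computed per period
   by default (`breaks_from = "current"` applies the current-period
   breaks everywhere instead). Class intervals are left-open at breaks: a
   cell's class is the number of breaks strictly below its value. Cell
   areas use the spherical formula
   `R² Δλ (sin φtop − sin φbottom)`, R = 6371.0088 km everywhere.
10. **Land use.** Suitability classes are cross-tabulated against a
    categorical land-use raster; for the correlation analysis the study
    area is tiled into 10 × 10-cell blocks, each contributing one
    (land-use area, suitable-habitat area) pair per land-use class, where
    "suitable" pools classes 1–3. Per class: OLS fit, Pearson r,
    `R² = 1 − SSres/SStot`, and the two-sided t-test p-value on n − 2
    degrees of freedom. The tile is the analysis unit because a
    correlation needs replicated spatial units; its size is configurable
    and recorded in the manifest.
11. **Centroids.** The distribution centre of each period's binary map is
    the area-weighted mean of presence-cell centres (longitudes averaged
    arithmetically — valid for study areas far narrower than 180°), with
    haversine step distances and forward azimuths between consecutive
    periods.

## Raster model and formats

Rasters are north-up WGS84 grids of square cells, row 0 at the top,
half-open cells (`[x, x + cellsize)`), 0-based indices. Rasters are read
and written as ESRI ASCII grids (`.asc`), written with 17 significant
digits so write/read round trips are exact; the NoData sentinel on write
is −9999. No resampling is performed anywhere: all layers of a stack must
share one geometry exactly, which keeps area accounting exact and
surfaces data errors early. Slope and aspect derive from elevation by
Horn's 3×3 weighted finite differences — the default of mainstream GIS
software — with degree-to-metre conversion at each cell's latitude
(111320 m per degree, scaled by cos φ in longitude); aspect is degrees
clockwise from north in [0, 360), with −1 as the flat sentinel.

## The synthetic-landscape generator

The generator defines the study conditions under which the pipeline is
validated. Covariates are Gaussian random fields: white noise smoothed by
circular FFT convolution with a Gaussian kernel (sd = the autocorrelation
length, 8 cells by default; lengths ≤ 1 mean unsmoothed noise), exactly
standardised to mean 0, sd 1. True suitability is an inverse-logit of
unimodal (Gaussian-bump) or logistic terms on a chosen subset of
covariates. The default scenario is a 100 × 100 grid at 2.5-arcmin
resolution with six covariates, two of them informative — bumps at +1 and
−1 sd with widths 0.3 and 0.36 and gains 10 over an intercept of −11 —
and 150 presences drawn without replacement with probability proportional
to suitability. These response parameters were chosen so the virtual
species has a genuinely restricted niche: mean landscape suitability
(prevalence) is ≈ 8%, typical of a montane specialist, rather than a
diffuse surface a model could neither learn nor fail on. Land use is a
nine-class multinomial per cell whose grassland probability is lifted by
`0.5 × suitability` over a grassland-dominated base composition (sum of
base rates 1; the lift is renormalised against the other classes), so a
positive habitat–grassland association exists by construction when the
coupling is on and vanishes when it is 0.

What the generator does *not* emulate: realistic topography, anisotropy,
covariate cross-correlation, observation bias in the presences, and real
paleo/future GCM deltas (the `shift_stack()` helper applies uniform
offsets only). Passing recovery tests therefore demonstrates that the
pipeline recovers a knowable niche under clean sampling — not that any
particular real-world map is correct.

## Numerical choices

- Quantiles are linear-interpolation (type 7) everywhere (SRE envelopes,
  Jenks binning).
- Fisher–Jenks is the exact weighted dynamic program on distinct values;
  above 2048 distinct values the data are first condensed onto 2048
  weighted quantile bins and the program run exactly on the bins
  (classification of 10⁴-cell maps would otherwise be quadratic in the
  number of distinct values). Returned breaks are class maxima.
- The max-TSS scan is exact, not a grid: TSS is piecewise constant
  between adjacent distinct scores, so midpoints plus endpoints cover all
  achievable values.
- Permutation importance is `mean(1 − cor(pred, pred_shuffled))` over 3
  shuffles, clamped to [0, 1]; constant predictions define importance 0
  (no dependence is measurable).
- Response curves use the evaluation-strip convention: one variable swept
  over its unmasked range in 100 steps, all others fixed at their
  unmasked means; the favourable range is where ensemble suitability
  exceeds 0.5; ties at the optimum go to the smallest value.
- All randomness flows from one root seed, expanded into named sub-seed
  streams (pseudo-absences, splits, per-model fits, shuffles) recorded in
  the run manifest; reruns are bit-identical. Note that the *column
  order* of covariates can perturb iterative learners at the
  10⁻¹⁰-relative level, so runs from in-memory stacks and from on-disk
  stacks (alphabetical layer order) agree to numerical noise rather than
  bitwise.

## Scope decisions

- The GeoTIFF dialect is declared in the raster interface but not
  implemented; ESRI ASCII grid is the supported interchange format. The
  format is plain text, diffable, and sufficient for single-band
  suitability and class maps.
- Committee weighting defaults to TSS with cutoff 0; both are
  configuration, and every choice is logged in the manifest.
- Natural breaks are computed per period by default so each period's map
  uses its own optimal classification; fixing the current-period breaks
  across periods (for strict cross-period comparability of class
  definitions) is one configuration flag away.
- One species per run; a wrapper loop handles multiple species.

## Validation problem sizes

The test suite validates metric, threshold, classification and geodesy
code against brute-force oracles (hundreds of random instances each), and
runs the full protocol end-to-end on the default 100 × 100 scenario: one
structural run (36 evaluation records, per-period four-class maps,
bit-identical rerun) and a ten-landscape parameter-recovery experiment
(held-out ensemble AUC, importance ranking of informative versus noise
covariates, response-curve optimum recovery within 10% of the variable
range, and presence/absence of the grassland association under coupled
and uncoupled land use). Committee-level unit tests use 40 × 40
landscapes with reduced committees; those sizes are a deliberate
trade-off between statistical resolution and a test suite that runs in a
couple of minutes.

## Known limitations

- Geographic (unprojected) WGS84 grids only; no reprojection or
  resampling.
- Pseudo-absence and split designs are uniform-random; biased background
  sampling (target-group, environmental stratification) is out of scope.
- The SRE member is intentionally primitive (a rectilinear envelope with
  binary output) — it anchors the committee's low end, as envelope models
  historically do.
- Permutation importance with 3 shuffles is noisy for near-tied
  variables; raise `n_shuffles` when ranking matters at fine resolution.
- The land-use correlation treats tiles as independent samples; spatial
  autocorrelation between tiles will anti-conservatively shrink p-values
  on strongly autocorrelated landscapes.
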