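---
title: "Ensemble habitat-suitability modelling for deep-sea taxa: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble habitat-suitability modelling for deep-sea taxa: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Cold-water corals and many commercially fished demersal species live on
continental margins and seamounts where the ocean is warming,
acidifying, losing oxygen and receiving less export production from the
surface. Only presence records exist for most of these taxa, so the
standard tool is presence-background habitat-suitability modelling
(SDM/HSM): fit the environmental niche from occurrences against
artificially generated pseudo-absences, predict a habitat suitability
index (HSI) over the seafloor, project the same niche onto future
environmental fields, and compare binary range maps between periods.

`bathyniche` implements that workflow end to end as a seeded, testable
pipeline. Because the real inputs (occurrence databases, bathymetry
mosaics, earth-system-model fields) cannot ship with a package, a
first-class synthetic-ocean module generates worlds with the same
statistical structure — a shelf/slope/abyss bathymetry, depth-coupled
covariates, a known ground-truth niche, and a future scenario — so
every stage can be verified against a known answer.

# Environmental layers

* **POC flux to the seafloor.** Export particulate organic carbon at
  100 m (`epc100`, mg C m^-2^ day^-1^) is attenuated to the seafloor
  with the Martin power law `epc = epc100 * (depth / 100)^-0.858`.
  Cells shallower than the export depth are evaluated by the same
  formula (no clamping): the power law is the definition used, and
  shallow cells are rarely in the modelled domain.
* **Saturation states.** Aragonite and calcite saturation (Ω) are the
  ratio of the bottom-water carbonate ion concentration to its
  concentration at equilibrium with the mineral; Ω = 1 marks the
  saturation horizon, Ω < 1 is corrosive.
* **Terrain.** Slope uses the Horn 3×3 finite-difference stencil (the
  de-facto GIS standard; the field's tools do not document an
  alternative). The bathymetric position index (BPI) is the elevation
  of a cell minus the mean elevation over an annulus (default inner
  radius 3 cells, outer 25), z-scored over the ocean mask; positive
  values are crests (Benthic Terrain Modeler sign convention). Edge
  cells use the annulus truncated at the border rather than NA — at
  3-km resolution the bias is negligible relative to the z-scoring.
* **Downscaling.** Coarse climate fields are brought to the 3×3 km
  grid by a linear drift on depth plus ordinary kriging of the
  residuals with an exponential variogram (nugget 0), which makes the
  interpolator exact at the coarse samples. When the variogram fit is
  degenerate (constant residuals, too few bins) the residual surface
  falls back to inverse-distance weighting and says so; the drift
  regression is unaffected. Layer validation reports RMSE plus an
  "adjusted R" read as the signed square root of the adjusted R² of a
  linear fit of observed on modelled; a plain-correlation variant is
  available behind the same interface because the field's reporting
  convention is ambiguous.

# Occurrence quality control

Records from aggregated databases (OBIS, NOAA) are rejected when they
carry no depth, or when the reported depth differs from the bathymetry
by **both** more than 30% (relative to the raster depth, which is taken
as the reference standard) **and** more than 50 m. Records from a VME
database are rejected when their positional error exceeds 5,000 m (the
natural reading of the accuracy rule: coarse positions are excluded);
institutional records are treated as accurate. Surviving records
collapse to one presence per 3-km cell, with provenance kept by the
priority institutional > NOAA > OBIS > ICES. The two filters have
disjoint source scopes, so their order is irrelevant; both emit
machine-readable rejection reasons.

# Pseudo-absence generation

Three steps, mirroring the environmental-profiling approach used for
deep-sea SDMs:

1. **Profiling.** A per-covariate quantile box (central 95% of presence
   covariate values) describes the presence environmental envelope —
   a transparent, testable stand-in for a one-class support estimator
   (an optional hook keeps the two behind the same contract). The
   region eligible for pseudo-absences is the ocean **outside** this
   envelope: artificial absences belong where the environment is
   demonstrably unlike occupied habitat. (The package also implements
   the inverted semantics — background restricted to the envelope — as
   `mode = "include"`; in our experiments that choice removes nearly
   all presence/background contrast and no model family can recover
   the niche from it, which is why it is not the default.)
2. **Buffering.** No pseudo-absence may fall within 6 km (planar
   distance on the equal-area grid; the buffer metric is unstated in
   the field's descriptions, and at 6 km the planar/great-circle
   difference is far below cell size) of any presence cell centre.
3. **Depth stratification.** Candidates are subsampled so their depth
   histogram matches the presence histogram: 250-m strata spanning the
   central (10th–90th percentile) occupied depth range with open-ended
   tail strata, per-stratum quotas integerised by the largest-remainder
   rule (totals exact), uniform sampling within strata. Open tails
   matter: the rare deepest/shallowest presences otherwise define
   strata in which no environmentally dissimilar candidate can exist,
   making the quota infeasible. Group defaults are 10,000
   pseudo-absences for corals and 100,000 for fishes.

The per-species stratification is self-contained; stratifying to a
pooled multi-species depth distribution (as multi-species studies do)
is available by passing explicit stratum edges.

# Model families

All three families share one `fit/predict` contract and emit HSI in
[0, 1]; the ensemble layer cannot tell them apart except by metadata.

* **Maximum entropy** is realised as an L1-regularised
  presence-background model over linear, quadratic and hinge features
  (4 hinge knots per covariate at training quantiles, forward and
  reverse), with the penalty chosen by internal 5-fold
  cross-validation and covariates clamped to their training range at
  prediction. The logistic output is
  `tau*exp(eta)/(1 - tau + tau*exp(eta))` with `eta` centred on the
  training presences and prevalence `tau = n_presence / n_pseudo-absence`.
* **GAM**: binomial errors, logit link, one thin-plate smooth per
  covariate with basis dimension 4 (3 for temperature and saturation
  states in coral models, where monotone-ish responses need little
  flexibility). Covariate subsets are chosen by exhaustive AIC up to 8
  candidates (2^8 fits), beyond which a forward-backward search takes
  over — the all-subsets approach is factorial and 8 is where it stops
  being the cheaper option.
* **Random forest**: classification forest, 500 trees,
  `mtry = floor(sqrt(p))`, no class weighting; HSI is the
  presence-class vote fraction.

# Evaluation

The study area is split into four contiguous rectangles holding similar
numbers of training points (median split on latitude, then per-half
median splits on longitude). Each of 10 iterations draws one block as
the test area (uniform draws with replacement — "random selection"
reads most naturally as independent draws), trains on an 80% subsample
of the rest, evaluates AUC (tie-aware Mann–Whitney form), kappa,
sensitivity, specificity and TSS on an 80% subsample of the test block,
and reports means ± sd. Binarization thresholds are computed on the
*training* data of each iteration: the 10th-percentile
training-presence threshold (P10; type-7 linear interpolation between
order statistics, so training sensitivity is 0.90 by construction for
distinct scores) and the maximum-sensitivity-plus-specificity threshold
(MSS; candidate thresholds at midpoints of adjacent distinct scores,
ties resolved to the lowest). Computing MSS on training rather than
test data keeps the threshold honest — it is part of the fitted model,
not of the evaluation. Accuracy classes (good/moderate/poor) follow
the conventional AUC/TSS cut-offs, resolved pessimistically when the
two metrics disagree.

# Ensemble, importance, uncertainty

Family weights are proportional to `(AUC + TSS)/2` from the blocked CV,
with TSS taken at the MSS threshold (TSS is threshold-dependent; the
MSS threshold is the one designed to represent overall skill). The
weighting formula is isolated in one function so AUC-only or TSS-only
variants are switchable. The ensemble HSI is the per-cell convex
combination; cells missing in any family are missing in the ensemble.

Variable importance is `1 - Pearson correlation` between original
predictions and predictions after permuting one covariate, averaged
over 10 permutations, then weight-averaged across families; a covariate
a model does not use scores exactly 0. Per-cell uncertainty is the
coefficient of variation over 100 bootstrap refits (rows resampled with
replacement, stratified by label so no replicate loses a class), with
family CV grids weight-averaged — averaging CVs rather than pooling
bootstrap maps, which is the natural reading of a per-model-then-
ensemble procedure.

# Projection and change maps

Both thresholds are always computed and reported side by side. A cell
is suitable iff `HSI >= threshold` (ties included — the threshold is
defined as a value attained by data). Change categories partition the
defined cells into loss / gain / refugia (suitable in both periods,
sensu climate-refugia usage) / never; areas are cell counts × 9 km²,
and the identities `A_present = A_loss + A_refugia` and
`A_future = A_gain + A_refugia` are asserted on every run. Median
latitude and depth are unweighted medians over suitable cell centres.

# The synthetic ocean

`build_world()` generates, from one seed: a margin bathymetry (land
strip, shelf < 200 m, slope, abyssal plain > 2,000 m, multiplied by
smoothed random relief); bottom temperature decreasing with depth with
a poleward gradient and mesoscale noise; export POC with latitudinal
and regional patchiness; aragonite and calcite saturation declining
with depth (horizons near 1,500 m and 3,000 m) and tightly
rank-correlated with depth (|ρ| > 0.85, so that collinearity screening
excludes depth for coral models exactly as in real carbonate systems);
and dissolved oxygen with a mid-depth minimum. Spatial autocorrelation
comes from Gaussian-filtered white noise with a configurable kernel.
Latitude is affine in the row index — adequate for median-latitude
summaries, nothing more.

Two calibration points matter and were chosen up front. First,
covariates need genuine variation *within* a depth band (as real water
masses provide): with depth-deterministic covariates the environmental
envelope degenerates to a depth band, leaving no contrast for the
models and no environmentally dissimilar cells at presence depths for
the stratified background. Second, the domain must be much larger than
the buffered presence set, because the pseudo-absence count is fixed at
10,000: the default world is 480×480 cells (~2 × 10^6 km², a small
fraction of the real North Atlantic's cell count but in the same
regime) with 300 occurrence records. Niche-recovery experiments use a
200×200 world with 1,000 presence cells and 2,000 single-stratum
pseudo-absences, where the stratified 10,000-point quota would be
geometrically infeasible under the 6-km buffer.

The default future delta applies +2 °C warming tapering with depth, a
25% carbonate-ion decline (shoaling both horizons), a 45% decline in
export POC (the midpoint of the 40–55% range projected under
business-as-usual forcing), and a 15 µmol/kg oxygen decline.

The generator reproduces the statistical structure the pipeline needs,
not ocean physics: no advection, no real coastlines, no
eddy-resolving fields, and corruption of records is injected by
construction rather than by observation processes. Passing tests on
this world show the pipeline's operations are correct and that known
niches are recoverable under realistic covariate collinearity; they do
not validate any particular real-species projection.

# Numerical choices and degenerate inputs

* Stage-scoped seeds: every stochastic stage derives its stream from
  `hash(master seed, stage name)`, so inserting a stage does not
  perturb later ones and a single seed reproduces a whole run.
* Z-scored BPI asserts mean 0 ± 1e-6 and sd 1 ± 1e-6 on the mask; a
  flat field is an explicit error rather than a NaN map.
* Perfect collinearity in VIF returns an `Inf` sentinel, not a crash.
* Ties in AUC get half-credit; constant scores give AUC 0.5.
* P10 with tied scores returns the tied value (sensitivity 1).
* Iterations whose test block lacks a class are skipped and logged;
  more than 5 skips abort the run.
* Bootstrap cells with mean HSI below 1e-6 report missing CV rather
  than dividing by ~0.

# Problem sizes

The shipped tests and the acceptance script run at desk scale chosen to
exercise every code path with comfortable statistical margins: worlds
from 60×60 (unit tests) through 200×200 (recovery and null-control
runs, 1,000 presences) to 480×480 (background-generation defaults);
blocked CV at 10 iterations; bootstrap checks at B = 15. The full
default configuration (480×480, three families, 10 CV iterations,
importance at 10 permutations) completes in minutes on one core.

# Known limitations

* The one-class profiling step is a quantile box, not a fitted
  one-class SVM; box profiling ignores covariate interactions in the
  envelope shape.
* The kriging downscaler fits a single global variogram; no
  anisotropy, no local neighbourhoods, dense solves only (fine for
  hundreds of coarse samples, not for tens of thousands).
* Pipeline presets run one species per call; pooled multi-species
  depth stratification requires explicit stratum edges.
* ASCII-grid I/O carries no projection metadata beyond the planar
  origin/cell size; consumers must know the frame.
* The fish-group default of 100,000 pseudo-absences assumes a domain
  large enough to hold them; desk-scale worlds should scale it down.
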