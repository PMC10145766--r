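---
title: "Ensemble distribution modeling and range-shift projection: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble distribution modeling and range-shift projection: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`cordsdm` implements a complete presence-only species distribution modeling
(SDM) workflow of the kind used to project climate-driven range shifts for
habitat specialists such as stream-dwelling *Cordulegaster* dragonflies:
occurrence curation and spatial thinning, predictor preparation and
collinearity filtering, pseudoabsence ensemble modeling, ROC-gated
ensembling, maximized-TSS binarization, and loss/stable/gain and
elevational-shift accounting between present and future climate surfaces.
Because real occurrence databases and WorldClim/CMIP5 rasters cannot ship
with a package, the pipeline is validated end-to-end on seeded virtual
species: simulated landscapes whose true suitability surface is known
exactly, so recovery can be measured rather than assumed.

# The modeling procedure

## Occurrence curation

Records carry a positional uncertainty in km. The accuracy filter keeps
records with uncertainty strictly below a bound (default 5 km); records with
unknown uncertainty are dropped in the default strict mode, since a record
that cannot demonstrate its accuracy fails the requirement. Spatial thinning
then enforces a minimum nearest-neighbor distance (default 10 km, 1000
randomized passes): each pass greedily accepts records in a random order,
and the largest accepted subset across passes is returned (first attained on
ties). Distances are great-circle (haversine) km — planar degrees would
distort the 10 km rule with latitude. Records are canonically sorted before
the seeded permutations, so the result does not depend on input row order.
For small inputs the randomized greedy provably attains the exhaustive
maximum-subset optimum; the test suite checks this against full enumeration
up to n = 12.

The study area is the union of disks of radius `buffer_deg` (default 2.5
decimal degrees) around the retained presences, rasterized on the analysis
grid. The buffer is deliberately planar-degree, mirroring the common
buffer-on-unprojected-coordinates GIS workflow; the metric distortion this
implies is accepted and documented rather than hidden.

## Predictors

Layers are aligned to a template grid by bilinear resampling, slope (in
degrees) is derived from elevation with Horn's 3×3 method (degree spacing
converted to meters at 111,320 m/° latitude, scaled by cos(latitude) in
longitude; edge cells and any cell whose window touches nodata are nodata),
and the stack is cropped and masked to the study area.

Collinearity is handled in two steps on a seeded sample of at most 10,000
valid cells (diagnostics on a sample of that size are statistically
indistinguishable from the full grid and keep the cost flat):

* **VIF**: `VIF_j = 1/(1 - R²_j)` from regressing each layer on the others;
  perfect collinearity is reported as infinite, never silently dropped.
* **Pairwise filter**: while any pair has `|r| ≥ 0.8` (Pearson), the member
  of the worst pair with the higher mean absolute correlation against the
  remaining variables is dropped. The published workflows perform the final
  choice among correlated variables by expert judgement; the package
  automates the tie with the mean-|r| rule and exposes a `keep_list` for the
  expert override (a protected variable's partner is dropped instead). The
  maximum remaining pairwise |r| is always reported, and by construction is
  below the threshold.

Candidate future climate surfaces (one per general circulation model, GCM)
are ranked by computing each candidate's study-area mean change in two
indicator variables, taking the across-candidate mean as the ensemble point,
and selecting the k candidates closest to it in Euclidean distance. Raw
units are the default; a z-scored mode is provided but off, because the
published tool's behavior is not documented on this point and the indicator
pairs used in practice are of comparable magnitude.

## Pseudoabsence ensemble modeling

True absences are unavailable for presence-only data, so each model
contrasts the presences against 5000 pseudoabsences drawn uniformly (without
replacement, presence cells excluded) from the study area; five independent
pseudoabsence sets times ten replicate 70/30 splits give 50 model runs.
Rows are weighted so each class contributes equal summed weight (prevalence
0.5, the ensemble-platform convention), and the split is stratified by class
so both partitions always contain both classes (the platform literature does
not state stratification; it is assumed here because an unstratified split
can produce a one-class test partition at low prevalence, which makes ROC
evaluation undefined).

Algorithms implemented behind one fitting contract: weighted binomial GLM,
gradient-boosted trees (GBM; defaults 2500 trees, depth 7, learning rate
0.001, bag fraction 0.5), probability random forest (RF; 500 trees), and a
single-hidden-layer neural network (ANN) as an optional plug-in. A MARS
plug-in is not included. Defaults mirror the conventional platform settings
and are overridable; tests and the bundled validation use reduced tree
counts. A pre-selection stage fits a few replicates per candidate algorithm
and carries the best mean held-out AUC forward.

## Evaluation, ensembling and binarization

* **AUC** is computed by the rank statistic, identical to the fraction of
  concordant presence/absence score pairs with ties counting one half.
* **MTSS** (maximized TSS threshold) scans the midpoints of consecutive
  sorted unique scores plus 0 and 1 — exact and scale-free, unlike a fixed
  lattice — with `score ≥ threshold` counting positive; the lowest
  maximizing threshold is taken on ties.
* The **ensemble** is the unweighted per-cell mean of the maps whose test
  AUC exceeds 0.8; the count of contributing models is reported.
* The ensemble's binarization threshold is a single MTSS computed from the
  pooled held-out partitions scored by the gated ensemble. The published
  description does not say whether thresholds are per model or per ensemble;
  per-ensemble matches the platform's ensemble workflow and avoids mixing
  thresholds fitted to different models.

## Range change and elevational shift

Per-GCM future binary maps within one scenario are averaged and
re-binarized at 0.5, ties counting as suitable (the majority rule for three
members). Transitions between the present and combined future binary maps
are counted as loss (1→0), stable (1→1), gain (0→1) and never (0→0), which
partition the valid cells, and

```
pct_loss   = 100 · loss / (loss + stable)
pct_gain   = 100 · gain / (loss + stable)
pct_change = pct_gain − pct_loss
```

reported to one decimal, rounding half away from zero (matching published
table formatting). The elevational summary extracts the elevation of cells
suitable in the present map and of cells suitable in the future map (stable
plus gain), reports means and quartiles, and defines the shift as the
difference of means.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
without claiming to reproduce any real climatology:

* **Layers**: smooth latent fields are built by Gaussian-kernel smoothing of
  white noise (kernel width = the autocorrelation range, in cells), chosen
  over spectral synthesis for simplicity and light dependencies. The fields
  are orthonormalized, so the configured loading matrix fixes the
  inter-layer correlations *exactly* (the empirical correlation of two
  layers equals the cosine of their loading rows); a lapse-rate-style
  coupling weight ties chosen layers to the standardized elevation pattern.
  Each layer is rescaled to a configured mean and standard deviation.
* **Elevation** is a deterministic east/north planar gradient plus a smooth
  random roughness component, so slope is nontrivial yet analytically
  checkable on the gradient part.
* **Virtual species**: suitability is a product of independent Gaussian
  responses, `S(x) = Π_v exp(−(E_v(x) − μ_v)² / 2σ_v²)`; presences are
  sampled with probability proportional to suitability (or by Bernoulli
  acceptance), at cell centers, seeded.
* **Futures** add a per-layer climate delta plus a smooth per-GCM deviation
  field — smooth rather than white, to mimic coherent disagreement between
  circulation models. Topography is never shifted.

The bundled demonstration landscape is 100×100 cells (0.05°) with six
bioclim-like layers — three the demo species responds to, three pure decoys
— a temperature layer strongly anticorrelated with elevation (|r| ≈ 0.87,
deliberately above the 0.8 filter threshold so the collinearity stage is
exercised), and niche breadths around half a layer standard deviation, a
specialist's niche consistent with the high model skill reported for real
montane habitat specialists. The two bundled scenarios move the thermal
optimum upslope while contracting the envelope (warming) and expand it
(mild cooling plus wetting); their effect on the *true* envelope is part of
the test suite, so the directional checks compare the model against a known
ground truth.

What the generator does **not** emulate: sampling bias beyond suitability
weighting, spatially clustered recording effort, non-Gaussian or
interacting niche responses, temporal disequilibrium, and real-world
covariance among nineteen bioclim variables. Passing the recovery tests
therefore demonstrates that the machinery is correct and self-consistent —
not that any particular real-data analysis is right.

# Validation conditions and problem sizes

The niche-recovery fixture runs the full pipeline on the demonstration
landscape with 300 presences, 10 km/50-iteration thinning, a 1.0° buffer,
2000 pseudoabsences × 2 sets × 3 replicates, and 150-tree random forests —
sizes chosen so the whole suite exercises every stage at meaningful scale
while remaining quick to run. Recovery is measured as the Spearman
correlation between the ensemble suitability map and the true suitability
over valid cells, mean held-out AUC, and the requirement that every
informative variable outranks every decoy in averaged permutation
importance (importance = `1 − max(0, r)` between predictions before and
after shuffling one column; the clamp at zero guards against pathological
negative correlations). A separate accounting run uses the published design
exactly — 5 pseudoabsence sets × 10 replicates = 50 models at 5000
pseudoabsences — with fast boosted trees, to verify run-count and
gate-count bookkeeping at full design size. The pipeline artifact test uses
a 40×40 landscape with 2×3 GLM runs.

# Numerical choices and degenerate inputs

* Strict inequality for the accuracy bound; missing uncertainty fails
  strict mode.
* Thinning tie-break: first subset attaining the maximum size, fixed by the
  seed; duplicate coordinates are resolved by thinning itself (distance 0,
  one survivor).
* Binarization uses inclusive `≥`; the majority combination counts exact
  0.5 ties as suitable.
* Constant predictors produce a warning, not an error; a model with
  zero-variance predictions gets importance 0 with a warning.
* All-nodata and one-class partitions raise immediate errors naming the
  violated contract.
* Every stage draws its seed as a deterministic 31-bit hash of the master
  seed and a stage label; the pipeline log records each one.

# Known limitations

Geographic (lat/lon) grids only — no projected CRS support; rasters are
exchanged as plain-text ESRI ASCII grids; no dispersal constraint is applied
to future projections (the unlimited-dispersal assumption); MaxEnt and
spatial block cross-validation are out of scope.
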