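---
title: "Methods: balanced-forest distribution models for prairie-pothole waterbirds"
author: "prairieSDM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: balanced-forest distribution models for prairie-pothole waterbirds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prairieSDM)
```

## The problem

Prairie-pothole wetlands — millions of small glacial basins across the
north-central Great Plains — support a large community of breeding
waterbirds. Because the basins are small and the climate semi-arid, warming
is expected to dry many of them out. This package implements a
species-distribution-model (SDM) pipeline for estimating how much suitable
breeding habitat each species stands to lose: segment-level presence/absence
records from roadside surveys are related to land-cover composition and
temporally aggregated climate, the fitted model is projected onto baseline
and future climate grids, and the change in the number of suitable grid
cells is the headline statistic per species.

The pipeline is paired with a synthetic-data generator that produces virtual
landscapes, climate series, and virtual species with *known* logistic
responses, so that every stage can be verified against analytic truth at
desk scale — parameter recovery, not just plumbing, is tested.

## The observation model

The sampling unit is a 10-stop roadside route segment (stops 0.8 km apart,
7.2 km end to end). A species is "present" in a segment-year when it is
detected at one or more stops. Detection is treated as perfect at segment
level — a single Bernoulli outcome per segment-year at the true occurrence
probability — on the argument that a full-segment survey during the breeding
season reliably documents regularly occurring species. This is an
assumption, not something the survey design can establish; no
detection-probability submodel is provided, and prevalence here always means
*apparent* occurrence rate.

Per species, either the first or the third segment of each route is used,
whichever has more detections (ties go to the first); the two candidate
segments accommodate species differing in when during the morning they are
most detectable. Focal species must reach a prevalence of at least 0.05
(0.07 with at least 10 detections for the short dry-years subset).

## Covariates

Thirty-one predictors, in the field's short names:

* **Land cover (13):** proportions of seven wetland classes — temporary
  (`temp`), seasonal (`seas`), semipermanent (`semi`), `lake`, `river`,
  forested (`forest`), `shrub` — plus two aggregates, total palustrine
  (`pal` = temp + seas + semi) and `total` (all wetland), and four upland
  classes: cropland (`crop`), grassland (`grass`), developed (`devel`),
  `tree`. Composition is measured in Euclidean buffers around the segment
  polyline at six radii (0.2, 0.4, 1, 2, 4, 8 km); the model-selection step
  picks the radius per species. The zonal rule is "cell centre inside the
  buffer" — deterministic and cheap; area-weighting would change third-digit
  proportions at most at these cell sizes. Land cover is static across
  years.
* **Climate (18):** temperature means and precipitation totals for spring
  (Mar–May), winter (Dec–Feb), fall (Sep–Nov) and summer (Jun–Aug), plus
  1-, 5- and 10-year aggregates and the 5- and 10-year standard deviations.
  All are aligned to the *bird-year*, the twelve months ending in May of the
  survey year, so that "last summer" means the summer preceding the June
  survey. Multi-year aggregates average bird-year values (mean of annual
  totals for precipitation); the standard deviations are sample (n−1) SDs
  over those annual values. Annual aggregation was chosen because the
  stated motivation for the variability covariates is multi-year wet/dry
  cycling of wetlands, which monthly SDs (dominated by seasonality) would
  not measure. Windows reaching before the start of the series are flagged
  incomplete and excluded rather than silently truncated.

Each segment uses the climate of its nearest grid point (Euclidean distance
to the segment midpoint, ties to the lowest point id).

## The model

Each species gets an ensemble of 3000 classification trees. Every tree is
grown on a bootstrap of 25 presence and 25 absence records drawn with
replacement, and 5 of the 31 predictors are candidates at each split. The
predicted probability is the fraction of trees voting presence.

Balanced per-tree sampling is the load-bearing choice. With equal class
priors per tree, the vote fraction estimates the *class-balanced posterior*
— the posterior probability under a 50/50 prior — which is invariant to the
prevalence of the training data. Thresholding the votes at 0.5 therefore
marks the likelihood-ratio-1 boundary, which is why the fixed 0.5 threshold
is coherent here where it would be miscalibrated for a forest trained on raw
imbalanced data. Two consequences worth knowing:

* the vote surface is *compressed* toward 0.5 relative to the true
  conditional probability (fifty-record trees are weak learners, and
  averaging many of them regularizes hard), so vote distributions cluster
  near the threshold; and
* the vote-0.5 contour coincides with the true-probability-0.5 contour only
  when training prevalence is itself near 0.5; at other prevalences it is
  the balanced-posterior boundary.

When a class has fewer than 25 records the contract of 25-per-class
sampling is preserved by replicating the scarce class's rows before
fitting (draws with replacement from the replicated rows are
distributionally identical to draws from the originals); a warning is
logged because out-of-bag statistics lose some of their meaning there.

**Partitions.** Within each route, surveyed years alternate between the
main training and main test sets (earliest year to training), so no two
consecutively surveyed years share a partition and temporal autocorrelation
cannot leak fitted noise into evaluation. The drought bird-years 1987–1992
form a third partition used two ways: models trained on the wetter years
are *evaluated* on it (transferability to conditions unlike training), and
separate dry-years models are fitted to compare variable importance.

**Scale selection** fits the six per-radius models and keeps the one with
the highest out-of-bag overall accuracy, ties to the smallest radius.
Out-of-bag accuracy is used because it consumes no test data; whether the
original analysis used out-of-bag, training or test accuracy is not
documented, and on synthetic data the choice moves selection only between
adjacent (highly correlated) radii.

**Importance and response signs.** Variable importance is the permutation
measure accumulated during fitting: the mean decrease in out-of-bag
accuracy when a predictor's values are shuffled. Sign codes are assigned
from a 20-point quantile-spaced partial-dependence profile with a 0.01
probability tolerance: monotone rising `+`, monotone falling `-`, interior
maximum `m`, otherwise equivocal `~`. The published tables use these four
codes without stating a procedure; this is one defensible construction, and
the unimodal/equivocal boundary in particular is ours.

## Evaluation

Confusion counts use the strict rule "presence iff probability > 0.5" (a
tie is absence), matching the suitability rule used in projection. Overall
accuracy is reported as an integer percent, rounded half away from zero —
the rule that reproduces the published accuracies from their own printed
confusion counts. AUC is the Mann–Whitney probability that a random
presence outscores a random absence, ties counting one half; bands follow
the conventional 0.7 / 0.8 / 0.9 cutpoints (acceptable / good /
outstanding). A Spearman rank correlation between per-species prevalence
and AUC checks that model quality is not an artifact of how common a
species is; with the transcribed reference tables (training prevalence vs
main-test AUC — the published text does not say which pair was used) it
reproduces the published −0.09 (p = 0.62).

## Projection and change

For a period (baseline 1981–2000; future 2040–2049), the model predicts
every grid cell for every bird-year of the period and the per-cell
probabilities are averaged; "probability over the period" is the mean of
annual predictions, not the prediction at mean covariates (with compressed
vote surfaces the two differ little, but averaging predictions is the
direct reading of a multi-year occurrence rate). A cell is suitable when
its period-mean probability exceeds 0.5; seven breakpoints at 0.125
intervals grade the confidence of the call. The change statistic is the
net percent change in suitable-cell count; the lost / gained / retained
decomposition is also reported because the published table's footnote
describes gross loss while its text suggests net change — both readings are
available. Tree ensembles clamp beyond the training range of any covariate
(predictions are constant past the last observed value), so projected
losses under strong warming are, if anything, underestimates.

## The synthetic generator

The generator is a first-class module whose defaults *are* the study
conditions the pipeline is validated under:

* **Landscape:** a 25.6 km × 25.6 km categorical raster at 100 m
  resolution; 2 wetland basins per km² as non-overlapping discs of 50–250 m
  radius (≈15 % wetland cover; rejection sampling with ≤100 retries per
  basin, failing loudly when asked for an impossible packing), regimes
  drawn as temporary 0.30 / seasonal 0.30 / semipermanent 0.20 / lake 0.06
  / river 0.04 / forested 0.05 / shrub 0.05; uplands tiled in ~0.6 km²
  square patches at cropland 0.55 / grassland 0.35 / developed 0.05 / tree
  0.05 — a cropland-dominated matrix typical of the region.
* **Climate:** monthly normals averaging 5.9 °C and totalling 548 mm/yr
  (the published baseline means), one regional anomaly per bird-year
  (additive N(0, 0.8 °C) for temperature; mean-one lognormal with 15 % SD
  for precipitation), a 1987–1992 drought block at 0.75× precipitation,
  and a north–south gradient of −0.3 °C per km of the miniature domain.
  The gradient makes the domain span ≈7.7 °C, emulating the mean-annual
  span of the full prairie-pothole region from its cool northwestern to
  its warm southeastern end; representing that span matters because a
  +2.9 °C future shift must leave part of the domain inside the spatially
  observed temperature range, exactly as in the real study area. The
  future series replays the same anomaly draws with +2.9 °C and ×1.039
  precipitation (the statistically-downscaled scenario magnitudes; a
  WRF-like alternative is +3.8 °C, ×1.031) and omits the historic drought
  block — future dryness enters through the offsets, not by replaying a
  specific historic drought.
* **Species:** occurrence truth is logistic in standardized covariates,
  with standardization constants frozen at calibration time and stored with
  the species so the oracle is exactly reproducible. Virtual species are
  scenario-specific; `default_species_pool()` provides a wetland obligate,
  a climate-sensitive species and a generalist as archetypes.
* **Surveys:** 25 routes, two 10-stop segments each (placed independently —
  at this domain size the 16 km separating real first and third segments
  cannot be honored, so first/third is a label feeding the segment-choice
  rule), surveyed 1971–2011. All randomness flows from one top-level seed
  through named substreams, so stages can be regenerated independently.

What the generator does *not* emulate: detection error, spatial
autocorrelation of occupancy beyond what covariates induce, land-cover
change over time, observer effects, and real geographic projections.
Passing recovery tests therefore demonstrates that the pipeline's
estimators track their targets under the stated generative assumptions —
not that those assumptions hold for field data.

## Planted-truth validation

Four benchmarks (exported, used by both the test suite and the acceptance
script):

* **Null calibration** — shuffling the response of a 400-row noise fixture
  yields out-of-bag AUC within 0.5 ± 0.08 across 20 seeds.
* **Prevalence invariance** — training sets sharing class-conditional
  distributions but differing in prevalence (0.1 vs 0.5, n = 2000) give
  probability surfaces within 0.05 mean absolute difference.
* **Driver and scale recovery** — a species planted on semipermanent
  wetland and grassland composition puts both drivers in the importance
  top 3 (≥8/10 seeds) and selects the true 2000-m response scale (≥7/10;
  misses go to the adjacent, ~0.9-correlated radius). Weakly weighted
  drivers that are aliased by aggregates — a faint annual-temperature
  signal next to its less noisy 10-year proxy — share permutation credit
  and are *not* reliably individually recoverable; the benchmark plants
  unaliased drivers and checks magnitude order among planted covariates.
* **End-to-end contraction recovery** — a temperature-limited species
  (`T_1yr` −3, `semi` +1, intercept 0, hence prevalence ≈0.5 so the vote
  threshold and the truth threshold coincide) is pushed through the whole
  pipeline; the projected percent range change agrees with the analytic
  change computed from the truth function on the same covariate stacks
  within 10 percentage points (20-seed median). The balanced-posterior
  threshold analysis above explains why a balanced, spatially sharp
  scenario is the right benchmark: at other prevalences the model
  estimates a different (balanced-posterior) boundary than the
  truth-probability boundary, and no finite ensemble could close that
  definitional gap.

## Numerical and reporting conventions

Integer percents round half away from zero everywhere. Probabilities on a
bin edge join the lower bin; probabilities exactly at threshold are
unsuitable/absent. Ties in scale selection go to the smaller radius, in
segment choice to the first segment, in nearest-point assignment to the
lowest id. Sample (n−1) SDs throughout. Rasters are plain-text ESRI ASCII
grids with JSON sidecars, climate series are long CSVs, and all artifacts
are reproducible byte-for-byte under a fixed seed.

Reference results from the published 31-species assessment ship as
transcribed CSV fixtures (`reference_table()`); two transcription notes:
species-name spellings are normalized across tables, and the published
per-species accuracy for one species (Green-winged Teal) differs by one
point from what its own printed confusion counts give — the fixtures keep
the printed values verbatim.

## Problem sizes

The shipped configuration runs the full pipeline — generation, six-scale
selection, evaluation, projection, twenty-seed recovery benchmarks — in a
few minutes on one CPU: 25 routes × 41 years (~2050 segment-years per
species), 25 climate points, a 400-cell projection grid, and 3000-tree
forests throughout. These sizes were chosen so that Monte-Carlo error in
the recovery benchmarks is comfortably below the tolerances being tested;
the statistical conclusions do not change at larger sizes.
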