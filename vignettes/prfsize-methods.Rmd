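---
title: "Models and methods behind prfsize"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind prfsize}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prfsize)
```

This vignette explains the models implemented in `prfsize`, the
assumptions behind them, the tunable parameters that matter, and the
numerical and design choices made where several reasonable options
existed. It is the package's reference account of its own methods; all
quantitative statements below are the ones the test suite and
`scripts/acceptance.R` compute.

## The scientific problem

Perceived object size varies idiosyncratically across the visual
field: the same circle can look slightly smaller in one quadrant than
another, stably so within an observer. The package implements a
pipeline for asking whether such perceptual fingerprints are
predicted by the local architecture of V1 — specifically by pRF
spread (the σ of a 2D Gaussian population receptive field, in visual
degrees) and by quadrant surface area — and a read-out model for why
coarser spatial tuning should shrink apparent size at all.

## The MAPS task and its detector model

In each trial of the multiple-alternative perceptual search (MAPS)
task an observer sees a central reference circle (0.98° diameter) and
four peripheral targets on the diagonals, and picks the target most
similar in size to the reference. Sizes are binary-log diameter
ratios, so 0 is a physical match. Two trial generators are provided:

* `draw_fixed_set_trials()` — four distinct offsets drawn without
  replacement from the 17-element set {0, ±0.05, ±0.1, ±0.15, ±0.2,
  ±0.25, ±0.5, ±0.75, ±1}; often no offset is exactly 0, so many
  trials have no correct answer (the fraction with a correct target is
  the hypergeometric 4/17 ≈ 0.235).
* `draw_gaussian_trials()` — one target is exactly 0 at a uniformly
  random location and the other three are zero-mean Gaussian draws
  (SD 0.3 log units).

Choices are modelled with four unit-amplitude Gaussian detectors, one
per location; the detector with the largest response to its own
target's offset determines the predicted choice, with exact ties going
to the lowest location index. Fitting (`fit_maps_model()`) minimises
the misprediction fraction over the 8 parameters (μ₁..μ₄ and, on a log
scale to keep them positive, σ₁..σ₄), using Nelder–Mead simplex search
restarted from jittered copies of a data-driven initialisation: μ
starts at the mean offset over trials where the location was chosen
incorrectly, σ at the SD of offsets over trials where it was chosen,
with documented fallbacks (μ = 0, σ = 0.3) for empty strata. A
positive fitted μ means targets at that location look smaller than
they are.

### Numerical choices in the fitter

Two structural facts about the 0/1 loss shaped the implementation:

1. It is **piecewise constant** — between decision-boundary crossings
   the misprediction count cannot change, so a simplex has no local
   gradient to follow.
2. It is **scale-blind in σ** — multiplying all four dispersions by a
   common factor never changes any argmax, so the choice data alone
   identify only dispersion ratios.

The fitter therefore adds a smooth surrogate — the softmax
(Luce-choice) negative log-likelihood of the detector responses — at
weight 0.2/n, strictly below the 1/n granularity of the loss. The
surrogate can never override a one-trial improvement in the primary
loss; it only steers the search inside flat plateaus and along the
flat overall-scale direction. The reported `fit_error` is always the
plain misprediction fraction, and the returned fit never scores worse
than the initialisation. Options expose a pure softmax objective
(`loss = "softmax"`) and an alternative scale anchor that pins the
geometric mean of the fitted σ to the initialisation's
(`scale_anchor = "init"`); defaults are the 0/1 loss and the
likelihood anchor. Bounds (μ ∈ [−2, 2], σ ∈ [0.01, 3]) reject
pathological fits; unanswered trials are dropped.

Per-run fitting is the default; runs can be pooled simply by
concatenating their trial tables before fitting.

## The population read-out model

The read-out model asks what size a downstream decoder would report
if it only saw V1-like activity. A screen column is a vector of 1050
pixels; the target's two edges (and, for Delboeuf stimuli, the two
inducer edges at 2.35°) are set to 1. A bank of Gaussian filters, one
per pixel, produces the population profile
`a(p) = Σₓ edge(x)·exp(-(x-p)²/2w(p)²)`; perceived extent is the
separation of the two local maxima nearest the target's true edges,
and the predicted bias is `log2(true / estimated)`.

Key behaviour, all verified by tests: with two equal unit Gaussians
separated by d pixels, two peaks exist iff σ < d/2 (peak merging);
below the merge point the estimated extent shrinks monotonically as
width grows (positive, growing bias); Delboeuf inducers push the
target peaks outward at narrow widths (overestimation, negative bias)
before the same attraction takes over. The difference between the two
conditions' biases — the relative illusion strength — grows with
width. Simulated biases are much larger than empirical ones; no
scaling factor is applied, since only the qualitative pattern is the
model's claim.

Choices: pixel pitch defaults to 30 px/°, configurable, since only
the pixel count of the display is fixed by the design; tuning width
can be constant per simulation or grow linearly with distance from a
centre pixel (`linear_width_fn()`), covering both readings of
"parameterised at each pixel"; peaks are localised with sub-pixel
quadratic interpolation (toggleable) to reduce rasterisation steps;
merged estimates are flagged missing, never reported as zero.

## The pRF engine

The mapping stimulus combines a 12°-wide polar wedge rotating in 60
one-second steps (3 cycles) with a ring expanding or contracting in
36 logarithmic steps (5 cycles), confined to 8.5° eccentricity, plus
45 trailing blank volumes: 225 modelled volumes. The ring's outer
radius steps geometrically from 0.6° to 8.5° with inner radius 0.7 ×
outer, so ring width grows in proportion to its diameter — an
assumption, documented here, since only "logarithmic steps in width
and overall diameter" is specified by the design.

The HRF is a difference of two gamma densities with four free
parameters (amplitude, peak latency, undershoot latency,
peak/undershoot ratio); gamma shapes are chosen so each term's mode
equals its latency. `fit_hrf()` averages 30-s epochs within units,
includes a unit only when its mean-minus-standard-error response over
the first half of the epoch is positive on average, averages included
units and fits by least squares (amplitude profiled analytically).

The forward model computes, per volume, the overlap of an isotropic
2D Gaussian with the binary aperture on a grid (default 101 × 101
over ±9°), z-standardises the overlap series, convolves with the HRF,
and z-scores the result — following that order literally, with a
`convolve_first` flag for sensitivity checks. Fitting is two-stage:
an exhaustive grid over 15 × 15 evenly spaced positions in [−9°, 9°]
(the "plausible values", chosen to cover the mapped field with
margin) × 34 spreads 0.18°·2^(0.2k) — the verbatim step rule, whose
top value ≈17.45° — maximising Pearson correlation, then simplex
refinement of (x, y, log σ) minimising squared residuals with the
response amplitude as a fourth parameter profiled by least squares at
every step. The fine fit returns the seed with a warning if it cannot
improve it. Grid predictions depend only on apertures and HRF, so
`prf_grid_predictions()` computes them once and reuses them across
all units. Preprocessing (`preprocess_series()`) detrends linearly,
z-scores, averages runs sharing a stimulus direction, and
concatenates the two direction means. Cortical-surface smoothing is
not implemented: synthetic vertices are independent units, and the
summaries tag which map a column came from instead.

## Cortical summaries

Vertices are assigned to visual-field quadrants from their polar
angle (0° = right horizontal meridian, counterclockwise, y up;
meridians go to the lower-index quadrant). Eccentricity bands are
half-open 1° intervals [k, k+1), k = 1..8, with band centres k+0.5 as
regression abscissae. Band statistics are the unweighted vertex mean
of pRF spread (with a percentile-bootstrap 95% CI) and the summed
surface area. Profiles are least-squares polynomials of band value on
band centre — degree 1 for spread, degree 2 for area — evaluated at
the stimulus eccentricities (flagged when extrapolating beyond the
fitted 1°–9° range, e.g. at 11.76° or 15.68°). Quadrant surface area
sums vertex areas over the closed interval [1°, 9°] and is normalised
as a percentage of whole-cortex area by default (square-root and
absolute modes available). The "local area" evaluated at a point is a
band-sized area, not a density; it is used only as a relative
predictor across locations.

## The statistical battery and its calibration

All tests treat the 120 location-observations of a full design (10
observers × 3 eccentricities × 4 quadrants) as follows:

* `pooled_pearson()` — Pearson r over all locations, two-sided
  t-based p.
* `variance_partition_regression()` — OLS of the outcome on three
  regressors built from the predictor (per-observer mean; per
  observer-by-eccentricity mean minus observer mean; per
  observer-by-quadrant mean minus observer mean) plus an intercept,
  leaving df = n − 4 = 116. The alternative dummy-covariate reading
  of the construction would not reproduce those df, which is why this
  construction was chosen.
* `demeaned_correlation()` — observer-by-eccentricity means removed
  from both variables, pooled r on the residuals tested at the
  nominal n. This test is deliberately anticonservative and the
  package quantifies by how much (below).
* `second_level_location_correlation()` — per-cell r over the four
  locations, Fisher z with |r| clipped at 1−10⁻⁶ (4-point cells reach
  ±1), two-sided one-sample t-test of the cell z's; zero-variance
  cells are dropped with a warning and an all-identical z vector is
  flagged degenerate with an infinite t. With 4-point cells the mean
  z is upward-biased for nonzero effects — a small-sample property of
  atanh(r), not an implementation artefact — so the unbiasedness test
  runs at 50-point cells and the 4-point design is checked for null
  centering and effect ordering.
* `condition_correlation_matrix()` — all 15 pairwise correlations
  among the 6 condition columns (2 stimulus types × 3 eccentricities,
  each visual-field location a data point, n = 40), flagged
  uncorrected and Bonferroni-corrected at 0.05/15. Bonferroni is used
  only for this family; elsewhere p values are reported uncorrected,
  matching how the analyses are reported.
* `pca_six_variable()` — eigendecomposition of the correlation matrix
  of the six z-standardised per-location measures; explained-variance
  percentages sum to 100 by trace conservation.

`power_fpr_simulation()` calibrates these by simulation: x and y are
drawn location-wise from a bivariate normal with the requested true
correlation (independent standard normals under the null — the
generative model behind the "nominal" rates), optionally with shared
observer- or cell-level components for sensitivity analyses. The
quantities `scripts/acceptance.R` recomputes at 10,000 replicates
are: power ≈ 90% for the pooled test at true r = 0.3 (the Fisher-z
closed form `power_fisher_z(0.3, 120)` gives 91.7%), a null rejection
rate ≈ 5% for the pooled test, and ≈ 9% for the demeaned variant —
the inflation follows from testing residuals that retain only 90
effective degrees of freedom at a nominal n of 120. The regression
variant tests one focal regressor (default the quadrant term); a
minimum over several terms would itself be anticonservative.

## The synthetic-data generator

`make_observer()` draws an observer whose true bias at a location is
`slope · eccentricity + quadrant offset`, with offsets shared across
eccentricities (that sharing is what makes biases correlate across
eccentricity within a quadrant, the structure the six-condition
matrix looks for). Defaults: slope 0.015 log-units/°, quadrant SD
0.05, internal noise SD 0.15 (scalar or per-location), lapse 0.02,
and a Delboeuf shift of 0.05 + 0.01·e log units — chosen once so
that simulated accuracy on Gaussian-variant trials falls in the
realistic 45–50% range (chance is 25%) and bias magnitudes are of
order 0.1 log units at the far eccentricity.

Responses are generated by an argmin rule — perceived offset =
physical offset − true bias + Gaussian noise; the observer picks the
smallest apparent mismatch — deliberately *not* the detector model,
so recovery tests do not test the fitter against its own assumption.
A detector-consistent generator (`simulate_detector_choices()`) is
provided for parameter-recovery tests where the ground truth must be
the detector parameters themselves; its Luce rule samples choices
with probability proportional to a power of each detector's response
(decisiveness 0.15 by default). Under that generator the fitter
recovers μ to a median error well under 0.03 with 600 trials and
ranks dispersions across runs with Spearman correlation above 0.8;
under the argmin generator with internal noise up to 0.5 the 0/1-loss
estimator's sampling variance is intrinsically larger, which is a
property of the loss, not of the optimiser.

`make_cortex()` lays out vertices per quadrant with eccentricity
density following areal magnification M(e) ∝ 1/(e + 0.75°) (a
standard inverse-linear form; only the shape matters), spread linear
in eccentricity (0.5° + 0.2°/e° by default) with vertex noise, and
per-vertex areas splitting a quadrant total. When given an observer
and a coupling coefficient ρ, quadrant spread offsets are constructed
to correlate ρ with the observer's quadrant bias offsets — the
planted effect the pipeline should detect. `make_bold()` adds white
noise to the forward model's prediction (noise SD = 1/CNR since
predictions are z-scored); it saves the generating parameters for
recovery tests. Real fMRI noise is not white and real cortices are
smooth sheets, so passing tests demonstrate the pipeline's
correctness and sensitivity, not field-strength-specific performance.

## Problem sizes and determinism

Default test and example sizes are desk-scale by design: 41 × 41
aperture grids in tests (101 × 101 defaults), tens of synthetic pRF
units, 12-run recovery grids, 200 trials per simulated run in the
pipeline example, and 10,000 Monte Carlo replicates for the
calibration quantities. All generators are plain consumers of R's
RNG: a single `set.seed()` (or the `seed` field of `run_config()`)
makes every result, including the full pipeline report,
bit-reproducible.

## Known limitations

* The detector fit identifies dispersion ratios, not the absolute
  dispersion scale; reported σ scales depend on the documented anchor.
* The read-out model is one-dimensional and noiseless by design;
  response nonlinearities, surround effects and hemodynamic noise are
  out of scope.
* The "local surface area" predictor inherits the band-area unit
  convention described above.
* Surface-based smoothing and real-data import beyond delimited
  tables are not implemented; the deposited observer data of the
  original study can be analysed by writing them into the documented
  table formats, but no downloader is included.
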