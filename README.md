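# prfsize

Idiosyncratic biases in perceived object size — which corner of your
visual field makes circles look a little smaller — turn out to be
stable personal "fingerprints". This package implements a complete,
testable computational chain linking such perceptual fingerprints to
the functional architecture of primary visual cortex (V1): the spatial
spread of population receptive fields (pRFs) and the cortical surface
area devoted to each visual-field quadrant.

It is written for vision scientists who want to simulate, fit, and
statistically relate:

1. **MAPS psychophysics** — a 4-alternative perceptual matching task.
   Four peripheral target circles (one per diagonal, eccentricities
   1.96°, 3.92°, 7.84°) are compared against a central 0.98° reference;
   sizes are expressed as `log2(target / reference)`. Choices are
   modelled by four Gaussian-tuned "neural detectors": the detector
   with the strongest output `exp(-(s - μ)² / 2σ²)` predicts the
   choice, and the per-location bias μ and dispersion σ are fitted by
   Nelder–Mead minimisation of the misprediction fraction
   (`fit_maps_model()`). A Delboeuf condition (2.35° inducer annulus)
   measures contextual size illusions; relative illusion strength is
   the bias difference between conditions.
2. **A population read-out model** — stimulus edges on a 1050-pixel
   line pass through a Gaussian filter bank; perceived size is the
   separation of the two activity peaks. The model predicts why
   apparent size shrinks as tuning width grows (peaks attract and
   eventually merge at σ = d/2), and why Delboeuf targets first look
   larger and then shrink too (`simulate_bias_curves()`).
3. **pRF modelling** — combined wedge (12°, 60 steps, 3 cycles) and
   ring (36 log steps, 5 cycles) apertures within 8.5° eccentricity,
   225 one-second volumes; a two-gamma HRF fitted from epoch averages;
   a 2D-Gaussian forward model (overlap → z-score → HRF convolution);
   a 15 × 15 × 34 coarse correlation grid (spreads 0.18°·2^0.2k)
   seeding a simplex fine fit with a free amplitude (`fit_prf()`).
4. **Cortical summaries** — 1°-wide eccentricity bands from 1° to 9°,
   mean pRF spread (bootstrap CIs) and summed surface area per band,
   linear (spread) and quadratic (area) polynomial profiles evaluated
   at the 12 behavioural target locations (`summarize_cortex()`).
5. **The statistical battery** — pooled location-wise Pearson
   correlations (n = 120), variance-partitioned regression with
   observer / eccentricity / quadrant regressors (df = 116),
   demeaned and second-level Fisher-z variants, a six-condition
   correlation matrix with a 15-comparison Bonferroni family, PCA, and
   Monte Carlo power / false-positive calibration of all of these
   (`power_fpr_simulation()`).

A synthetic-data generator (`make_observer()`, `make_cortex()`,
`make_bold()`, `make_world()`) produces coupled behavioural and
cortical data with the statistical structure the analysis assumes, so
every stage is testable end to end without any external data.

## Worked example

Simulate a ten-observer study in which quadrant-level pRF spread is
coupled to quadrant-level size bias (coupling 0.5), fit everything,
and run the statistics:

```r
library(prfsize)
report <- run_full_pipeline(run_config(seed = 42, n_observers = 10,
                                       n_trials = 200, fit_restarts = 10))
print(report)
#> Synthetic pipeline report
#>   observers: 10  trials/run: 200  coupling: 0.5
#>   pooled spread-bias correlation: Pearson r = 0.491, p = 1.286e-08, n = 120
#>   demeaned correlation: Pearson r = 0.072, p = 0.4328, n = 120
#>   PCA percent variance: 43.8, 19.3, 13.9, 13.1, 7.8, 2.2
```

The pooled correlation treats each of the 120 location-observations
(10 observers × 3 eccentricities × 4 quadrants) as one data point:
locations covered by larger pRFs are judged smaller, so the planted
positive coupling comes back as a positive r. The demeaned variant
removes observer-by-eccentricity means and asks only about the pattern
across quadrants — a much weaker signal at this coupling. The
variance-partitioned regression separates the same effects formally:

```r
print(report$stats$regression)
#> Variance-partitioned regression (df = 116)
#>             term        beta          t            p
#>        intercept  0.10411160  0.6280141 5.312291e-01
#>  between_subject -0.02393291 -0.2030050 8.394867e-01
#>     eccentricity  0.08457417  6.1833225 9.667351e-09
#>         quadrant  0.04038708  0.7262139 4.691704e-01
```

Here the shared eccentricity trend carries most of the association
(t(116) = 6.2), as expected when both spread and bias grow with
eccentricity.

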