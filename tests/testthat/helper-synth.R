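# Shared fixtures built in code.

# Detector-model recovery experiment: draws true parameters from the
# given ranges, simulates Luce-rule choices, fits, and returns errors.
recovery_experiment <- function(n_runs, n_trials, mu_range = c(-0.3, 0.3),
                                sigma_range = c(0.1, 0.5), restarts = 20L) {
  mu_err <- c()
  sigma_true <- c()
  sigma_fit <- c()
  for (k in seq_len(n_runs)) {
    mu_t <- stats::runif(4, mu_range[1], mu_range[2])
    s_t <- stats::runif(4, sigma_range[1], sigma_range[2])
    tr <- draw_gaussian_trials(n_trials)
    tr <- simulate_detector_choices(tr, mu_t, s_t)
    f <- fit_maps_model(tr, restarts = restarts)
    mu_err <- c(mu_err, abs(f$mu - mu_t))
    sigma_true <- c(sigma_true, s_t)
    sigma_fit <- c(sigma_fit, f$sigma)
  }
  list(mu_err = mu_err, sigma_true = sigma_true, sigma_fit = sigma_fit)
}

# Small aperture sequence reused across pRF tests (built once per run).
test_apertures <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_apertures(aperture_config(grid_n = 41L))
    cache
  }
})

test_grid_pred <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- prf_grid_predictions(test_apertures())
    cache
  }
})

# Synthetic vertex table with a known linear spread profile and no
# vertex noise, for profile-recovery checks. Vertices sit symmetric
# about each band centre so band means equal the centre value exactly.
exact_cortex <- function(intercept = 0.5, slope = 0.25) {
  ecc <- as.numeric(outer(c(-0.3, -0.1, 0.1, 0.3), 1:8 + 0.5, `+`))
  n <- length(ecc)
  data.frame(
    vertex_id = seq_len(n), region = "V1", quadrant = "upper_left",
    ecc_deg = ecc, polar_deg = 135,
    sigma_deg = intercept + slope * ecc,
    area_mm2 = rep(2, n)
  )
}
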