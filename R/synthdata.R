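#' Synthetic observer with a perceptual "fingerprint"
#'
#' Generates an observer whose true per-location size biases combine a
#' linear eccentricity trend (peripheral targets look smaller, so bias
#' grows with eccentricity) with zero-mean quadrant idiosyncrasies
#' shared across eccentricities, producing the stable across-location
#' heterogeneity the analysis targets. Delboeuf stimuli receive an
#' additional negative shift (apparent enlargement) growing with
#' eccentricity, the relative illusion strength.
#'
#' @param bias_slope Increase in true bias per degree of eccentricity
#'   (binary-log units / degree; default 0.015).
#' @param quadrant_sd SD of the zero-mean quadrant offsets (binary-log
#'   units; default 0.05).
#' @param noise_sd Internal (decision) noise SD in binary-log units,
#'   a scalar or one value per location (default 0.15, which places
#'   accuracy on Gaussian-variant trials in the realistic 45-50%
#'   range).
#' @param lapse Lapse rate in [0, 0.2]: probability of a uniformly
#'   random response (default 0.02).
#' @param illusion_intercept,illusion_slope Relative illusion strength
#'   at 0 degrees and its growth per degree.
#' @param eccentricities Stimulus eccentricities (degrees).
#' @return Object of class `observer_truth` with bias matrices
#'   `bias_isolated` and `bias_delboeuf` (eccentricities x quadrants),
#'   `quadrant_offsets`, and the generating parameters.
#' @export
make_observer <- function(bias_slope = 0.015, quadrant_sd = 0.05,
                          noise_sd = 0.15, lapse = 0.02,
                          illusion_intercept = 0.05,
                          illusion_slope = 0.01,
                          eccentricities = c(1.96, 3.92, 7.84)) {
  stopifnot(all(noise_sd > 0), length(noise_sd) %in% c(1L, 4L),
            lapse >= 0, lapse <= 0.2)
  noise_sd <- rep_len(noise_sd, 4L)
  offsets <- stats::rnorm(4L, 0, quadrant_sd)
  bias_iso <- outer(eccentricities * bias_slope, offsets, `+`)
  illusion <- illusion_intercept + illusion_slope * eccentricities
  bias_del <- bias_iso - illusion
  dimnames(bias_iso) <- dimnames(bias_del) <-
    list(as.character(eccentricities), quadrant_labels())
  structure(
    list(bias_isolated = bias_iso, bias_delboeuf = bias_del,
         quadrant_offsets = offsets, eccentricities = eccentricities,
         noise_sd = noise_sd, lapse = lapse, bias_slope = bias_slope,
         quadrant_sd = quadrant_sd),
    class = "observer_truth"
  )
}

#' True bias of an observer at one eccentricity and condition
#' @param observer An `observer_truth`.
#' @param eccentricity One of the observer's eccentricities.
#' @param condition `"isolated"` or `"delboeuf"`.
#' @return Length-4 vector of true biases (locations 1-4).
#' @export
true_bias <- function(observer, eccentricity,
                      condition = c("isolated", "delboeuf")) {
  condition <- match.arg(condition)
  i <- match(eccentricity, observer$eccentricities)
  if (is.na(i)) stop("eccentricity not in the observer's design")
  m <- if (condition == "isolated") observer$bias_isolated else
    observer$bias_delboeuf
  m[i, ]
}

#' Simulate an observer's choices on MAPS trials
#'
#' The perceived offset of each target is its physical offset minus
#' the observer's true bias at that location plus internal Gaussian
#' noise; the observer picks the target whose perceived offset is
#' closest to zero (closest apparent match to the reference). With
#' probability `lapse` the choice is uniformly random instead. This
#' perceived-offset rule is deliberately not the detector model used
#' for fitting, so recovery tests do not test the fitter against its
#' own assumption; `rule = "detector"` switches to a detector-model
#' generator for sensitivity checks.
#'
#' @param observer An `observer_truth`.
#' @param trials Trial data frame from the generators in this package.
#' @param condition Condition whose biases apply.
#' @param rule `"argmin"` (default) or `"detector"`.
#' @return The trial data frame with `chosen_loc` filled in.
#' @export
simulate_responses <- function(observer, trials,
                               condition = c("isolated", "delboeuf"),
                               rule = c("argmin", "detector")) {
  condition <- match.arg(condition)
  rule <- match.arg(rule)
  n <- nrow(trials)
  sizes <- trial_sizes(trials)
  eccs <- unique(trials$eccentricity_deg)
  chosen <- integer(n)
  for (e in eccs) {
    i <- trials$eccentricity_deg == e
    b <- true_bias(observer, e, condition)
    noise <- matrix(stats::rnorm(sum(i) * 4L), ncol = 4L)
    noise <- sweep(noise, 2L, observer$noise_sd, `*`)
    perceived <- sweep(sizes[i, , drop = FALSE], 2L, b) + noise
    chosen[i] <- if (rule == "argmin") {
      max.col(-abs(perceived), ties.method = "first")
    } else {
      # detector-consistent observer: the true biases and per-location
      # noise SDs play the roles of detector peak and dispersion
      noisy <- sizes[i, , drop = FALSE] +
        matrix(stats::rnorm(sum(i) * 4L, 0, min(observer$noise_sd) / 2),
               ncol = 4L)
      d <- sweep(noisy, 2L, b)^2
      max.col(-sweep(d, 2L, 2 * observer$noise_sd^2, `/`),
              ties.method = "first")
    }
  }
  lapsed <- stats::runif(n) < observer$lapse
  chosen[lapsed] <- sample.int(4L, sum(lapsed), replace = TRUE)
  trials$chosen_loc <- chosen
  trials
}

#' Simulate choices of a detector-model observer
#'
#' Generates choices directly from the Gaussian detector model: each
#' trial's sizes are perturbed by perceptual noise and the detector
#' with the strongest response wins. Used for parameter-recovery
#' tests where the ground truth is the detector parameter set itself.
#'
#' @param trials Trial data frame.
#' @param mu,sigma Length-4 true detector parameters.
#' @param percept_noise SD of the perceptual noise added to the
#'   physical sizes before the detectors respond (default 0.05; used
#'   by the `"max"` rule).
#' @param rule `"luce"` (default): the choice is sampled with
#'   probability proportional to a power of each detector's output, so
#'   both the peak and the absolute dispersion shape the choice
#'   statistics; `"max"`: the strongest response to the
#'   noise-perturbed sizes wins deterministically.
#' @param decisiveness Softmax temperature of the Luce rule: choice
#'   probabilities are proportional to `response^(1/decisiveness)`.
#'   Small values give decisive, near-argmax behaviour; the default
#'   0.15 produces realistically consistent choices.
#' @param lapse Probability of a uniformly random choice.
#' @return The trial data frame with `chosen_loc` filled in.
#' @export
simulate_detector_choices <- function(trials, mu, sigma,
                                      percept_noise = 0.05,
                                      rule = c("luce", "max"),
                                      decisiveness = 0.15,
                                      lapse = 0) {
  rule <- match.arg(rule)
  stopifnot(length(mu) == 4L, length(sigma) == 4L, all(sigma > 0),
            decisiveness > 0)
  n <- nrow(trials)
  if (rule == "luce") {
    s <- trial_sizes(trials)
    d <- -sweep(sweep(s, 2L, mu)^2, 2L, 2 * sigma^2, `/`) / decisiveness
    # Gumbel-max sampling from P(i) proportional to exp(d_i)
    g <- -log(-log(matrix(stats::runif(4L * n), ncol = 4L)))
    chosen <- max.col(d + g, ties.method = "first")
  } else {
    noisy <- trial_sizes(trials) +
      matrix(stats::rnorm(4L * n, 0, percept_noise), ncol = 4L)
    d <- sweep(sweep(noisy, 2L, mu)^2, 2L, 2 * sigma^2, `/`)
    chosen <- max.col(-d, ties.method = "first")
  }
  if (lapse > 0) {
    lapsed <- stats::runif(n) < lapse
    chosen[lapsed] <- sample.int(4L, sum(lapsed), replace = TRUE)
  }
  trials$chosen_loc <- chosen
  trials
}

#' Areal cortical magnification function
#'
#' Standard inverse-linear form `M(e) = 1 / (e + e0)` (relative units;
#' only the shape matters for the pipeline).
#'
#' @param ecc Eccentricity in degrees.
#' @param e0 Foveal offset in degrees (default 0.75).
#' @return Relative linear magnification.
#' @export
cortical_magnification <- function(ecc, e0 = 0.75) 1 / (ecc + e0)

#' Synthetic V1 vertex table for one observer
#'
#' Vertices are laid out per quadrant with eccentricity density
#' following areal magnification (density proportional to
#' `e * M(e)^2`), uniform polar angle within the quadrant, pRF spread
#' linear in eccentricity with a quadrant-specific offset and vertex
#' noise, and per-vertex surface area splitting a quadrant total.
#' When an observer is supplied with nonzero `coupling`, the quadrant
#' spread offsets correlate with the observer's quadrant bias offsets
#' with that coefficient, planting the spread-bias association the
#' analysis is designed to detect.
#'
#' @param observer Optional `observer_truth` to couple to.
#' @param coupling Correlation in [-1, 1] between quadrant bias
#'   offsets and quadrant spread offsets (default 0).
#' @param n_per_quadrant Vertices per quadrant (default 400).
#' @param spread_intercept,spread_slope Population spread profile
#'   (degrees; spread = intercept + slope * ecc).
#' @param spread_offset_sd SD of the quadrant-level spread offsets.
#' @param vertex_noise_sd SD of per-vertex spread noise (degrees).
#' @param quadrant_area_mean,quadrant_area_sd Total quadrant surface
#'   area distribution (mm^2).
#' @param ecc_range Eccentricity support of the vertices (degrees).
#' @param e0 Magnification foveal offset.
#' @return Vertex data frame: `vertex_id`, `region`, `quadrant`,
#'   `ecc_deg`, `polar_deg`, `sigma_deg`, `area_mm2`, with attribute
#'   `spread_offsets` (the quadrant offsets used).
#' @export
make_cortex <- function(observer = NULL, coupling = 0,
                        n_per_quadrant = 400L,
                        spread_intercept = 0.5, spread_slope = 0.2,
                        spread_offset_sd = 0.15,
                        vertex_noise_sd = 0.3,
                        quadrant_area_mean = 1200,
                        quadrant_area_sd = 150,
                        ecc_range = c(0.5, 9.5), e0 = 0.75) {
  stopifnot(coupling >= -1, coupling <= 1)
  labels <- quadrant_labels()
  # quadrant polar sectors matching assign_quadrant's convention
  sectors <- list(c(90, 180), c(0, 90), c(180, 270), c(270, 360))
  if (!is.null(observer) && coupling != 0) {
    z_bias <- observer$quadrant_offsets / observer$quadrant_sd
    offsets <- spread_offset_sd *
      (coupling * z_bias + sqrt(1 - coupling^2) * stats::rnorm(4L))
  } else {
    offsets <- stats::rnorm(4L, 0, spread_offset_sd)
  }
  rows <- lapply(1:4, function(q) {
    ecc <- sample_magnified_ecc(n_per_quadrant, ecc_range, e0)
    polar <- stats::runif(n_per_quadrant, sectors[[q]][1L] + 1e-3,
                          sectors[[q]][2L] - 1e-3)
    sigma <- spread_intercept + spread_slope * ecc + offsets[q] +
      stats::rnorm(n_per_quadrant, 0, vertex_noise_sd)
    sigma <- pmax(sigma, 0.05)
    total <- max(stats::rnorm(1L, quadrant_area_mean, quadrant_area_sd),
                 100)
    w <- stats::runif(n_per_quadrant, 0.5, 1.5)
    data.frame(
      region = "V1", quadrant = labels[q], ecc_deg = ecc,
      polar_deg = polar, sigma_deg = sigma,
      area_mm2 = total * w / sum(w)
    )
  })
  out <- do.call(rbind, rows)
  out <- cbind(vertex_id = seq_len(nrow(out)), out)
  attr(out, "spread_offsets") <- offsets
  out
}

# inverse-CDF-free sampler: rejection from the areal-magnification
# density  f(e) proportional to e * M(e)^2  on [lo, hi]
sample_magnified_ecc <- function(n, ecc_range, e0) {
  lo <- ecc_range[1L]
  hi <- ecc_range[2L]
  dens <- function(e) e * cortical_magnification(e, e0)^2
  fmax <- max(dens(seq(lo, hi, length.out = 512L)))
  out <- numeric(0)
  while (length(out) < n) {
    m <- 2L * (n - length(out))
    e <- stats::runif(m, lo, hi)
    keep <- stats::runif(m) < dens(e) / fmax
    out <- c(out, e[keep])
  }
  out[seq_len(n)]
}

#' Synthetic BOLD series from a vertex table
#'
#' For each vertex, converts (eccentricity, polar angle) to Cartesian
#' pRF coordinates, generates the noiseless predicted series from the
#' forward model, and adds i.i.d. Gaussian noise. The generating
#' parameters are returned for recovery tests.
#'
#' @param vertices Vertex data frame (columns `ecc_deg`, `polar_deg`,
#'   `sigma_deg`).
#' @param apertures An `aperture_sequence`.
#' @param hrf HRF parameters.
#' @param noise_sd SD of the additive noise (the noiseless prediction
#'   is z-scored, so this is 1/CNR).
#' @return List with `series` (volumes x vertices matrix) and `truth`
#'   (data frame `unit`, `x`, `y`, `spread`, `degenerate`).
#' @export
make_bold <- function(vertices, apertures, hrf = default_hrf(),
                      noise_sd = 0.5) {
  n <- nrow(vertices)
  x <- vertices$ecc_deg * cos(vertices$polar_deg * pi / 180)
  y <- vertices$ecc_deg * sin(vertices$polar_deg * pi / 180)
  series <- matrix(NA_real_, nrow = apertures$n_volumes, ncol = n)
  degen <- logical(n)
  for (i in seq_len(n)) {
    p <- predict_timeseries(x[i], y[i], vertices$sigma_deg[i], apertures,
                            hrf)
    degen[i] <- isTRUE(attr(p, "degenerate"))
    series[, i] <- p + stats::rnorm(apertures$n_volumes, 0, noise_sd)
  }
  list(series = series,
       truth = data.frame(unit = seq_len(n), x = x, y = y,
                          spread = vertices$sigma_deg,
                          degenerate = degen))
}

#' Generate a complete coupled synthetic study
#'
#' Builds `n_observers` observers, each with MAPS trial runs for both
#' stimulus conditions at every eccentricity (responses simulated from
#' the observer's true biases) and a coupled synthetic cortex.
#'
#' @param n_observers Number of observers (default 10).
#' @param n_trials Trials per observer, condition and eccentricity
#'   (default 200).
#' @param coupling Spread-bias coupling passed to [make_cortex()].
#' @param eccentricities Stimulus eccentricities.
#' @param observer_args,cortex_args Extra arguments for
#'   [make_observer()] / [make_cortex()].
#' @param noise_sd Distractor SD of the Gaussian trial variant.
#' @return List of class `synthetic_world` with `observers`,
#'   `trials` (nested list observer/condition/eccentricity),
#'   `cortices`, and the call parameters.
#' @export
make_world <- function(n_observers = 10L, n_trials = 200L,
                       coupling = 0.5,
                       eccentricities = c(1.96, 3.92, 7.84),
                       observer_args = list(), cortex_args = list(),
                       noise_sd = 0.3) {
  observers <- vector("list", n_observers)
  trials <- vector("list", n_observers)
  cortices <- vector("list", n_observers)
  for (o in seq_len(n_observers)) {
    obs <- do.call(make_observer,
                   c(list(eccentricities = eccentricities), observer_args))
    tr <- list()
    for (cond in c("isolated", "delboeuf")) {
      geom <- stimulus_geometry(condition = cond,
                                eccentricities = eccentricities)
      for (e in eccentricities) {
        t0 <- draw_gaussian_trials(n_trials, geom, e, noise_sd)
        tr[[cond]][[as.character(e)]] <-
          simulate_responses(obs, t0, cond)
      }
    }
    observers[[o]] <- obs
    trials[[o]] <- tr
    cortices[[o]] <- do.call(make_cortex,
                             c(list(observer = obs, coupling = coupling),
                               cortex_args))
  }
  structure(
    list(observers = observers, trials = trials, cortices = cortices,
         n_observers = n_observers, n_trials = n_trials,
         coupling = coupling, eccentricities = eccentricities),
    class = "synthetic_world"
  )
}
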