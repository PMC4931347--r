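#' Stimulus geometry for the MAPS size-matching task
#'
#' Describes the circle array used in the multiple-alternative perceptual
#' search (MAPS) task: a central reference circle plus four peripheral
#' targets on the diagonals, optionally each surrounded by a larger
#' Delboeuf inducer annulus.
#'
#' Locations are indexed by visual-field quadrant with y pointing up:
#' 1 = upper-left, 2 = upper-right, 3 = lower-left, 4 = lower-right.
#' Polar angle 0 degrees is the right horizontal meridian, increasing
#' counterclockwise, so the four diagonals sit at 135, 45, 225 and 315
#' degrees for locations 1--4 respectively.
#'
#' @param reference_diameter Diameter of the central reference circle in
#'   degrees of visual angle.
#' @param inducer_diameter Diameter of the Delboeuf inducer annulus in
#'   degrees; must exceed the reference diameter when `condition` is
#'   `"delboeuf"`.
#' @param eccentricities Target eccentricities (degrees) used in the
#'   study design.
#' @param condition `"isolated"` (plain circles) or `"delboeuf"`
#'   (inducer annulus around each target).
#'
#' @return An object of class `stimulus_geometry`.
#' @export
stimulus_geometry <- function(reference_diameter = 0.98,
                              inducer_diameter = 2.35,
                              eccentricities = c(1.96, 3.92, 7.84),
                              condition = c("isolated", "delboeuf")) {
  condition <- match.arg(condition)
  stopifnot(reference_diameter > 0, all(eccentricities > 0))
  if (condition == "delboeuf" && inducer_diameter <= reference_diameter) {
    stop("inducer_diameter must exceed reference_diameter for delboeuf stimuli")
  }
  structure(
    list(
      reference_diameter = reference_diameter,
      inducer_diameter = inducer_diameter,
      eccentricities = eccentricities,
      polar_angles = c(135, 45, 225, 315),
      condition = condition
    ),
    class = "stimulus_geometry"
  )
}

#' Extended eccentricity set including the far periphery
#'
#' @return Numeric vector of the five target eccentricities in degrees.
#' @export
extended_eccentricities <- function() c(1.96, 3.92, 7.84, 11.76, 15.68)

#' Binary-log size ratio between a target and the reference
#'
#' Target sizes throughout the package are expressed as the binary
#' logarithm of the ratio of target to reference diameters, so 0 means
#' physically equal, +1 means double and -1 means half the reference
#' diameter.
#'
#' @param target_diameter,reference_diameter Diameters in degrees, > 0.
#' @return Log-size offset in binary-log units.
#' @export
log_size_ratio <- function(target_diameter, reference_diameter) {
  if (any(target_diameter <= 0) || any(reference_diameter <= 0)) {
    stop("diameters must be positive")
  }
  log2(target_diameter / reference_diameter)
}

#' The fixed set of log-size offsets used in the size-eccentricity design
#'
#' @return The 17 offsets 0, +/-0.05, +/-0.1, +/-0.15, +/-0.2, +/-0.25,
#'   +/-0.5, +/-0.75, +/-1 (binary-log units).
#' @export
fixed_size_set <- function() {
  m <- c(0.05, 0.1, 0.15, 0.2, 0.25, 0.5, 0.75, 1)
  sort(c(0, m, -m))
}

new_trial <- function(trial_id, condition, eccentricity, sizes,
                      correct_location = NA_integer_,
                      chosen_location = NA_integer_) {
  list(
    trial_id = trial_id, condition = condition,
    eccentricity = eccentricity, sizes = sizes,
    correct_location = correct_location, chosen_location = chosen_location
  )
}

#' Draw MAPS trials with target sizes from the fixed 17-element set
#'
#' Each trial draws four pairwise-distinct offsets without replacement
#' from [fixed_size_set()]. The correct location is defined only when
#' the 0 offset happens to be among the four; frequently it is not, so
#' there is often no objectively correct target.
#'
#' @param n_trials Number of trials.
#' @param geometry A [stimulus_geometry()].
#' @param eccentricity Target eccentricity in degrees.
#' @return A trial data frame (see [trials_to_df()] for the layout).
#' @export
draw_fixed_set_trials <- function(n_trials, geometry = stimulus_geometry(),
                                  eccentricity = 3.92) {
  set <- fixed_size_set()
  sizes <- t(vapply(seq_len(n_trials), function(i) sample(set, 4L),
                    numeric(4)))
  correct <- apply(sizes, 1L, function(s) {
    i <- which(s == 0)
    if (length(i) == 1L) i else NA_integer_
  })
  trials_df(n_trials, geometry$condition, eccentricity, sizes,
            as.integer(correct))
}

#' Draw MAPS trials with Gaussian-noise distractors and one exact match
#'
#' One target, at a uniformly random location, is set to offset 0 (the
#' correct answer); the other three are independent zero-mean Gaussian
#' draws with the given standard deviation.
#'
#' @param n_trials Number of trials.
#' @param geometry A [stimulus_geometry()].
#' @param eccentricity Target eccentricity in degrees.
#' @param noise_sd SD of the distractor offsets in binary-log units
#'   (default 0.3).
#' @return A trial data frame.
#' @export
draw_gaussian_trials <- function(n_trials, geometry = stimulus_geometry(),
                                 eccentricity = 3.92, noise_sd = 0.3) {
  stopifnot(noise_sd > 0)
  sizes <- matrix(stats::rnorm(4L * n_trials, 0, noise_sd),
                  nrow = n_trials, ncol = 4L)
  correct <- sample.int(4L, n_trials, replace = TRUE)
  sizes[cbind(seq_len(n_trials), correct)] <- 0
  trials_df(n_trials, geometry$condition, eccentricity, sizes, correct)
}

#' Assemble a trial data frame from its parts
#'
#' Low-level constructor for the canonical trial-table layout used by
#' all generators and the fitter.
#'
#' @param n_trials Number of trials.
#' @param condition Condition label.
#' @param eccentricity Eccentricity in degrees.
#' @param sizes n x 4 matrix of log-size offsets.
#' @param correct Integer vector of correct locations (NA when no
#'   target offset is exactly zero).
#' @return Trial data frame with `chosen_loc` unset.
#' @export
trials_df <- function(n_trials, condition, eccentricity, sizes, correct) {
  data.frame(
    trial_id = seq_len(n_trials),
    condition = condition,
    eccentricity_deg = eccentricity,
    s1 = sizes[, 1L], s2 = sizes[, 2L], s3 = sizes[, 3L], s4 = sizes[, 4L],
    correct_loc = correct,
    chosen_loc = NA_integer_
  )
}

#' Extract the n x 4 size matrix from a trial data frame
#' @param trials Trial data frame.
#' @return Numeric matrix, one row per trial, columns = locations 1-4.
#' @export
trial_sizes <- function(trials) {
  as.matrix(trials[, c("s1", "s2", "s3", "s4")])
}

#' Cartesian visual-field coordinates of the four target positions
#'
#' @param geometry A [stimulus_geometry()].
#' @param eccentricity Radial distance from fixation in degrees.
#' @return Data frame with columns `location`, `quadrant`, `polar_deg`,
#'   `x`, `y` (degrees, y up).
#' @export
target_positions <- function(geometry = stimulus_geometry(),
                             eccentricity = 3.92) {
  stopifnot(eccentricity > 0)
  ang <- geometry$polar_angles
  data.frame(
    location = 1:4,
    quadrant = quadrant_labels(),
    polar_deg = ang,
    x = eccentricity * cos(ang * pi / 180),
    y = eccentricity * sin(ang * pi / 180)
  )
}

#' Quadrant labels in location order
#' @return Character vector of length 4.
#' @export
quadrant_labels <- function() {
  c("upper_left", "upper_right", "lower_left", "lower_right")
}

#' Generate a full MAPS session
#'
#' A session consists of runs of `n_blocks` blocks of `n_per_block`
#' trials each (block structure is recorded as metadata only; the
#' analysis ignores it).
#'
#' @param variant `"fixed"` or `"gaussian"` trial generator.
#' @param n_blocks Blocks per run (default 10).
#' @param n_per_block Trials per block (default 20).
#' @inheritParams draw_gaussian_trials
#' @return Trial data frame with an extra `block` column.
#' @export
maps_session <- function(variant = c("gaussian", "fixed"),
                         geometry = stimulus_geometry(),
                         eccentricity = 3.92,
                         n_blocks = 10L, n_per_block = 20L,
                         noise_sd = 0.3) {
  variant <- match.arg(variant)
  n <- n_blocks * n_per_block
  trials <- switch(variant,
    gaussian = draw_gaussian_trials(n, geometry, eccentricity, noise_sd),
    fixed = draw_fixed_set_trials(n, geometry, eccentricity)
  )
  trials$block <- rep(seq_len(n_blocks), each = n_per_block)
  trials
}
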