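#' Configuration of the 1D population read-out model
#'
#' The read-out model represents one screen column as a vector of
#' pixels; stimulus edges are marked with 1 against a 0 background and
#' passed through a bank of Gaussian spatial filters, one centred on
#' each pixel. The filter tuning width may be constant or vary with
#' pixel position (e.g. growing with eccentricity from the vector
#' centre), mirroring the growth of receptive field size across the
#' visual field.
#'
#' @param n_pixels Length of the pixel vector (default 1050, the screen
#'   height of the original display).
#' @param px_per_deg Pixels per degree of visual angle (default 30).
#' @param width_fn Either a single positive number (constant tuning
#'   width, in pixels) or a function of pixel position (1-based index)
#'   returning positive widths in pixels.
#' @return Object of class `readout_config`.
#' @export
readout_config <- function(n_pixels = 1050L, px_per_deg = 30,
                           width_fn = 10) {
  stopifnot(n_pixels > 0, px_per_deg > 0)
  if (is.numeric(width_fn)) {
    w <- width_fn
    stopifnot(length(w) == 1L, w > 0)
    width_fn <- function(p) rep(w, length(p))
  }
  wtest <- width_fn(seq_len(n_pixels))
  if (any(wtest <= 0)) stop("width_fn must be positive everywhere")
  structure(
    list(n_pixels = as.integer(n_pixels), px_per_deg = px_per_deg,
         width_fn = width_fn),
    class = "readout_config"
  )
}

#' Linear eccentricity-dependent tuning width
#'
#' Helper constructing a width function that grows linearly with
#' distance from a centre pixel, emulating the increase of spatial
#' tuning width with eccentricity.
#'
#' @param w0 Width at the centre pixel (pixels, > 0).
#' @param slope Increase in width per pixel of distance from centre.
#' @param center_px Centre pixel (1-based).
#' @return Function usable as `width_fn` in [readout_config()].
#' @export
linear_width_fn <- function(w0, slope, center_px) {
  stopifnot(w0 > 0, slope >= 0)
  function(p) w0 + slope * abs(p - center_px)
}

#' Rasterise stimulus edges into a binary pixel vector
#'
#' Marks the two edge pixels of the target circle (centre +/- half the
#' diameter, in pixels, rounded) with 1; Delboeuf stimuli additionally
#' mark the two inducer edges. All other pixels are 0.
#'
#' @param geometry A [stimulus_geometry()].
#' @param config A [readout_config()].
#' @param center_px Pixel position of the stimulus centre (1-based).
#' @param target_offset Log-size offset of the target in binary-log
#'   units (0 = reference size).
#' @return Binary integer vector of length `config$n_pixels` with
#'   attribute `edges` (target edge pixels) and, for Delboeuf stimuli,
#'   `inducer_edges`.
#' @export
rasterize_edges <- function(geometry, config,
                            center_px = (config$n_pixels + 1) / 2,
                            target_offset = 0) {
  v <- integer(config$n_pixels)
  if (is.null(geometry)) return(v)  # empty display
  diam <- geometry$reference_diameter * 2^target_offset
  half <- diam / 2 * config$px_per_deg
  edges <- round(c(center_px - half, center_px + half))
  pix <- edges
  if (geometry$condition == "delboeuf") {
    ih <- geometry$inducer_diameter / 2 * config$px_per_deg
    ind <- round(c(center_px - ih, center_px + ih))
    pix <- c(pix, ind)
  }
  if (any(pix < 1L | pix > config$n_pixels)) {
    stop("stimulus edges fall outside the pixel vector")
  }
  v[pix] <- 1L
  attr(v, "edges") <- edges
  if (geometry$condition == "delboeuf") attr(v, "inducer_edges") <- ind
  v
}

#' Population activity profile of the Gaussian filter bank
#'
#' The filter centred on pixel p responds with
#' `sum_x edge[x] * exp(-(x - p)^2 / (2 w(p)^2))`; with constant width
#' this is a sum of unit Gaussians centred on the marked edges.
#'
#' @param edge_vector Binary vector from [rasterize_edges()] (any
#'   nonnegative weights are accepted).
#' @param config A [readout_config()].
#' @return Object of class `activity_profile`: list with `activity`,
#'   `edge_positions`, `tuning_width` (per-pixel widths).
#' @export
population_profile <- function(edge_vector, config) {
  n <- config$n_pixels
  stopifnot(length(edge_vector) == n)
  pos <- which(edge_vector != 0)
  w <- config$width_fn(seq_len(n))
  act <- numeric(n)
  p <- seq_len(n)
  for (x in pos) {
    act <- act + edge_vector[x] * exp(-(x - p)^2 / (2 * w^2))
  }
  structure(
    list(activity = act, edge_positions = attr(edge_vector, "edges"),
         inducer_edges = attr(edge_vector, "inducer_edges"),
         tuning_width = w),
    class = "activity_profile"
  )
}

#' Locate strict local maxima of an activity profile
#'
#' Plateaus count as a single peak at the plateau centre.
#'
#' @param profile An `activity_profile` (or a bare numeric vector).
#' @param refine Use quadratic interpolation around each maximum for
#'   sub-pixel localisation (default TRUE).
#' @return Numeric vector of peak positions (pixels, possibly
#'   fractional when `refine = TRUE`).
#' @export
find_peaks <- function(profile, refine = TRUE) {
  a <- if (inherits(profile, "activity_profile")) profile$activity else profile
  n <- length(a)
  if (diff(range(a)) == 0) stop("constant activity profile has no peaks")
  # run-length encode so plateau maxima resolve to their centres
  r <- rle(a)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  peaks <- numeric(0)
  for (i in seq_len(k)) {
    left_ok <- i == 1L || r$values[i - 1L] < r$values[i]
    right_ok <- i == k || r$values[i + 1L] < r$values[i]
    if (left_ok && right_ok) {
      center <- (starts[i] + ends[i]) / 2
      if (refine && r$lengths[i] == 1L && starts[i] > 1L && ends[i] < n) {
        p <- starts[i]
        y1 <- a[p - 1L]; y2 <- a[p]; y3 <- a[p + 1L]
        denom <- y1 - 2 * y2 + y3
        if (denom < 0) center <- p + 0.5 * (y1 - y3) / denom
      }
      peaks <- c(peaks, center)
    }
  }
  peaks
}

#' Infer stimulus size from the activity-peak separation
#'
#' The estimated extent is the separation of the two local maxima
#' nearest the target's true edge positions; when the profile has
#' collapsed to a single peak the estimate is flagged as merged. The
#' predicted perceptual bias is `log2(true extent / estimated extent)`,
#' positive when the stimulus is perceived as smaller than it is.
#'
#' @param profile An `activity_profile` from [population_profile()].
#' @param refine Passed to [find_peaks()].
#' @return List of class `size_estimate`: `estimated_extent` (pixels,
#'   NA when merged), `true_extent`, `merged`, `predicted_bias`
#'   (binary-log units, NA when merged).
#' @export
estimate_size <- function(profile, refine = TRUE) {
  edges <- profile$edge_positions
  stopifnot(length(edges) == 2L)
  true_extent <- abs(diff(edges))
  peaks <- find_peaks(profile, refine = refine)
  merged <- length(peaks) < 2L
  if (!merged) {
    left <- peaks[which.min(abs(peaks - edges[1L]))]
    right <- peaks[which.min(abs(peaks - edges[2L]))]
    merged <- isTRUE(all.equal(left, right))
  }
  if (merged) {
    est <- NA_real_
    bias <- NA_real_
  } else {
    est <- abs(right - left)
    bias <- log2(true_extent / est)
  }
  structure(
    list(estimated_extent = est, true_extent = true_extent,
         merged = merged, predicted_bias = bias),
    class = "size_estimate"
  )
}

#' Simulated perceptual bias curves across tuning widths
#'
#' For each tuning width, simulates the read-out of an isolated target
#' circle and of the same target inside a Delboeuf inducer, and records
#' the predicted biases and the relative illusion strength (isolated
#' minus Delboeuf).
#'
#' @param width_grid Ascending positive tuning widths in pixels.
#' @param geometry_isolated,geometry_delboeuf Stimulus geometries for
#'   the two conditions (defaults: the standard reference/inducer
#'   sizes).
#' @param n_pixels,px_per_deg Passed to [readout_config()].
#' @param refine Sub-pixel peak localisation toggle.
#' @return Data frame with columns `width_px`, `width_deg`,
#'   `bias_isolated`, `bias_delboeuf`, `relative_illusion`,
#'   `merged_isolated`, `merged_delboeuf`. Merged cells carry NA biases.
#' @export
simulate_bias_curves <- function(width_grid,
                                 geometry_isolated =
                                   stimulus_geometry(condition = "isolated"),
                                 geometry_delboeuf =
                                   stimulus_geometry(condition = "delboeuf"),
                                 n_pixels = 1050L, px_per_deg = 30,
                                 refine = TRUE) {
  stopifnot(all(width_grid > 0), !is.unsorted(width_grid))
  rows <- lapply(width_grid, function(w) {
    cfg <- readout_config(n_pixels, px_per_deg, width_fn = w)
    iso <- estimate_size(
      population_profile(rasterize_edges(geometry_isolated, cfg), cfg),
      refine = refine)
    del <- estimate_size(
      population_profile(rasterize_edges(geometry_delboeuf, cfg), cfg),
      refine = refine)
    data.frame(
      width_px = w, width_deg = w / px_per_deg,
      bias_isolated = iso$predicted_bias,
      bias_delboeuf = del$predicted_bias,
      relative_illusion = iso$predicted_bias - del$predicted_bias,
      merged_isolated = iso$merged, merged_delboeuf = del$merged
    )
  })
  do.call(rbind, rows)
}
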