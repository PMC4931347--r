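#' Configuration of the retinotopic mapping aperture sequence
#'
#' The mapping stimulus combines a rotating polar wedge (12 degrees of
#' polar angle, 60 one-second steps per rotation, 3 cycles) with a ring
#' that expands or contracts in 36 logarithmic steps per cycle over 5
#' cycles, both confined to a maximal eccentricity of 8.5 degrees. The
#' modelled sequence appends 45 s of fixation-only blanks, for 225
#' one-second volumes in total.
#'
#' @param grid_n Pixels per side of the square evaluation grid.
#' @param half_width Half-width of the grid in degrees (grid spans
#'   `[-half_width, half_width]` on both axes).
#' @param field_radius Maximal stimulus eccentricity in degrees.
#' @param wedge_width_deg Polar width of the wedge in degrees.
#' @param wedge_steps,wedge_cycles Steps per wedge rotation and number
#'   of rotations.
#' @param ring_steps,ring_cycles Logarithmic steps per ring cycle and
#'   number of cycles.
#' @param ring_outer_min Outer radius of the smallest ring (degrees).
#' @param ring_ratio Inner/outer radius ratio of the ring annulus, so
#'   ring width grows in proportion to its radius.
#' @param blank_volumes Trailing fixation-only volumes.
#' @param wedge_dir `"ccw"` or `"cw"` rotation.
#' @param ring_dir `"expand"` or `"contract"`.
#' @return Object of class `aperture_config`.
#' @export
aperture_config <- function(grid_n = 101L, half_width = 9,
                            field_radius = 8.5,
                            wedge_width_deg = 12,
                            wedge_steps = 60L, wedge_cycles = 3L,
                            ring_steps = 36L, ring_cycles = 5L,
                            ring_outer_min = 0.6, ring_ratio = 0.7,
                            blank_volumes = 45L,
                            wedge_dir = c("ccw", "cw"),
                            ring_dir = c("expand", "contract")) {
  stopifnot(grid_n >= 11L, half_width >= field_radius,
            ring_outer_min > 0, ring_outer_min < field_radius,
            ring_ratio > 0, ring_ratio < 1)
  structure(
    list(grid_n = as.integer(grid_n), half_width = half_width,
         field_radius = field_radius, wedge_width_deg = wedge_width_deg,
         wedge_steps = as.integer(wedge_steps),
         wedge_cycles = as.integer(wedge_cycles),
         ring_steps = as.integer(ring_steps),
         ring_cycles = as.integer(ring_cycles),
         ring_outer_min = ring_outer_min, ring_ratio = ring_ratio,
         blank_volumes = as.integer(blank_volumes),
         wedge_dir = match.arg(wedge_dir),
         ring_dir = match.arg(ring_dir)),
    class = "aperture_config"
  )
}

grid_axes <- function(config) {
  seq(-config$half_width, config$half_width, length.out = config$grid_n)
}

#' Outer radii of the ring across one cycle
#'
#' The radius sequence is geometric from `ring_outer_min` to the field
#' radius (logarithmic steps), reversed for contracting rings.
#'
#' @param config An [aperture_config()].
#' @return Numeric vector of length `ring_steps`.
#' @export
ring_radius_sequence <- function(config) {
  r <- exp(seq(log(config$ring_outer_min), log(config$field_radius),
               length.out = config$ring_steps))
  if (config$ring_dir == "contract") r <- rev(r)
  r
}

#' Wedge start angles (degrees, polar) across one rotation
#'
#' The wedge advances by `360 / wedge_steps` degrees per volume,
#' counterclockwise by default.
#'
#' @param config An [aperture_config()].
#' @return Numeric vector of length `wedge_steps`.
#' @export
wedge_angle_sequence <- function(config) {
  step <- 360 / config$wedge_steps
  a <- (seq_len(config$wedge_steps) - 1L) * step
  if (config$wedge_dir == "cw") a <- (-a) %% 360
  a
}

#' Build the binary aperture sequence of the mapping stimulus
#'
#' Each volume's mask is the union of the wedge sector and the ring
#' annulus for that second, clipped to the mapped field; the sequence
#' ends with blank volumes.
#'
#' @param config An [aperture_config()].
#' @return Object of class `aperture_sequence`: list with `masks`
#'   (matrix, pixels x volumes, values 0/1), `config`, `x`, `y` (pixel
#'   centre coordinates in degrees, y up), and `n_volumes`.
#' @export
build_apertures <- function(config = aperture_config()) {
  ax <- grid_axes(config)
  gx <- rep(ax, times = config$grid_n)
  gy <- rep(ax, each = config$grid_n)
  rad <- sqrt(gx^2 + gy^2)
  theta <- (atan2(gy, gx) * 180 / pi) %% 360
  in_field <- rad <= config$field_radius

  n_stim <- config$wedge_steps * config$wedge_cycles
  stopifnot(n_stim == config$ring_steps * config$ring_cycles)
  n_vol <- n_stim + config$blank_volumes

  wedge_a <- wedge_angle_sequence(config)
  ring_r <- ring_radius_sequence(config)
  masks <- matrix(0, nrow = length(gx), ncol = n_vol)
  for (v in seq_len(n_stim)) {
    a0 <- wedge_a[((v - 1L) %% config$wedge_steps) + 1L]
    dtheta <- (theta - a0) %% 360
    wedge <- dtheta <= config$wedge_width_deg
    r_out <- ring_r[((v - 1L) %% config$ring_steps) + 1L]
    ring <- rad <= r_out & rad >= r_out * config$ring_ratio
    masks[, v] <- as.numeric((wedge | ring) & in_field)
  }
  structure(
    list(masks = masks, config = config, x = gx, y = gy,
         n_volumes = n_vol),
    class = "aperture_sequence"
  )
}
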