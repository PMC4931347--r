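#' Assign a visual-field quadrant to a polar angle
#'
#' Polar angle 0 is the right horizontal meridian, increasing
#' counterclockwise, y up. Quadrants follow the location convention
#' 1 = upper-left, 2 = upper-right, 3 = lower-left, 4 = lower-right;
#' angles exactly on a meridian are assigned to the adjacent quadrant
#' with the lower index.
#'
#' @param polar_angle Angle(s) in degrees (any value; reduced mod 360).
#' @return Character vector of quadrant labels.
#' @export
assign_quadrant <- function(polar_angle) {
  a <- polar_angle %% 360
  labels <- quadrant_labels()
  # quadrant index by sector: (0,90) UR=2, (90,180) UL=1,
  # (180,270) LL=3, (270,360) LR=4
  sector_idx <- c(2L, 1L, 3L, 4L)
  vapply(a, function(ang) {
    if (ang %% 90 == 0) {
      k <- (ang / 90) %% 4              # meridian between two sectors
      before <- sector_idx[(as.integer(k - 1) %% 4L) + 1L]
      after <- sector_idx[as.integer(k) + 1L]
      labels[min(before, after)]
    } else {
      labels[sector_idx[floor(ang / 90) + 1L]]
    }
  }, character(1))
}

#' Eccentricity-band summaries of pRF spread or surface area
#'
#' Vertices are divided into 1-degree half-open eccentricity bands
#' `[k, k+1)` for k = 1..8. For spread the band statistic is the mean
#' with a percentile-bootstrap 95% confidence interval; for area it is
#' the band sum.
#'
#' @param vertices Vertex data frame with columns `ecc_deg` and
#'   `sigma_deg` (spread) or `area_mm2`, typically already filtered to
#'   one region and quadrant.
#' @param statistic `"spread"` or `"area"`.
#' @param n_boot Bootstrap resamples for the spread CI (default 1000).
#' @param band_edges Band boundaries (default 1:9).
#' @return Data frame with `band_lo`, `band_hi`, `center`, `n`,
#'   `value`, and (for spread) `ci_lo`, `ci_hi`. Empty bands carry NA
#'   values and `n = 0`.
#' @export
band_summaries <- function(vertices, statistic = c("spread", "area"),
                           n_boot = 1000L, band_edges = 1:9) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "spread") "sigma_deg" else "area_mm2"
  stopifnot(col %in% names(vertices))
  lo <- band_edges[-length(band_edges)]
  hi <- band_edges[-1L]
  rows <- lapply(seq_along(lo), function(i) {
    v <- vertices[[col]][vertices$ecc_deg >= lo[i] & vertices$ecc_deg < hi[i]]
    n <- length(v)
    if (statistic == "area") {
      data.frame(band_lo = lo[i], band_hi = hi[i],
                 center = (lo[i] + hi[i]) / 2, n = n,
                 value = if (n > 0L) sum(v) else NA_real_)
    } else {
      if (n == 0L) {
        return(data.frame(band_lo = lo[i], band_hi = hi[i],
                          center = (lo[i] + hi[i]) / 2, n = 0L,
                          value = NA_real_, ci_lo = NA_real_,
                          ci_hi = NA_real_))
      }
      bm <- vapply(seq_len(n_boot), function(b) {
        mean(v[sample.int(n, n, replace = TRUE)])
      }, numeric(1))
      ci <- stats::quantile(bm, c(0.025, 0.975), names = FALSE)
      data.frame(band_lo = lo[i], band_hi = hi[i],
                 center = (lo[i] + hi[i]) / 2, n = n, value = mean(v),
                 ci_lo = ci[1L], ci_hi = ci[2L])
    }
  })
  do.call(rbind, rows)
}

#' Fit a polynomial eccentricity profile to band summaries
#'
#' pRF spread is fitted with a first-order (linear) polynomial of band
#' value on band-centre eccentricity; surface area with a second-order
#' polynomial.
#'
#' @param bands Output of [band_summaries()].
#' @param kind `"spread"` (degree 1) or `"area"` (degree 2).
#' @return Object of class `ecc_profile`: list with `coefficients`
#'   (ascending powers), `degree`, `kind`, `range` (fitted
#'   eccentricity range), and `residuals`.
#' @export
fit_ecc_profile <- function(bands, kind = c("spread", "area")) {
  kind <- match.arg(kind)
  degree <- if (kind == "spread") 1L else 2L
  keep <- !is.na(bands$value)
  if (sum(keep) < degree + 1L) {
    stop("need at least ", degree + 1L, " non-empty bands")
  }
  x <- bands$center[keep]
  y <- bands$value[keep]
  X <- stats::poly(x, degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), y)
  structure(
    list(coefficients = unname(fit$coefficients), degree = degree,
         kind = kind, range = range(bands$band_lo, bands$band_hi),
         residuals = unname(fit$residuals)),
    class = "ecc_profile"
  )
}

#' Evaluate an eccentricity profile at stimulus eccentricities
#'
#' Interpolates (or extrapolates) the fitted polynomial at the target
#' eccentricities used behaviourally. Values outside the fitted band
#' range are flagged as extrapolations, and negative predicted spreads
#' are flagged.
#'
#' @param profile An `ecc_profile`.
#' @param ecc Eccentricities in degrees (default the standard
#'   1.96, 3.92, 7.84 set).
#' @return Data frame with `ecc`, `value`, `extrapolated`, `negative`.
#' @export
value_at_eccentricity <- function(profile, ecc = c(1.96, 3.92, 7.84)) {
  powers <- 0:profile$degree
  val <- vapply(ecc, function(e) sum(profile$coefficients * e^powers),
                numeric(1))
  data.frame(
    ecc = ecc, value = val,
    extrapolated = ecc < profile$range[1L] | ecc > profile$range[2L],
    negative = profile$kind == "spread" & val < 0
  )
}

#' Macroscopic surface area of one quadrant map
#'
#' Sums vertex surface area over eccentricities 1 to 9 degrees
#' (inclusive on both ends) and normalises per the chosen mode.
#'
#' @param vertices Vertex data frame (one quadrant) with `ecc_deg` and
#'   `area_mm2`.
#' @param normalization `"percent"` (percent of whole-cortex area),
#'   `"sqrt"` (square root of the absolute area, mm), or
#'   `"absolute"` (mm^2).
#' @param cortex_area Whole-cortex surface area in mm^2 (required for
#'   `"percent"`).
#' @param ecc_range Inclusive eccentricity limits (default 1 to 9).
#' @return Scalar area measure.
#' @export
quadrant_surface_area <- function(vertices,
                                  normalization = c("percent", "sqrt",
                                                    "absolute"),
                                  cortex_area = NULL,
                                  ecc_range = c(1, 9)) {
  normalization <- match.arg(normalization)
  keep <- vertices$ecc_deg >= ecc_range[1L] & vertices$ecc_deg <= ecc_range[2L]
  total <- sum(vertices$area_mm2[keep])
  switch(normalization,
    percent = {
      if (is.null(cortex_area) || cortex_area <= 0) {
        stop("percent normalization requires a positive cortex_area")
      }
      100 * total / cortex_area
    },
    sqrt = sqrt(total),
    absolute = total
  )
}

#' Per-location cortical predictors for one observer
#'
#' Summarises a vertex table into the 12 per-location predictors used
#' by the statistics: for every quadrant, the fitted pRF spread and
#' local surface area evaluated at each stimulus eccentricity, plus
#' the normalised quadrant surface area.
#'
#' @param vertices Vertex data frame with columns `quadrant`,
#'   `ecc_deg`, `sigma_deg`, `area_mm2`.
#' @param ecc Stimulus eccentricities.
#' @param cortex_area Whole-cortex area in mm^2 for the percent
#'   normalisation.
#' @param n_boot Bootstrap resamples for band CIs.
#' @return Data frame: `quadrant`, `location`, `ecc`, `spread_hat`,
#'   `local_area`, `quadrant_area_pct`.
#' @export
summarize_cortex <- function(vertices, ecc = c(1.96, 3.92, 7.84),
                             cortex_area = 1e5, n_boot = 200L) {
  labels <- quadrant_labels()
  rows <- lapply(seq_along(labels), function(qi) {
    vq <- vertices[vertices$quadrant == labels[qi], , drop = FALSE]
    sp <- fit_ecc_profile(band_summaries(vq, "spread", n_boot = n_boot),
                          "spread")
    ar <- fit_ecc_profile(band_summaries(vq, "area"), "area")
    qa <- quadrant_surface_area(vq, "percent", cortex_area = cortex_area)
    data.frame(
      quadrant = labels[qi], location = qi, ecc = ecc,
      spread_hat = value_at_eccentricity(sp, ecc)$value,
      local_area = value_at_eccentricity(ar, ecc)$value,
      quadrant_area_pct = qa
    )
  })
  do.call(rbind, rows)
}
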