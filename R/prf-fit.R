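#' Predicted BOLD time series of a 2D Gaussian pRF
#'
#' The pRF is a 2D isotropic Gaussian in visual space. For every
#' volume, the overlap between the Gaussian profile and the binary
#' aperture is computed on the evaluation grid; the overlap series is
#' z-standardised, convolved with the HRF, and the final series is
#' z-scored again (so the prediction is amplitude-free).
#'
#' @param x,y pRF centre in degrees (y up).
#' @param spread pRF spread (Gaussian SD) in degrees, > 0.
#' @param apertures An `aperture_sequence` from [build_apertures()].
#' @param hrf HRF parameter list (see [default_hrf()]) or an `hrf_fit`.
#' @param tr Sampling interval in seconds.
#' @param convolve_first If TRUE, convolve the raw overlap series with
#'   the HRF before z-scoring (sensitivity-check variant); the default
#'   follows z-score-then-convolve.
#' @return Numeric z-scored series of length `apertures$n_volumes`.
#'   A pRF with (numerically) no overlap variance anywhere in the
#'   sequence yields an all-zero series with attribute
#'   `degenerate = TRUE`.
#' @export
predict_timeseries <- function(x, y, spread, apertures,
                               hrf = default_hrf(), tr = 1,
                               convolve_first = FALSE) {
  stopifnot(spread > 0)
  g <- prf_gaussian_field(x, y, spread, apertures)
  overlap <- as.numeric(crossprod(apertures$masks, g))
  hk <- hrf_kernel(hrf, tr = tr)
  n <- length(overlap)
  if (stats::sd(overlap) < 1e-12) {
    out <- numeric(n)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  s <- if (convolve_first) overlap else as.numeric(scale(overlap))
  conv <- stats::convolve(c(s, numeric(length(hk))), rev(hk),
                          type = "open")[seq_len(n)]
  out <- as.numeric(scale(conv))
  attr(out, "degenerate") <- FALSE
  out
}

prf_gaussian_field <- function(x, y, spread, apertures) {
  exp(-((apertures$x - x)^2 + (apertures$y - y)^2) / (2 * spread^2))
}

#' The coarse search grid of candidate pRF parameters
#'
#' 15 evenly spaced values per spatial axis crossed with 34 spreads in
#' logarithmic steps of 0.2 binary-log units starting at 0.18 degrees
#' (0.18 * 2^(0.2 k), k = 0..33), i.e. 15 x 15 x 34 = 7650 candidates.
#'
#' @param x_range,y_range Spatial extents in degrees.
#' @param n_xy Values per spatial axis.
#' @param spread_min Smallest spread (degrees).
#' @param n_spread Number of spread steps.
#' @param spread_step Log2 step between spreads.
#' @return Data frame with columns `x`, `y`, `spread`.
#' @export
prf_search_grid <- function(x_range = c(-9, 9), y_range = c(-9, 9),
                            n_xy = 15L, spread_min = 0.18,
                            n_spread = 34L, spread_step = 0.2) {
  xs <- seq(x_range[1L], x_range[2L], length.out = n_xy)
  ys <- seq(y_range[1L], y_range[2L], length.out = n_xy)
  spreads <- spread_min * 2^(spread_step * (seq_len(n_spread) - 1L))
  out <- expand.grid(x = xs, y = ys, spread = spreads,
                     KEEP.OUT.ATTRS = FALSE)
  out[, c("x", "y", "spread")]
}

#' Precompute predicted series for every grid candidate
#'
#' The grid predictions depend only on the aperture sequence and HRF,
#' so they are computed once and reused across all units.
#'
#' @param apertures An `aperture_sequence`.
#' @param hrf HRF parameters.
#' @param grid Candidate table from [prf_search_grid()].
#' @param tr Sampling interval (seconds).
#' @return Object of class `prf_grid_predictions`: list with `grid`
#'   and `predictions` (volumes x candidates matrix; degenerate
#'   candidates are all-NA columns).
#' @export
prf_grid_predictions <- function(apertures, hrf = default_hrf(),
                                 grid = prf_search_grid(), tr = 1) {
  masks_t <- t(apertures$masks)
  n_vol <- nrow(masks_t)
  hk <- hrf_kernel(hrf, tr = tr)
  pred <- matrix(NA_real_, nrow = n_vol, ncol = nrow(grid))
  for (s in unique(grid$spread)) {
    idx <- which(grid$spread == s)
    G <- vapply(idx, function(i) {
      prf_gaussian_field(grid$x[i], grid$y[i], s, apertures)
    }, numeric(length(apertures$x)))
    ov <- masks_t %*% G
    sds <- apply(ov, 2L, stats::sd)
    ok <- sds > 1e-12
    if (any(ok)) {
      z <- scale(ov[, ok, drop = FALSE])
      cz <- apply(z, 2L, function(col) {
        stats::convolve(c(col, numeric(length(hk))), rev(hk),
                        type = "open")[seq_len(n_vol)]
      })
      pred[, idx[ok]] <- scale(cz)
    }
  }
  structure(list(grid = grid, predictions = pred),
            class = "prf_grid_predictions")
}

#' Coarse grid fit of a pRF by maximal correlation
#'
#' Exhaustively correlates the observed series with every candidate's
#' predicted series and returns the best candidate.
#'
#' @param observed Numeric series (one unit) or a volumes x units
#'   matrix.
#' @param grid_pred A `prf_grid_predictions` object.
#' @return For a single unit, a list with `x`, `y`, `spread`, `r`;
#'   for a matrix, a data frame with one row per unit.
#' @export
coarse_fit <- function(observed, grid_pred) {
  single <- is.null(dim(observed))
  obs <- if (single) matrix(observed, ncol = 1L) else observed
  stopifnot(nrow(obs) == nrow(grid_pred$predictions))
  ok <- !is.na(grid_pred$predictions[1L, ])
  if (!any(ok)) stop("no valid grid candidates")
  r <- suppressWarnings(
    stats::cor(obs, grid_pred$predictions[, ok, drop = FALSE])
  )
  r[!is.finite(r)] <- -Inf
  if (all(r == -Inf)) stop("all candidate correlations undefined")
  best <- max.col(r, ties.method = "first")
  idx <- which(ok)[best]
  out <- data.frame(unit = seq_len(ncol(obs)),
                    x = grid_pred$grid$x[idx],
                    y = grid_pred$grid$y[idx],
                    spread = grid_pred$grid$spread[idx],
                    r = r[cbind(seq_len(ncol(obs)), best)])
  if (single) as.list(out[1L, c("x", "y", "spread", "r")]) else out
}

prf_sse <- function(par_xy_logs, observed, apertures, hrf, tr,
                    convolve_first) {
  pred <- predict_timeseries(par_xy_logs[1L], par_xy_logs[2L],
                             exp(par_xy_logs[3L]), apertures, hrf,
                             tr = tr, convolve_first = convolve_first)
  if (isTRUE(attr(pred, "degenerate"))) return(sum(observed^2))
  a <- sum(pred * observed) / sum(pred * pred)
  sum((observed - a * pred)^2)
}

#' Fine pRF fit by simplex refinement
#'
#' Refines the coarse-fit seed by Nelder-Mead search over x, y,
#' log-spread, minimising the squared residuals between the predicted
#' and observed series; the response amplitude is estimated by least
#' squares at every step (a fourth, analytically profiled parameter).
#' If the search fails to improve on the seed, the seed is returned
#' with a warning.
#'
#' @param observed Numeric observed series for one unit (z-scored).
#' @param seed List with `x`, `y`, `spread` (typically from
#'   [coarse_fit()]).
#' @param apertures An `aperture_sequence`.
#' @param hrf HRF parameters.
#' @param tr Sampling interval (seconds).
#' @param convolve_first Passed to [predict_timeseries()].
#' @param maxit Simplex iteration cap.
#' @return List with `x`, `y`, `spread`, `amplitude`, `sse`,
#'   `seed_sse`, and `r` (correlation of the final prediction).
#' @export
fine_fit <- function(observed, seed, apertures, hrf = default_hrf(),
                     tr = 1, convolve_first = FALSE, maxit = 400L) {
  par0 <- c(seed$x, seed$y, log(seed$spread))
  seed_sse <- prf_sse(par0, observed, apertures, hrf, tr, convolve_first)
  opt <- stats::optim(par0, prf_sse, observed = observed,
                      apertures = apertures, hrf = hrf, tr = tr,
                      convolve_first = convolve_first,
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-10))
  if (!is.finite(opt$value) || opt$value > seed_sse) {
    warning("fine fit did not improve on the coarse seed; returning seed")
    par <- par0
    sse <- seed_sse
  } else {
    par <- opt$par
    sse <- opt$value
  }
  pred <- predict_timeseries(par[1L], par[2L], exp(par[3L]), apertures,
                             hrf, tr = tr, convolve_first = convolve_first)
  a <- if (isTRUE(attr(pred, "degenerate"))) 0 else {
    sum(pred * observed) / sum(pred * pred)
  }
  r <- if (a == 0) NA_real_ else stats::cor(observed, pred)
  list(x = par[1L], y = par[2L], spread = exp(par[3L]), amplitude = a,
       sse = sse, seed_sse = seed_sse, r = r)
}

#' Preprocess raw mapping runs for pRF fitting
#'
#' Each run is linearly detrended per unit, z-standardised, averaged
#' within its stimulus-direction group, and the two group averages are
#' concatenated in time.
#'
#' @param runs List of volumes x units matrices, all of equal
#'   dimension.
#' @param directions Character/factor vector, one entry per run, with
#'   exactly two distinct values (e.g. `"cw_exp"`, `"ccw_con"`).
#' @return Matrix of dimension (2 x volumes) x units with attribute
#'   `excluded_units` listing units that had zero variance in some run
#'   (their output is zero there).
#' @export
preprocess_series <- function(runs, directions) {
  stopifnot(length(runs) == length(directions), length(runs) >= 2L)
  dims <- vapply(runs, dim, integer(2))
  stopifnot(all(dims[1L, ] == dims[1L, 1L]), all(dims[2L, ] == dims[2L, 1L]))
  groups <- unique(directions)
  if (length(groups) != 2L) stop("exactly two stimulus-direction groups required")
  n_vol <- dims[1L, 1L]
  tt <- seq_len(n_vol)
  clean <- lapply(runs, function(m) {
    apply(m, 2L, function(v) {
      res <- stats::residuals(stats::lm.fit(cbind(1, tt), v))
      s <- stats::sd(res)
      if (s < 1e-12) numeric(n_vol) else res / s
    })
  })
  excluded <- sort(unique(unlist(lapply(clean, function(m) {
    which(apply(m, 2L, function(v) all(v == 0)))
  }))))
  avg <- lapply(groups, function(g) {
    ms <- clean[directions == g]
    Reduce(`+`, ms) / length(ms)
  })
  out <- rbind(avg[[1L]], avg[[2L]])
  attr(out, "excluded_units") <- excluded
  out
}

#' Fit pRFs for a matrix of observed series (coarse + fine)
#'
#' @param observed Volumes x units matrix.
#' @param apertures An `aperture_sequence`.
#' @param hrf HRF parameters.
#' @param grid Candidate grid (default [prf_search_grid()]).
#' @param grid_pred Optional precomputed `prf_grid_predictions`.
#' @param fine Run the fine stage (default TRUE).
#' @return Data frame: unit, x, y, spread, amplitude, r.
#' @export
fit_prf <- function(observed, apertures, hrf = default_hrf(),
                    grid = prf_search_grid(), grid_pred = NULL,
                    fine = TRUE) {
  if (is.null(grid_pred)) {
    grid_pred <- prf_grid_predictions(apertures, hrf, grid)
  }
  coarse <- coarse_fit(observed, grid_pred)
  if (!fine) {
    coarse$amplitude <- NA_real_
    return(coarse)
  }
  rows <- lapply(seq_len(nrow(coarse)), function(i) {
    f <- fine_fit(observed[, i], as.list(coarse[i, c("x", "y", "spread")]),
                  apertures, hrf)
    data.frame(unit = i, x = f$x, y = f$y, spread = f$spread,
               amplitude = f$amplitude, r = f$r)
  })
  do.call(rbind, rows)
}
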