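#' Two-gamma haemodynamic response function
#'
#' The HRF is modelled as the difference of two gamma density terms:
#' a positive response peaking at `peak_latency` and an undershoot
#' peaking at `undershoot_latency`, scaled down by `1 / ratio` relative
#' to the peak, all multiplied by `amplitude`. Gamma shapes are chosen
#' so the mode of each term equals its latency (unit rate).
#'
#' @param t Time since stimulus onset in seconds, >= 0.
#' @param amplitude Overall scale.
#' @param peak_latency Latency of the response peak in seconds, > 0.
#' @param undershoot_latency Latency of the undershoot in seconds, > 0.
#' @param ratio Peak-to-undershoot amplitude ratio, > 0; large values
#'   remove the undershoot.
#' @return HRF value(s) at `t`.
#' @export
two_gamma <- function(t, amplitude = 1, peak_latency = 5,
                      undershoot_latency = 15, ratio = 6) {
  if (peak_latency <= 0 || undershoot_latency <= 0 || ratio <= 0) {
    stop("invalid HRF parameters")
  }
  if (any(t < 0)) stop("t must be nonnegative")
  amplitude * (stats::dgamma(t, shape = peak_latency + 1, rate = 1) -
                 stats::dgamma(t, shape = undershoot_latency + 1,
                               rate = 1) / ratio)
}

#' Default HRF parameter set
#' @return Named list of the four two-gamma parameters.
#' @export
default_hrf <- function() {
  list(amplitude = 1, peak_latency = 5, undershoot_latency = 15, ratio = 6)
}

hrf_kernel <- function(hrf, duration = 32, tr = 1) {
  t <- seq(0, duration, by = tr)
  two_gamma(t, hrf$amplitude, hrf$peak_latency, hrf$undershoot_latency,
            hrf$ratio)
}

#' Estimate the subject-level HRF from event-locked epochs
#'
#' Each unit (vertex) contributes a matrix of epochs (rows) by time
#' points (columns), aligned to 2-s stimulus onsets followed by a long
#' blank. Epochs are averaged within units; a unit is included only if
#' its average response minus the standard error, over the first half
#' of the epoch, is positive on average. Included units are averaged
#' and a two-gamma function (four free parameters) is fitted by
#' least squares.
#'
#' @param epoch_list List of numeric matrices, one per unit, each
#'   epochs x time (seconds at `tr` spacing).
#' @param tr Sampling interval in seconds (default 1).
#' @param stim_duration Stimulus duration in seconds (default 2); the
#'   fitted curve is the two-gamma convolved with this boxcar.
#' @return List of class `hrf_fit`: the four fitted parameters, the
#'   average response `curve`, fitted values `fitted`, included unit
#'   indices, and the residual sum of squares.
#' @export
fit_hrf <- function(epoch_list, tr = 1, stim_duration = 2) {
  stopifnot(length(epoch_list) >= 1L)
  unit_means <- lapply(epoch_list, colMeans)
  n_t <- length(unit_means[[1L]])
  first_half <- seq_len(floor(n_t / 2))
  included <- vapply(epoch_list, function(ep) {
    m <- colMeans(ep)
    se <- apply(ep, 2L, stats::sd) / sqrt(nrow(ep))
    mean(m[first_half] - se[first_half]) > 0
  }, logical(1))
  if (!any(included)) stop("no unit passes the HRF inclusion rule")
  curve <- colMeans(do.call(rbind, unit_means[included]))
  tt <- (seq_len(n_t) - 1L) * tr

  box <- rep(1, max(1L, round(stim_duration / tr)))
  predict_curve <- function(p) {
    h <- two_gamma(tt, 1, p[1L], p[2L], p[3L])
    y <- stats::convolve(c(h, numeric(length(box))), rev(box),
                         type = "open")[seq_len(n_t)]
    y
  }
  sse <- function(par) {
    p <- c(exp(par[1L]), exp(par[2L]), exp(par[3L]))
    y <- predict_curve(p)
    a <- sum(y * curve) / sum(y * y)   # profiled amplitude
    sum((curve - a * y)^2)
  }
  opt <- stats::optim(log(c(5, 15, 6)), sse, method = "Nelder-Mead",
                      control = list(maxit = 1000L, reltol = 1e-10))
  p <- exp(opt$par)
  y <- predict_curve(p)
  a <- sum(y * curve) / sum(y * y)
  structure(
    list(amplitude = a, peak_latency = p[1L], undershoot_latency = p[2L],
         ratio = p[3L], curve = curve, fitted = a * y,
         included = which(included), rss = opt$value),
    class = "hrf_fit"
  )
}
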