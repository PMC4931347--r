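#' Monte Carlo power and false-positive calibration of the tests
#'
#' Simulates location data sets with the study's clustered design (10
#' observers by 3 eccentricities by 4 quadrants = 120 paired
#' observations by default), applies the chosen analysis, and reports
#' the fraction of replicates rejecting at the given alpha together
#' with its binomial Monte Carlo standard error.
#'
#' The default generative model draws x and y location-wise from a
#' bivariate normal with correlation `true_r` and no shared cluster
#' effects (`true_r = 0` gives the i.i.d. null used for the nominal
#' false-positive rate). Optional observer- and eccentricity-level
#' variance components can be added to probe sensitivity to clustering.
#'
#' @param analysis `"pooled"` (Pearson over all locations),
#'   `"demeaned"` (observer-by-eccentricity means removed first, tested
#'   at nominal n), `"regression"` (variance-partitioned regression;
#'   rejection on the focal term given by `regression_term`), or
#'   `"second_level"` (within-cell correlations, Fisher-z t-test).
#' @param true_r Population correlation of the location-level pairs.
#' @param n_reps Number of simulated data sets (warning below 100).
#' @param alpha Two-sided significance level.
#' @param n_observers,n_ecc,n_quadrants Design dimensions.
#' @param observer_sd,ecc_sd SDs of optional shared cluster effects
#'   added to both variables (default 0 = no clustering).
#' @param regression_term Focal regressor tested in the
#'   `"regression"` analysis (default `"quadrant"`).
#' @return List of class `power_result`: `rate` (rejection fraction),
#'   `se` (binomial MC standard error), `n_reps`, `alpha`, `n`
#'   (observations per data set), `analysis`, `true_r`.
#' @export
power_fpr_simulation <- function(analysis = c("pooled", "demeaned",
                                              "regression", "second_level"),
                                 true_r = 0, n_reps = 10000L,
                                 alpha = 0.05, n_observers = 10L,
                                 n_ecc = 3L, n_quadrants = 4L,
                                 observer_sd = 0, ecc_sd = 0,
                                 regression_term = "quadrant") {
  analysis <- match.arg(analysis)
  if (n_reps < 100L) warning("n_reps < 100 gives a very noisy estimate")
  stopifnot(abs(true_r) < 1, alpha > 0, alpha < 1)
  n <- n_observers * n_ecc * n_quadrants
  observer <- rep(seq_len(n_observers), each = n_ecc * n_quadrants)
  ecc <- rep(rep(seq_len(n_ecc), each = n_quadrants), times = n_observers)
  quadrant <- rep(seq_len(n_quadrants), times = n_observers * n_ecc)
  cell <- (observer - 1L) * n_ecc + ecc     # observer x eccentricity group

  draw_xy <- function() {
    x <- matrix(stats::rnorm(n * n_reps), n, n_reps)
    e <- matrix(stats::rnorm(n * n_reps), n, n_reps)
    y <- true_r * x + sqrt(1 - true_r^2) * e
    if (observer_sd > 0) {
      u <- matrix(stats::rnorm(n_observers * n_reps, 0, observer_sd),
                  n_observers, n_reps)
      x <- x + u[observer, ]
      y <- y + u[observer, ]
    }
    if (ecc_sd > 0) {
      ncell <- n_observers * n_ecc
      u <- matrix(stats::rnorm(ncell * n_reps, 0, ecc_sd), ncell, n_reps)
      x <- x + u[cell, ]
      y <- y + u[cell, ]
    }
    list(x = x, y = y)
  }

  col_pearson_p <- function(x, y, df) {
    xc <- sweep(x, 2L, colMeans(x))
    yc <- sweep(y, 2L, colMeans(y))
    r <- colSums(xc * yc) / sqrt(colSums(xc^2) * colSums(yc^2))
    tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, .Machine$double.eps))
    2 * stats::pt(-abs(tval), df)
  }

  d <- draw_xy()
  p <- switch(analysis,
    pooled = col_pearson_p(d$x, d$y, n - 2L),
    demeaned = {
      gm_x <- rowsum(d$x, cell) / n_quadrants
      gm_y <- rowsum(d$y, cell) / n_quadrants
      col_pearson_p(d$x - gm_x[cell, ], d$y - gm_y[cell, ], n - 2L)
    },
    regression = vapply(seq_len(n_reps), function(k) {
      res <- variance_partition_regression(d$x[, k], d$y[, k], observer,
                                           ecc, quadrant)
      res$table$p[res$table$term == regression_term]
    }, numeric(1)),
    second_level = vapply(seq_len(n_reps), function(k) {
      second_level_location_correlation(d$x[, k], d$y[, k], observer,
                                        ecc)$p
    }, numeric(1))
  )
  rate <- mean(p < alpha)
  structure(
    list(rate = rate, se = sqrt(rate * (1 - rate) / n_reps),
         n_reps = n_reps, alpha = alpha, n = n, analysis = analysis,
         true_r = true_r),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf(
    "%s analysis, true r = %.2f: rejection rate %.1f%% (MC se %.2f pp), %d reps of n = %d\n",
    x$analysis, x$true_r, 100 * x$rate, 100 * x$se, x$n_reps, x$n))
  invisible(x)
}

#' Closed-form power of the Pearson test via the Fisher z approximation
#'
#' Approximates the power of the two-sided Pearson correlation test
#' using the normal approximation `atanh(r_hat) ~ N(atanh(r), 1/(n-3))`.
#'
#' @param r True correlation.
#' @param n Sample size.
#' @param alpha Two-sided significance level.
#' @return Approximate power in [0, 1].
#' @export
power_fisher_z <- function(r, n, alpha = 0.05) {
  za <- stats::qnorm(1 - alpha / 2)
  shift <- atanh(r) * sqrt(n - 3)
  stats::pnorm(shift - za) + stats::pnorm(-shift - za)
}
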