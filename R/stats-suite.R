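#' Pooled Pearson correlation across all location-observations
#'
#' Treats every stimulus location in every observer as a separate
#' observation and computes the Pearson correlation with a two-sided
#' t-based p value.
#'
#' @param x,y Equal-length finite numeric vectors, n >= 3.
#' @return List of class `correlation_result`: `r`, `p`, `n`, `df`.
#' @export
pooled_pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(
    list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
         df = unname(ct$parameter)),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f, p = %.4g, n = %d\n", x$r, x$p, x$n))
  invisible(x)
}

#' Variance-partitioned regression of bias on a cortical predictor
#'
#' Builds three regressors from the predictor: the per-observer mean
#' (between-subject variance), the per-observer eccentricity means
#' minus the observer mean (individual eccentricity effects), and the
#' per-observer quadrant means minus the observer mean (individual
#' quadrant effects). The outcome is regressed on these plus an
#' intercept by ordinary least squares, leaving n - 4 residual degrees
#' of freedom on the full design.
#'
#' @param predictor,outcome Numeric vectors over all locations.
#' @param observer,eccentricity,quadrant Grouping vectors of the same
#'   length.
#' @return List of class `regression_result`: data frame `table`
#'   (term, beta, t, p) and `df`.
#' @export
variance_partition_regression <- function(predictor, outcome, observer,
                                          eccentricity, quadrant) {
  n <- length(outcome)
  stopifnot(length(predictor) == n, length(observer) == n,
            length(eccentricity) == n, length(quadrant) == n)
  obs_mean <- stats::ave(predictor, observer)
  ecc_eff <- stats::ave(predictor, observer, eccentricity) - obs_mean
  quad_eff <- stats::ave(predictor, observer, quadrant) - obs_mean
  X <- cbind(between_subject = obs_mean, eccentricity = ecc_eff,
             quadrant = quad_eff)
  qrX <- qr(cbind(1, X))
  if (qrX$rank < 4L) {
    bad <- colnames(X)[qrX$pivot[seq(qrX$rank + 1L, 4L)] - 1L]
    stop("rank-deficient design; collinear regressor(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(outcome ~ X)
  sm <- summary(fit)$coefficients
  tab <- data.frame(
    term = c("intercept", colnames(X)),
    beta = sm[, 1L], t = sm[, 3L], p = sm[, 4L],
    row.names = NULL
  )
  structure(list(table = tab, df = fit$df.residual),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Variance-partitioned regression (df = ", x$df, ")\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Pooled correlation after removing observer-by-eccentricity means
#'
#' Subtracts the group mean (observer crossed with eccentricity) from
#' both variables, removing between-subject variance and eccentricity
#' effects, then computes the pooled Pearson correlation on the
#' residuals with the nominal sample size. Note this test is
#' anticonservative under the null (see [power_fpr_simulation()]).
#'
#' @param x,y Numeric vectors over all locations.
#' @param observer,eccentricity Grouping vectors; every group must
#'   have at least 2 members.
#' @return `correlation_result` as in [pooled_pearson()].
#' @export
demeaned_correlation <- function(x, y, observer, eccentricity) {
  g <- interaction(observer, eccentricity, drop = TRUE)
  if (any(table(g) < 2L)) stop("every observer x eccentricity group needs >= 2 members")
  xr <- x - stats::ave(x, g)
  yr <- y - stats::ave(y, g)
  pooled_pearson(xr, yr)
}

#' Second-level test of within-cell location-wise correlations
#'
#' For each observer-by-eccentricity cell, correlates the two
#' variables across the four locations, Fisher z-transforms the cell
#' correlations (with |r| clipped just below 1), and tests the cell
#' z values against zero with a two-sided one-sample t-test.
#'
#' @param x,y Numeric vectors over all locations.
#' @param observer,eccentricity Grouping vectors defining the cells.
#' @param clip Clipping bound for |r| before `atanh`.
#' @return List of class `second_level_result`: `mean_z`, `t`, `df`,
#'   `p`, `n_cells`, `dropped` (cells with zero variance), and
#'   `degenerate` (TRUE when the cell z values have no variance, in
#'   which case `t` is infinite).
#' @export
second_level_location_correlation <- function(x, y, observer, eccentricity,
                                              clip = 1 - 1e-6) {
  g <- interaction(observer, eccentricity, drop = TRUE)
  zs <- c()
  dropped <- 0L
  for (cell in levels(g)) {
    i <- g == cell
    if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) {
      dropped <- dropped + 1L
      next
    }
    r <- stats::cor(x[i], y[i])
    zs <- c(zs, atanh(pmin(pmax(r, -clip), clip)))
  }
  if (dropped > 0L) warning(dropped, " degenerate cell(s) dropped")
  if (length(zs) == 0L) stop("all cells degenerate")
  degenerate <- stats::sd(zs) == 0
  if (degenerate) {
    tval <- if (mean(zs) == 0) 0 else sign(mean(zs)) * Inf
    p <- if (mean(zs) == 0) 1 else 0
  } else {
    tt <- stats::t.test(zs, mu = 0)
    tval <- unname(tt$statistic)
    p <- tt$p.value
  }
  structure(
    list(mean_z = mean(zs), t = tval, df = length(zs) - 1L, p = p,
         n_cells = length(zs), dropped = dropped, degenerate = degenerate),
    class = "second_level_result"
  )
}

#' Pairwise correlation matrix of per-location biases across conditions
#'
#' Each visual-field location (quadrant) in each observer is one data
#' point; the six columns are the two stimulus types at the three
#' eccentricities. Significance flags are reported uncorrected and
#' Bonferroni-corrected for the 15 off-diagonal comparisons.
#'
#' @param bias_table Data frame or matrix with 6 numeric columns
#'   (2 conditions x 3 eccentricities) and one row per
#'   location-observation.
#' @param alpha Family significance level (default 0.05).
#' @return List of class `condition_cor_matrix`: `r`, `p`,
#'   `sig_uncorrected`, `sig_bonferroni`, `n`, `n_comparisons`.
#' @export
condition_correlation_matrix <- function(bias_table, alpha = 0.05) {
  m <- as.matrix(bias_table)
  stopifnot(ncol(m) == 6L)
  if (anyNA(m)) {
    keep <- stats::complete.cases(m)
    warning("dropping ", sum(!keep), " incomplete row(s)")
    m <- m[keep, , drop = FALSE]
  }
  k <- ncol(m)
  n_comp <- k * (k - 1L) / 2L
  r <- stats::cor(m)
  p <- matrix(NA_real_, k, k, dimnames = dimnames(r))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      p[i, j] <- if (i == j) 0 else {
        stats::cor.test(m[, i], m[, j])$p.value
      }
    }
  }
  sig_unc <- p < alpha & row(p) != col(p)
  sig_bon <- p < alpha / n_comp & row(p) != col(p)
  structure(
    list(r = r, p = p, sig_uncorrected = sig_unc,
         sig_bonferroni = sig_bon, n = nrow(m), n_comparisons = n_comp),
    class = "condition_cor_matrix"
  )
}

#' Principal component analysis of the six per-location measures
#'
#' Columns (raw biases and dispersions for both stimulus types, pRF
#' spread and local surface area) are z-standardised and the
#' correlation matrix eigendecomposed; components are ordered by
#' explained variance, which sums to 100 percent.
#'
#' @param dataset Data frame or matrix with 6 complete numeric
#'   columns.
#' @return List of class `pca_result`: `loadings` (variables x
#'   components), `eigenvalues`, `percent_variance`, `scores`.
#' @export
pca_six_variable <- function(dataset) {
  m <- as.matrix(dataset)
  if (any(apply(m, 2L, stats::sd) == 0)) stop("constant column in PCA input")
  z <- scale(m)
  eg <- eigen(stats::cor(m), symmetric = TRUE)
  structure(
    list(loadings = eg$vectors, eigenvalues = eg$values,
         percent_variance = 100 * eg$values / sum(eg$values),
         scores = z %*% eg$vectors),
    class = "pca_result"
  )
}
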