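test_that("pooled Pearson matches the direct covariance formula", {
  set.seed(501)
  x <- rnorm(50)
  y <- 0.4 * x + rnorm(50)
  res <- pooled_pearson(x, y)
  r_brute <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_brute)
  expect_equal(res$n, 50L)
  expect_equal(res$df, 48)
  expect_equal(pooled_pearson(x, x)$r, 1)
  expect_error(pooled_pearson(rep(1, 10), rnorm(10)), "variance")
  # independent variables at large n: correlation near zero
  set.seed(502)
  big <- pooled_pearson(rnorm(5000), rnorm(5000))
  expect_lt(abs(big$r), 0.05)
})

test_that("variance-partitioned regression leaves n - 4 df and matches a brute-force solve", {
  set.seed(503)
  observer <- rep(1:10, each = 12)
  ecc <- rep(rep(1:3, each = 4), 10)
  quad <- rep(1:4, 30)
  x <- rnorm(120)
  y <- 0.3 * x + rnorm(120)
  res <- variance_partition_regression(x, y, observer, ecc, quad)
  expect_equal(res$df, 116)
  expect_equal(nrow(res$table), 4L)
  # brute-force normal equations on the same regressors
  r1 <- ave(x, observer)
  r2 <- ave(x, observer, ecc) - r1
  r3 <- ave(x, observer, quad) - r1
  X <- cbind(1, r1, r2, r3)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(res$table$beta, as.numeric(beta), tolerance = 1e-10)
  resid <- y - X %*% beta
  s2 <- sum(resid^2) / 116
  se <- sqrt(diag(solve(t(X) %*% X)) * s2)
  expect_equal(res$table$t, as.numeric(beta / se), tolerance = 1e-10)
  # collinear regressors are named in the error
  expect_error(
    variance_partition_regression(rep(1:10, each = 12) + 0, y, observer,
                                  ecc, quad),
    "collinear")
})

test_that("demeaning annihilates group structure and zeroes group sums", {
  set.seed(504)
  observer <- rep(1:10, each = 12)
  ecc <- rep(rep(1:3, each = 4), 10)
  x <- rnorm(120)
  y <- rnorm(120)
  g <- interaction(observer, ecc)
  res <- demeaned_correlation(x, y, observer, ecc)
  xr <- x - ave(x, g)
  expect_true(all(abs(tapply(xr, g, sum)) < 1e-10))
  expect_equal(res$n, 120L)
  # signals constant within groups carry no demeaned correlation
  xg <- ave(rnorm(120), g) + rnorm(120, 0, 1e-3)
  yg <- ave(rnorm(120), g) + rnorm(120, 0, 1e-3)
  expect_lt(abs(demeaned_correlation(xg, yg, observer, ecc)$r), 0.25)
  expect_error(demeaned_correlation(x[1:5], y[1:5], 1:5, rep(1, 5)),
               ">= 2 members")
})

test_that("the second-level test averages Fisher-z within-cell correlations", {
  # plant a common within-cell correlation; with large cells the mean
  # Fisher z recovers its atanh within Monte-Carlo error
  set.seed(505)
  rho <- 0.5
  n_cell <- 50L
  obs_big <- rep(1:10, each = 3 * n_cell)
  ecc_big <- rep(rep(1:3, each = n_cell), 10)
  reps <- replicate(60, {
    x <- rnorm(length(obs_big))
    y <- rho * x + sqrt(1 - rho^2) * rnorm(length(obs_big))
    second_level_location_correlation(x, y, obs_big, ecc_big)$mean_z
  })
  expect_equal(mean(reps), atanh(rho), tolerance = 0.05)
  # with 4-point cells the mean z still orders effect sizes correctly
  observer <- rep(1:10, each = 12)
  ecc <- rep(rep(1:3, each = 4), 10)
  mean_z_at <- function(r_true) {
    mean(replicate(100, {
      x <- rnorm(120)
      y <- r_true * x + sqrt(1 - r_true^2) * rnorm(120)
      second_level_location_correlation(x, y, observer, ecc)$mean_z
    }))
  }
  set.seed(510)
  expect_lt(abs(mean_z_at(0)), 0.1)
  expect_gt(mean_z_at(0.5), 0.3)
  # degenerate case: identical nonzero cell correlations
  x2 <- rep(c(1, 2, 3, 4), 30)
  y2 <- rep(c(2, 4, 6, 8), 30)
  res <- second_level_location_correlation(x2, y2, observer, ecc)
  expect_true(res$degenerate)
  expect_true(is.infinite(res$t))
  # cells with no variance are dropped with a warning
  x3 <- x2
  x3[1:4] <- 5
  expect_warning(second_level_location_correlation(x3, y2, observer, ecc),
                 "dropped")
})

test_that("the condition matrix is symmetric with a 15-comparison Bonferroni family", {
  set.seed(506)
  base <- matrix(rnorm(40 * 2), 40, 2)
  tab <- cbind(base[, 1] + rnorm(40, 0, 0.3),
               base[, 1] + rnorm(40, 0, 0.3),
               base[, 1] + rnorm(40, 0, 0.3),
               base[, 2] + rnorm(40, 0, 0.3),
               base[, 2] + rnorm(40, 0, 0.3),
               base[, 2] + rnorm(40, 0, 0.3))
  res <- condition_correlation_matrix(tab)
  expect_equal(res$n_comparisons, 15L)
  expect_equal(diag(res$r), rep(1, 6))
  expect_equal(res$r, t(res$r))
  expect_equal(res$p, t(res$p))
  expect_false(any(diag(res$sig_bonferroni)))
  # Bonferroni flags are a subset of the uncorrected flags
  expect_true(all(res$sig_uncorrected[res$sig_bonferroni]))
  # corrected threshold is alpha / 15
  expect_identical(res$sig_bonferroni[1, 2],
                   unname(res$p[1, 2] < 0.05 / 15))
  tab2 <- tab
  tab2[3, 2] <- NA
  expect_warning(res2 <- condition_correlation_matrix(tab2),
                 "incomplete")
  expect_equal(res2$n, 39L)
})

test_that("the six-variable PCA conserves variance and reconstructs correlations", {
  set.seed(507)
  z <- matrix(rnorm(200 * 3), 200, 3)
  dat <- cbind(z[, 1], z[, 1] + 0.5 * z[, 2], z[, 2], z[, 3],
               z[, 3] - z[, 1], z[, 2] + z[, 3])
  res <- pca_six_variable(dat)
  expect_equal(sum(res$percent_variance), 100)
  expect_true(all(diff(res$eigenvalues) <= 1e-12))
  recon <- res$loadings %*% diag(res$eigenvalues) %*% t(res$loadings)
  expect_equal(recon, stats::cor(dat), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(pca_six_variable(cbind(dat[, 1:5], 1)), "constant")
  # independent columns at large n: near-equal shares
  set.seed(508)
  flat <- pca_six_variable(matrix(rnorm(6e4), ncol = 6))
  expect_true(all(abs(flat$percent_variance - 100 / 6) < 3))
})

test_that("power is monotone in the true correlation and sample size", {
  set.seed(509)
  p1 <- power_fpr_simulation("pooled", true_r = 0.1, n_reps = 2000L)
  p3 <- power_fpr_simulation("pooled", true_r = 0.3, n_reps = 2000L)
  p5 <- power_fpr_simulation("pooled", true_r = 0.5, n_reps = 2000L)
  expect_lt(p1$rate, p3$rate)
  expect_lt(p3$rate, p5$rate)
  small <- power_fpr_simulation("pooled", true_r = 0.3, n_reps = 2000L,
                                n_observers = 5L)
  expect_lt(small$rate, p3$rate)
  expect_warning(power_fpr_simulation("pooled", n_reps = 50L), "noisy")
})
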