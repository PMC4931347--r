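test_that("the aperture sequence spans 225 volumes inside the mapped field", {
  ap <- test_apertures()
  cfg <- ap$config
  expect_equal(ap$n_volumes, 225L)
  expect_equal(cfg$wedge_steps * cfg$wedge_cycles +
                 cfg$blank_volumes, 225L)
  # all masks vanish outside the 8.5 degree field
  outside <- sqrt(ap$x^2 + ap$y^2) > cfg$field_radius
  expect_true(all(ap$masks[outside, ] == 0))
  # trailing 45 volumes are blank
  expect_true(all(ap$masks[, 181:225] == 0))
  expect_true(all(colSums(ap$masks[, 1:180]) > 0))
})

test_that("the wedge advances 6 polar degrees per volume", {
  cfg <- aperture_config()
  a <- wedge_angle_sequence(cfg)
  expect_length(a, 60L)
  expect_equal(unique(diff(a)), 6)
  cw <- wedge_angle_sequence(aperture_config(wedge_dir = "cw"))
  expect_equal(unique(diff(cw[-1])), -6)
})

test_that("the ring radius sequence is geometric up to the field edge", {
  cfg <- aperture_config()
  r <- ring_radius_sequence(cfg)
  expect_length(r, 36L)
  ratios <- r[-1] / r[-length(r)]
  expect_equal(ratios, rep(ratios[1], 35), tolerance = 1e-12)
  expect_equal(max(r), cfg$field_radius)
  contract <- ring_radius_sequence(aperture_config(ring_dir = "contract"))
  expect_equal(contract, rev(r))
})

test_that("the wedge sector covers about 12/360 of the disc", {
  # shrink the ring to a sliver so the mask is essentially wedge-only
  cfg <- aperture_config(grid_n = 201L, ring_ratio = 0.999)
  ap <- build_apertures(cfg)
  disc <- sum(sqrt(ap$x^2 + ap$y^2) <= cfg$field_radius)
  frac <- mean(colSums(ap$masks[, 1:180]) / disc)
  expect_equal(frac, 12 / 360, tolerance = 0.15)
})

test_that("the two-gamma HRF peaks at its latency and loses its undershoot", {
  t <- seq(0, 32, by = 0.1)
  h <- two_gamma(t, peak_latency = 5)
  expect_equal(t[which.max(h)], 5, tolerance = 0.2)
  h2 <- two_gamma(t, ratio = 1e9)
  expect_true(all(h2 >= -1e-12))
  expect_error(two_gamma(t, peak_latency = -1), "invalid")
  expect_error(two_gamma(-1), "nonnegative")
})

test_that("HRF fitting averages epochs, applies the inclusion rule, and recovers latency", {
  set.seed(301)
  tt <- 0:29
  shape <- two_gamma(tt, peak_latency = 6, undershoot_latency = 16,
                     ratio = 5)
  shape <- stats::convolve(c(shape, 0, 0), rev(c(1, 1)),
                           type = "open")[1:30]
  good <- lapply(1:5, function(i) {
    do.call(rbind, lapply(1:10, function(e) shape + rnorm(30, 0, 0.005)))
  })
  bad <- list(matrix(rnorm(300, -1, 0.01), nrow = 10))
  fit <- fit_hrf(c(good, bad))
  expect_equal(fit$included, 1:5)
  expect_equal(fit$peak_latency, 6, tolerance = 0.5)
  # ten identical epochs average to any single epoch
  same <- matrix(rep(shape, each = 10), nrow = 10, byrow = FALSE)
  same <- do.call(rbind, replicate(10, shape, simplify = FALSE))
  expect_equal(colMeans(same), shape)
  expect_error(fit_hrf(bad), "no unit")
})

test_that("predicted series are amplitude-free and flag off-field pRFs", {
  ap <- test_apertures()
  p <- predict_timeseries(2, 1, 1.5, ap)
  expect_length(p, 225L)
  expect_equal(mean(p), 0, tolerance = 1e-10)
  expect_equal(sd(p), 1, tolerance = 1e-10)
  expect_false(attr(p, "degenerate"))
  far <- predict_timeseries(30, 30, 0.3, ap)
  expect_true(attr(far, "degenerate"))
  expect_true(all(far == 0))
})

test_that("the coarse search grid has 15 x 15 x 34 log-spaced candidates", {
  g <- prf_search_grid()
  expect_equal(nrow(g), 15 * 15 * 34)
  expect_equal(sort(unique(g$spread)), 0.18 * 2^(0.2 * (0:33)))
  expect_equal(length(unique(g$x)), 15L)
  expect_equal(length(unique(g$y)), 15L)
})

test_that("a noiseless grid-point series is returned exactly by the coarse fit", {
  ap <- test_apertures()
  gp <- test_grid_pred()
  pick <- c(1700, 4000)
  for (i in pick) {
    truth <- gp$grid[i, ]
    obs <- predict_timeseries(truth$x, truth$y, truth$spread, ap)
    co <- coarse_fit(as.numeric(obs), gp)
    expect_equal(co$x, truth$x)
    expect_equal(co$y, truth$y)
    expect_equal(co$spread, truth$spread)
    expect_gt(co$r, 0.999)
  }
})

test_that("the fine fit recovers off-grid ground truth and never worsens the seed", {
  ap <- test_apertures()
  gp <- test_grid_pred()
  truth <- data.frame(x = c(2.3, -4.1), y = c(1.1, 3.3),
                      s = c(0.9, 2.2))
  for (i in seq_len(nrow(truth))) {
    obs <- as.numeric(predict_timeseries(truth$x[i], truth$y[i],
                                         truth$s[i], ap))
    co <- coarse_fit(obs, gp)
    fi <- fine_fit(obs, co, ap)
    expect_lte(fi$sse, fi$seed_sse)
    expect_lt(abs(fi$x - truth$x[i]), 0.05)
    expect_lt(abs(fi$y - truth$y[i]), 0.05)
    expect_lt(abs(fi$spread / truth$s[i] - 1), 0.05)
  }
})

test_that("fine-fit amplitude scales linearly with the observed series", {
  ap <- test_apertures()
  gp <- test_grid_pred()
  obs <- as.numeric(predict_timeseries(1.5, -2.0, 1.2, ap))
  co <- coarse_fit(obs, gp)
  f1 <- fine_fit(obs, co, ap)
  f3 <- fine_fit(3 * obs, coarse_fit(3 * obs, gp), ap)
  expect_equal(f3$amplitude / f1$amplitude, 3, tolerance = 1e-3)
})

test_that("noisy recovery stays within tolerance where the coarse fit is reliable", {
  set.seed(302)
  ap <- test_apertures()
  gp <- test_grid_pred()
  n_units <- 40L
  ecc <- runif(n_units, 1, 7)
  ang <- runif(n_units, 0, 2 * pi)
  truth <- data.frame(x = ecc * cos(ang), y = ecc * sin(ang),
                      s = runif(n_units, 0.5, 2.5))
  err_pos <- err_spread <- rs <- numeric(0)
  for (i in seq_len(n_units)) {
    # contrast-to-noise in the regime where the coarse fit is reliable
    obs <- as.numeric(predict_timeseries(truth$x[i], truth$y[i],
                                         truth$s[i], ap)) +
      rnorm(225, 0, 0.55)
    co <- coarse_fit(obs, gp)
    if (co$r < 0.5) next
    fi <- fine_fit(obs, co, ap)
    rs <- c(rs, co$r)
    err_pos <- c(err_pos, sqrt((fi$x - truth$x[i])^2 +
                                 (fi$y - truth$y[i])^2))
    err_spread <- c(err_spread, abs(fi$spread / truth$s[i] - 1))
  }
  expect_gt(length(rs), 10)
  expect_lt(median(err_pos), 0.25)
  expect_lt(median(err_spread), 0.20)
})

test_that("preprocessing detrends, standardises, averages and concatenates", {
  set.seed(303)
  n_vol <- 50L
  base <- matrix(rnorm(n_vol * 3), n_vol, 3)
  runs <- list(base + outer(1:n_vol, c(0.1, 0, -0.2)),
               base + 5,
               base + outer(1:n_vol, c(-0.3, 0.2, 0)),
               base - 2)
  out <- preprocess_series(runs, c("a", "b", "a", "b"))
  expect_equal(dim(out), c(100L, 3L))
  # a pure linear ramp becomes all zeros (guarded z-score)
  ramp <- list(matrix(1:20, 20, 2), matrix(seq(2, 40, 2), 20, 2))
  out2 <- preprocess_series(ramp, c("a", "b"))
  expect_true(all(out2 == 0))
  expect_equal(attr(out2, "excluded_units"), 1:2)
  # averaging k noise runs shrinks the SD roughly by sqrt(k)
  noise_runs <- lapply(1:8, function(i) matrix(rnorm(2000), 500, 4))
  avg <- preprocess_series(noise_runs, rep(c("a", "b"), each = 4))
  expect_equal(sd(avg), 1 / sqrt(4), tolerance = 0.1)
})
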