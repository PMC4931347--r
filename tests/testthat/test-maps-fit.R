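test_that("detector response is a unit-amplitude Gaussian tuning curve", {
  expect_equal(detector_response(0.2, 0.2, 0.3), 1)
  expect_equal(detector_response(0.2 + 0.3, 0.2, 0.3), exp(-1 / 2))
  expect_equal(detector_response(0.15, 0, 0.3), exp(-0.125))
  expect_error(detector_response(0, 0, 0), "positive")
  expect_error(detector_response(0, 0, -0.1), "positive")
})

test_that("the strongest detector determines the predicted choice", {
  expect_identical(
    predict_choice(c(0.5, -0.05, 0.3, -1.0), rep(0, 4), rep(0.3, 4)), 2L)
  expect_identical(
    predict_choice(c(0.2, 0.1, -0.3, 0.5), c(0.2, 0, 0, 0), rep(0.3, 4)),
    1L)
  # exact two-way tie resolved to the lower location index
  expect_identical(
    predict_choice(c(0.1, -0.1, 0.5, 0.5), rep(0, 4), rep(0.3, 4)), 1L)
  # a matrix of trials is handled row-wise
  m <- rbind(c(0.5, -0.05, 0.3, -1.0), c(0.2, 0.1, -0.3, 0.5))
  expect_identical(predict_choice(m, rep(0, 4), rep(0.3, 4)), c(2L, 2L))
})

test_that("choices are invariant to a common scaling of detector outputs", {
  set.seed(201)
  sizes <- matrix(rnorm(400, 0, 0.3), ncol = 4)
  mu <- runif(4, -0.2, 0.2)
  sigma <- runif(4, 0.1, 0.5)
  resp <- sapply(1:4, function(l) detector_response(sizes[, l], mu[l],
                                                    sigma[l]))
  expect_identical(max.col(resp, ties.method = "first"),
                   max.col(7.3 * resp, ties.method = "first"))
  expect_identical(max.col(resp, ties.method = "first"),
                   predict_choice(sizes, mu, sigma))
  # common rescaling of all dispersions also leaves choices unchanged
  expect_identical(predict_choice(sizes, mu, sigma),
                   predict_choice(sizes, mu, 3 * sigma))
})

test_that("prediction error is the misprediction fraction", {
  set.seed(202)
  tr <- draw_gaussian_trials(200)
  # choices equal to model predictions on exactly half the trials
  pred <- predict_choice(trial_sizes(tr), rep(0, 4), rep(0.3, 4))
  tr$chosen_loc <- pred
  flip <- seq_len(100)
  tr$chosen_loc[flip] <- (pred[flip] %% 4L) + 1L
  expect_equal(prediction_error(rep(0, 4), rep(0.3, 4), tr), 0.5)
  tr$chosen_loc <- pred
  expect_equal(prediction_error(rep(0, 4), rep(0.3, 4), tr), 0)
  expect_error(prediction_error(rep(0, 4), rep(0.3, 4),
                                tr[0, , drop = FALSE]), "no answered")
  # a random-guessing observer disagrees with any fixed model ~75%
  tr2 <- draw_gaussian_trials(4000)
  tr2$chosen_loc <- sample.int(4L, nrow(tr2), replace = TRUE)
  expect_equal(prediction_error(rep(0, 4), rep(0.3, 4), tr2), 0.75,
               tolerance = 0.05)
})

test_that("initial parameters follow the chosen-incorrectly rule", {
  tr <- trials_df(4, "isolated", 3.92,
                  rbind(c(0.1, 0.4, 0.2, -0.2),
                        c(0.3, 0.0, -0.1, 0.5),
                        c(0.2, 0.0, 0.3, -0.4),
                        c(-0.5, 0.1, 0.0, 0.2)),
                  correct = c(NA, 2L, 2L, 3L))
  # location 1 chosen on trials 1 and 2; trial 2 has correct target
  # elsewhere, so only its size (0.3) enters mu0; SD over both chosen
  tr$chosen_loc <- c(1L, 1L, 2L, 4L)
  init <- initialize_params(tr)
  expect_equal(init$mu[1], 0.3)
  expect_equal(init$sigma[1], sd(c(0.1, 0.3)))
  # location 2 chosen once, correctly: fallback to all chosen trials
  expect_equal(init$mu[2], 0.0)
  # location 3 never chosen: documented fallback
  expect_equal(init$mu[3], 0)
  expect_equal(init$sigma[3], 0.3)
  # degenerate stratum: identical sizes give the fallback dispersion
  tr2 <- trials_df(3, "isolated", 3.92,
                   matrix(c(0.2, 0.2, 0.2, 0, 0, 0, 0.1, 0.1, 0.1,
                            -0.1, -0.1, -0.1), nrow = 3),
                   correct = rep(2L, 3))
  tr2$chosen_loc <- rep(1L, 3)
  expect_equal(initialize_params(tr2)$sigma[1], 0.3)
})

test_that("fitting never scores worse than the initialisation", {
  set.seed(203)
  obs <- make_observer(quadrant_sd = 0.08)
  tr <- simulate_responses(obs, draw_gaussian_trials(300), "isolated")
  fit <- fit_maps_model(tr, restarts = 5L)
  init <- initialize_params(tr)
  expect_lte(fit$fit_error,
             prediction_error(init$mu, init$sigma, tr))
  expect_true(all(fit$sigma > 0))
  expect_gte(fit$fit_error, 0)
  expect_lte(fit$fit_error, 1)
  expect_equal(fit$n_trials, 300L)
})

test_that("an unbiased low-noise observer yields near-zero fitted biases", {
  set.seed(204)
  obs <- make_observer(bias_slope = 0, quadrant_sd = 0, noise_sd = 0.05)
  tr <- simulate_responses(obs, draw_gaussian_trials(600), "isolated")
  fit <- fit_maps_model(tr)
  expect_true(all(abs(fit$mu) <= 0.02))
})

test_that("injected opposite 0.1 log-unit biases are recovered", {
  set.seed(205)
  mu_t <- c(0.1, -0.1, 0, 0)
  # average the fitted biases over replicate 600-trial runs
  mus <- vapply(1:5, function(i) {
    tr <- simulate_detector_choices(draw_gaussian_trials(600), mu_t,
                                    rep(0.3, 4))
    fit_maps_model(tr)$mu
  }, numeric(4))
  mu_hat <- rowMeans(mus)
  expect_true(all(abs(mu_hat - mu_t) <= 0.03))
  expect_gt(mu_hat[1], 0)
  expect_lt(mu_hat[2], 0)
})

test_that("parameter recovery improves with more trials", {
  set.seed(206)
  err_at <- function(n, reps) {
    unlist(lapply(seq_len(reps), function(i) {
      recovery_experiment(1, n, restarts = 10L)$mu_err
    }))
  }
  e100 <- err_at(100, 4)
  e1000 <- err_at(1000, 4)
  expect_lt(median(e1000), median(e100))
})

test_that("unanswered trials are dropped before fitting", {
  set.seed(207)
  obs <- make_observer()
  tr <- simulate_responses(obs, draw_gaussian_trials(300), "isolated")
  tr$chosen_loc[1:50] <- NA_integer_
  fit <- fit_maps_model(tr, restarts = 3L)
  expect_equal(fit$n_trials, 250L)
})

test_that("precision-weighted bias matches the direct formula", {
  expect_equal(precision_weighted_bias(c(0.1, 0.3), c(0.2, 0.2)), 0.2)
  expect_equal(precision_weighted_bias(c(0.2, 0.0), c(0.1, 1000)), 0.2,
               tolerance = 1e-3)
  set.seed(208)
  b <- rnorm(10)
  d <- runif(10, 0.1, 2)
  expect_equal(precision_weighted_bias(b, d),
               sum(b / d) / sum(1 / d))
  expect_error(precision_weighted_bias(c(0.1, 0.2), c(0.1, -1)),
               "positive")
})

test_that("relative illusion strength is the bias difference", {
  expect_equal(relative_illusion_strength(0.2, 0.2), 0)
  expect_equal(relative_illusion_strength(0.10, -0.05), 0.15)
  # Delboeuf inducers enlarge apparent size, so the illusion is positive
  set.seed(209)
  obs <- make_observer()
  iso <- true_bias(obs, 3.92, "isolated")
  del <- true_bias(obs, 3.92, "delboeuf")
  expect_true(all(relative_illusion_strength(iso, del) > 0))
})
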