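test_that("robust rejection is calibrated on clean data and catches plants", {
  set.seed(1)
  x <- rnorm(1000); y <- 0.9 * x + rnorm(1000, 0, 0.5)
  ol <- remove_outliers(x, y, alpha = 0.01)
  expect_equal(ol$estimator, "mcd")
  expect_lte(mean(!ol$keep), 0.04)
  # five planted points at ~10 robust SDs must all go
  x2 <- c(rnorm(100), rnorm(5, 0, 0.1))
  y2 <- c(0.9 * x2[1:100] + rnorm(100, 0, 0.5), rep(12, 5))
  ol2 <- remove_outliers(x2, y2, alpha = 0.01)
  expect_true(all(!ol2$keep[101:105]))
  # alpha -> 0 disables rejection
  ol3 <- remove_outliers(x, y, alpha = 0)
  expect_true(all(ol3$keep))
  expect_error(remove_outliers(1:5, 1:5), "at least 10")
})

test_that("degenerate scatter falls back gracefully", {
  set.seed(2)
  x <- rnorm(40)
  y <- 2 * x                    # exactly collinear: MCD scatter singular
  expect_warning(expect_warning(ol <- remove_outliers(x, y, alpha = 0.01),
                                "falling back|singular"))
  expect_true(is.list(ol))
})

test_that("bias/gain regression matches exact and hand-computed OLS", {
  az <- rep(seq(-30, 30, 5), 3)
  fit <- suppressWarnings(fit_bias_gain(az, 0.8 * az + 5))  # exact fit
  expect_equal(fit$gain, 0.8)
  expect_equal(fit$bias, 5)
  expect_equal(fit$se_gain, 0, tolerance = 1e-8)
  expect_equal(fit$se_bias, 0, tolerance = 1e-8)
  fitc <- suppressWarnings(fit_bias_gain(az, rep(7, length(az))))
  expect_equal(fitc$gain, 0)
  # noisy data: SEs from the closed-form normal equations
  set.seed(3)
  y <- 0.9 * az + 2 + rnorm(length(az), 0, 4)
  f <- fit_bias_gain(az, y)
  sxx <- sum((az - mean(az))^2)
  beta <- sum((az - mean(az)) * (y - mean(y))) / sxx
  alpha <- mean(y) - beta * mean(az)
  s2 <- sum((y - alpha - beta * az)^2) / (length(az) - 2)
  expect_equal(f$gain, beta)
  expect_equal(f$bias, alpha)
  expect_equal(f$se_gain, sqrt(s2 / sxx))
  expect_equal(f$se_bias, sqrt(s2 * (1 / length(az) + mean(az)^2 / sxx)))
  expect_error(fit_bias_gain(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_bias_gain(rep(1, 5), rnorm(5)), "distinct")
})

test_that("disparity contrasts are antisymmetric", {
  e1 <- data.frame(bias = 4, gain = 1.1)
  e2 <- data.frame(bias = -4, gain = 0.9)
  ct <- contrast_disparities(e1, e2)
  expect_equal(ct$vae_magnitude, 8)
  expect_equal(ct$gain_change, 0.2, tolerance = 1e-12)
  swapped <- contrast_disparities(e2, e1)
  expect_equal(swapped$vae_magnitude, -ct$vae_magnitude)
  expect_equal(swapped$gain_change, -ct$gain_change)
  expect_equal(contrast_disparities(e1, e1)$vae_magnitude, 0)
})

test_that("the noiseless pipeline recovers generative contrasts exactly", {
  pop <- population_spec(
    observer_params(gain = 0.95, bias = 1,
                    response_noise_sd = 1e-9, outlier_rate = 0),
    sd_gain = 0, sd_bias = 0, sd_asymptote = 0, sd_log_timeconstant = 0)
  sim <- simulate_dataset(1, 3, pop = pop, seed = 5)
  fl <- first_level_pipeline(sim$trials, alpha = NULL)
  m <- pop$means
  for (i in seq_len(nrow(fl$contrasts))) {
    row <- fl$contrasts[i, ]
    truth <- m$vae_asymptote[[row$condition]] *
      (1 - exp(-row$duration_s / m$vae_timeconstant[[row$condition]]))
    expect_equal(row$vae_magnitude, truth, tolerance = 1e-5)
    expect_equal(row$gain_change, 0, tolerance = 1e-6)
  }
})

test_that("pipeline output is invariant to trial order", {
  sim <- simulate_dataset(2, 3, seed = 6)
  set.seed(10)
  fl1 <- first_level_pipeline(sim$trials, alpha = 0.01)
  shuffled <- sim$trials[sample(nrow(sim$trials)), ]
  set.seed(10)
  fl2 <- first_level_pipeline(shuffled, alpha = 0.01)
  expect_equal(fl1$contrasts[order(fl1$contrasts$participant,
                                   fl1$contrasts$duration_s), ],
               fl2$contrasts[order(fl2$contrasts$participant,
                                   fl2$contrasts$duration_s), ],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("rejection rates track the contamination rate", {
  pop <- population_spec(observer_params(outlier_rate = 0.05))
  sim <- simulate_dataset(1, 8, pop = pop, seed = 7)
  set.seed(11)
  fl <- first_level_pipeline(sim$trials, alpha = 0.01)
  expect_gt(fl$rejection_rate, 0.025)
  expect_lt(fl$rejection_rate, 0.085)
  # clean data: rejection stays near the nominal alpha
  pop0 <- population_spec(observer_params(outlier_rate = 0,
                                          response_noise_sd = 2))
  sim0 <- simulate_dataset(2, 6, pop = pop0, seed = 8)
  set.seed(12)
  fl0 <- first_level_pipeline(sim0$trials, alpha = 0.01)
  expect_lte(fl0$rejection_rate, 0.01 + 0.03)
})

test_that("cycle filtering restricts the per-cycle re-analysis", {
  sim <- simulate_dataset(2, 2, seed = 9)
  fl <- first_level_pipeline(sim$trials, alpha = NULL, cycles = 1)
  expect_true(all(fl$estimates$n_used + fl$estimates$n_rejected == 10))
  fl34 <- first_level_pipeline(sim$trials, alpha = NULL, cycles = c(3, 4))
  expect_true(all(fl34$estimates$n_used == 20))
})

test_that("the VAE estimator is unbiased over seeded replicates", {
  set.seed(13)
  pop <- population_spec(observer_params(outlier_rate = 0))
  m <- pop$means
  errs <- replicate(60, {
    sim <- simulate_dataset(1, 8, pop = pop)
    fl <- first_level_pipeline(sim$trials, alpha = NULL)
    truth <- vapply(seq_len(nrow(fl$contrasts)), function(i) {
      row <- fl$contrasts[i, ]
      expected_vae(m$vae_asymptote[[row$condition]],
                   m$vae_timeconstant[[row$condition]],
                   row$duration_s, pop$sd_asymptote,
                   pop$sd_log_timeconstant)
    }, numeric(1))
    mean(fl$contrasts$vae_magnitude - truth)
  })
  expect_lt(abs(mean(errs)), 0.3)
})
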