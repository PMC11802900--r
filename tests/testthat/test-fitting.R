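test_that("difference spectrum cancels the shared state and normalizes", {
  grid <- seq(300, 700, 1)
  bleached <- tibble::tibble(wavelength = grid, value = 0.4)
  t530 <- pigment_template(530)
  recovered <- tibble::tibble(wavelength = grid,
                              value = 0.4 + 0.5 * t530$value)
  d <- difference_spectrum(recovered, bleached)
  expect_equal(d$value, t530$value, tolerance = 1e-12)
  expect_equal(d$kind[1], "absorbance")

  expect_error(difference_spectrum(bleached, bleached), "flat")
  expect_error(
    difference_spectrum(recovered,
                        tibble::tibble(wavelength = grid + 1, value = 0.4)),
    "grid")
})

test_that("noisy difference spectra still correlate with their template", {
  grid <- seq(300, 700, 1)
  t530 <- pigment_template(530)
  bleached <- tibble::tibble(wavelength = grid, value = 0.4)
  set.seed(5)
  recovered <- tibble::tibble(
    wavelength = grid,
    value = 0.4 + 0.5 * t530$value + rnorm(length(grid), sd = 0.01))
  d <- difference_spectrum(recovered, bleached)
  expect_gt(cor(d$value, t530$value), 0.99)
})

test_that("fit_lambda_max recovers noiseless templates across the pigment set", {
  for (lm in c(355, 431, 435, 530)) {
    beta <- lm >= 400
    s <- pigment_template(lm, beta_band = beta)
    fit <- fit_lambda_max(s, search = c(max(300, lm - 80), min(700, lm + 80)),
                          beta_band = beta)
    expect_equal(fit$lambda_max, lm, tolerance = 0.05)
    expect_lt(fit$rss, 1e-10)
  }
})

test_that("fit_lambda_max agrees with an exhaustive fine-grid search", {
  s <- gen_difference_spectrum(435.1, noise_sd = 0.02, seed = 3)
  fit <- fit_lambda_max(s, search = c(380, 500))
  expect_equal(fit$lambda_max, 435.1, tolerance = 1)

  # oracle: exhaustive grid search at 0.01 nm over the same objective
  keep <- s$wavelength >= 380 & s$wavelength <= 500
  wl <- s$wavelength[keep]
  y <- s$value[keep]
  cand <- seq(420, 450, by = 0.01)
  rss <- vapply(cand, function(lm) {
    tv <- rnlvis:::template_values(lm, wl, TRUE)
    amp <- sum(y * tv) / sum(tv^2)
    sum((y - amp * tv)^2)
  }, numeric(1))
  expect_equal(fit$lambda_max, cand[which.min(rss)], tolerance = 0.02)
})

test_that("fit_lambda_max flags boundary optima and tiny fit ranges", {
  s <- pigment_template(530)
  expect_warning(fit <- fit_lambda_max(s, search = c(400, 480)), "boundary")
  expect_true(fit$boundary)
  short <- tibble::tibble(wavelength = c(500, 510, 520, 530), value = 1)
  expect_error(fit_lambda_max(short, search = c(450, 600)), "fewer than 5")
})

test_that("fit_lambda_max is nearly unbiased under measurement noise", {
  est <- vapply(1:200, function(seed) {
    s <- gen_difference_spectrum(530, noise_sd = 0.02, seed = seed)
    fit_lambda_max(s, search = c(450, 600))$lambda_max
  }, numeric(1))
  expect_lt(abs(mean(est) - 530), 0.5)
})

test_that("flux_to_sensitivity inverts and normalizes criterion fluxes", {
  pupil <- tibble::tibble(wavelength = seq(340, 580, 10),
                          criterion_flux = rep(2e9, 25))
  s <- flux_to_sensitivity(pupil)
  expect_equal(s$value, rep(1, 25))

  pupil$criterion_flux[10] <- 1e9
  s <- flux_to_sensitivity(pupil)
  expect_equal(s$value[10], 1)
  expect_equal(s$value[-10], rep(0.5, 24))

  pupil$criterion_flux[1] <- 0
  expect_error(flux_to_sensitivity(pupil), "positive")
})

test_that("noise-free pupil data invert exactly to the generating mixture", {
  pd <- gen_pupil_dataset(355, 530, 0.25, noise_sd = 0, seed = 1)
  s <- flux_to_sensitivity(pd)
  mix <- 0.25 * rnlvis:::template_values(355, pd$wavelength, FALSE) +
    rnlvis:::template_values(530, pd$wavelength, TRUE)
  expect_equal(s$value, mix / max(mix), tolerance = 1e-12)
})

test_that("pupil dataset reader validates its three columns", {
  f <- write_tmp(c("340 1.2e9 0.07", "350 1.0e9 0.07"))
  pd <- read_pupil_dataset(f)
  expect_equal(pd$criterion, c(0.07, 0.07))
  bad <- write_tmp(c("340 1.2e9 0.07", "350 -1 0.07"))
  expect_error(read_pupil_dataset(bad), "positive")
})

test_that("the mixture fit recovers both generating peaks", {
  pd <- gen_pupil_dataset(355, 530, 0.25, noise_sd = 0.03, seed = 1)
  fit <- fit_pigment_mixture(flux_to_sensitivity(pd))
  expect_equal(fit$lambda_uv, 355, tolerance = 2)
  expect_equal(fit$lambda_lw, 530, tolerance = 2)
  expect_gt(fit$amplitude_uv, 0)
  expect_gt(fit$amplitude_lw, 0)

  # noiseless data: peaks exact to the refinement tolerance
  fit0 <- fit_pigment_mixture(flux_to_sensitivity(
    gen_pupil_dataset(355, 530, 0.25, noise_sd = 0)))
  expect_equal(fit0$lambda_uv, 355, tolerance = 0.05)
  expect_equal(fit0$lambda_lw, 530, tolerance = 0.05)
})

test_that("a pure long-wavelength sensitivity gets near-zero UV amplitude", {
  fit <- fit_pigment_mixture(pigment_template(530))
  expect_lte(fit$amplitude_uv, 0.01)
})

test_that("mixture fit rejects overlapping or empty ranges", {
  s <- pigment_template(530)
  expect_error(fit_pigment_mixture(s, uv_range = c(340, 500),
                                   lw_range = c(490, 580)), "overlap")
  expect_error(fit_pigment_mixture(s, uv_range = c(301.2, 301.4)), "no data")
})

test_that("blue residual exposes an injected blue receptor contribution", {
  # paired datasets, same seed, with and without a blue bump
  with_bump <- gen_pupil_dataset(355, 530, 0.25,
                                 blue_bump = c(430, 0.15), noise_sd = 0.02,
                                 seed = 8)
  without <- gen_pupil_dataset(355, 530, 0.25, noise_sd = 0.02, seed = 8)
  rb_with <- blue_residual(flux_to_sensitivity(with_bump),
                           fit_pigment_mixture(flux_to_sensitivity(with_bump)))
  rb_without <- blue_residual(flux_to_sensitivity(without),
                              fit_pigment_mixture(flux_to_sensitivity(without)))
  expect_gt(mean(rb_with$value), mean(rb_without$value))
  # the bump's excess peaks inside the blue window
  peak_wl <- rb_with$wavelength[which.max(rb_with$value)]
  expect_gte(peak_wl, 390)
  expect_lte(peak_wl, 480)
})

test_that("blue residual is zero when the data equal the fitted mixture", {
  pd <- gen_pupil_dataset(355, 530, 0.25, noise_sd = 0)
  sens <- flux_to_sensitivity(pd)
  fit <- fit_pigment_mixture(sens)
  rb <- blue_residual(sens, fit)
  expect_equal(max(abs(rb$value)), 0, tolerance = 1e-3)
  expect_error(blue_residual(sens, fit, range = c(700, 710)), "no data")
})

test_that("tidy and glance summarise fit objects", {
  fit <- fit_lambda_max(pigment_template(530), search = c(450, 600))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "lambda_max"], 530, tolerance = 0.05)
  expect_named(glance(fit), c("rss", "n", "boundary"))
  mf <- fit_pigment_mixture(flux_to_sensitivity(
    gen_pupil_dataset(355, 530, 0.25, noise_sd = 0)))
  expect_equal(nrow(tidy(mf)), 4)
})
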