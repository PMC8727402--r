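test_that("cold-day percentage is the inclusive fraction of cold minima", {
  expect_equal(percent_cold_days(c(3, 5, 7, 9), 6), 50)
  expect_equal(percent_cold_days(c(3, 5, 7, 9), 2), 0)
  expect_equal(percent_cold_days(rep(c(1, 20), c(25, 75)), 5), 25)
  expect_equal(percent_cold_days(c(3, 5), 5), 100) # <= is inclusive
  expect_error(percent_cold_days(numeric(0), 5), "empty")
})

test_that("cold-day percentage is a non-decreasing step function of the threshold", {
  set.seed(3)
  tmin <- round(rnorm(60, 8, 4), 1)
  grid <- seq(-5, 25, by = 0.1)
  p <- percent_cold_days(tmin, grid)
  expect_true(all(diff(p) >= 0))
  expect_equal(p[length(p)], 100)
  expect_equal(percent_cold_days(tmin, max(tmin)), 100)
})

test_that("yield regression recovers implanted coefficients and matches the oracle", {
  rec <- make_records(n_years = 12, tc_true = 10, beta0 = 1000,
                      b_p = -10, b_r = 2, noise_sd = 0, seed = 2)
  fit <- fit_yield_regression(rec, 10)
  expect_true(fit$fittable)
  expect_equal(fit$beta0, 1000, tolerance = 1e-8)
  expect_equal(fit$beta1, -10, tolerance = 1e-8)
  expect_equal(fit$beta2, 2, tolerance = 1e-8)
  expect_lt(fit$p_beta1, 1e-10)

  noisy <- make_records(n_years = 15, noise_sd = 80, seed = 4)
  fit_n <- fit_yield_regression(noisy, 9)
  p <- vapply(noisy$rp_tmin, function(v) percent_cold_days(v, 9), numeric(1))
  orc <- ols_oracle(noisy$yf, p, noisy$r)
  expect_equal(c(fit_n$beta0, fit_n$beta1, fit_n$beta2), orc$beta, tolerance = 1e-10)
  expect_equal(fit_n$p_beta1, orc$p[2], tolerance = 1e-10)
})

test_that("a constant-yield response gives a null association", {
  rec <- make_records(n_years = 8, b_p = 0, b_r = 0, noise_sd = 0, seed = 6)
  fit <- fit_yield_regression(rec, 10)
  expect_equal(fit$beta1, 0)
  expect_equal(fit$p_beta1, 1)
})

test_that("the default grid has 191 candidates and skips unfittable ones", {
  rec <- make_records(n_years = 10, seed = 8)
  scan <- scan_thresholds(rec)
  expect_equal(nrow(scan), 191)
  expect_equal(scan$tc[1], 0)
  expect_equal(scan$tc[191], 19)
  expect_equal(diff(scan$tc), rep(0.1, 190), tolerance = 1e-9)

  # all minima above the grid: P is constantly zero, nothing fittable
  warm <- make_records(n_years = 10, tmin_centre = 26, tmin_spread = 3, seed = 9)
  scan_w <- scan_thresholds(warm)
  expect_true(all(!scan_w$fittable))
  res <- select_threshold(scan_w, unlist(warm$rp_tmin))
  expect_false(res$detected)
  expect_error(scan_thresholds(rec[1:3, ]), "at least 4")
})

test_that("selection applies the min-p rule, max tie-break and both criteria", {
  fake_scan <- function(tc, p) {
    out <- tibble::tibble(tc = tc, fittable = TRUE, beta0 = 0, beta1 = -1,
                          beta2 = 0, p_beta1 = p, sigma = 1)
    class(out) <- c("tc_scan", class(out))
    out
  }
  pooled <- seq(2, 16, by = 0.5) # quartiles 5.5 and 12.5

  single <- select_threshold(fake_scan(8, 0.01), pooled)
  expect_true(single$detected)
  expect_equal(single$tc, 8)

  weak <- select_threshold(fake_scan(c(8, 9), c(0.20, 0.30)), pooled)
  expect_false(weak$detected)

  tie <- select_threshold(fake_scan(c(8, 9.5, 11), c(0.01, 0.01, 0.02)), pooled)
  expect_true(tie$detected)
  expect_equal(tie$tc, 9.5) # max of the tied pair

  outside <- select_threshold(fake_scan(c(2, 8), c(0.001, 0.04)), pooled)
  expect_false(outside$detected) # best p sits below the first quartile
  expect_match(outside$reason, "quartile")
})

test_that("the quantified effect recovers the implanted loss and scales linearly", {
  rec <- make_records(n_years = 20, tc_true = 10, b_p = -5, noise_sd = 0, seed = 10)
  res <- detect_threshold(rec)
  expect_true(res$detected)
  eff <- quantify_effect(rec, res)
  expect_equal(eff$beta1, -5, tolerance = 1e-6)
  expect_true(eff$yield_loss_expected)

  doubled <- rec
  doubled$yf <- 2 * doubled$yf
  eff2 <- quantify_effect(doubled, detect_threshold(doubled))
  expect_equal(eff2$beta1, 2 * eff$beta1, tolerance = 1e-6)

  null_res <- structure(list(detected = FALSE), class = "tc_result")
  expect_error(quantify_effect(rec, null_res), "no threshold")
})

test_that("threshold detection recovers an implanted truth on controlled records", {
  rec <- make_records(n_years = 40, tc_true = 8, b_p = -8, b_r = 2,
                      noise_sd = 0, seed = 12)
  res <- detect_threshold(rec)
  expect_true(res$detected)
  expect_lt(abs(res$tc - 8), 0.1 + 1e-9)
  expect_equal(res$beta1, -8, tolerance = 1e-6)
})

test_that("geography regression recovers an exact plane", {
  set.seed(14)
  sites <- tibble::tibble(latitude = runif(12, -40, -25),
                          longitude = runif(12, 115, 152))
  sites$tc <- 40 + 0.5 * sites$latitude - 0.1 * sites$longitude
  geo <- spatial_threshold_regression(sites)
  expect_equal(unname(stats::coef(geo$fit)), c(40, 0.5, -0.1), tolerance = 1e-8)

  flat <- sites
  flat$tc <- 9.4
  geo_flat <- spatial_threshold_regression(flat)
  expect_equal(unname(stats::coef(geo_flat$fit))[2:3], c(0, 0), tolerance = 1e-10)

  perm <- sites[sample(nrow(sites)), ]
  geo_perm <- spatial_threshold_regression(perm)
  expect_equal(stats::coef(geo_perm$fit), stats::coef(geo$fit), tolerance = 1e-10)
  expect_error(spatial_threshold_regression(sites[1:2, ]), "3 sites")
})

test_that("tidy and glance methods expose the fitted quantities", {
  rec <- make_records(n_years = 20, noise_sd = 50, seed = 15)
  res <- detect_threshold(rec)
  td <- tidy(res)
  expect_named(td, c("term", "estimate", "p.value"))
  expect_equal(td$estimate[2], res$beta1)
  gl <- glance(res)
  expect_equal(gl$tc, res$tc)
  sc <- attr(res, "scan")
  expect_s3_class(autoplot(sc, res), "ggplot")
})
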