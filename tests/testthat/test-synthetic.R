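test_that("noise-free weather is the pure sinusoid with zero rain", {
  spec <- synthetic_spec(latitude = -35, years = 2000:2001,
                         temp_noise_sd = 0, temp_interannual_sd = 0,
                         rain_prob_per_day = 0, seed = 1)
  w <- generate_weather(spec)
  expect_true(all(w$rain == 0))
  doy <- as.integer(format(w$date, "%j"))
  tmean <- spec$temp_mean_annual -
    spec$temp_seasonal_amplitude * cos(2 * pi * (doy - 196) / 365.25)
  expect_equal(w$tmin, tmean - spec$diurnal_range_mean / 2)
  expect_equal(w$tmax, tmean + spec$diurnal_range_mean / 2)
})

test_that("weather generation is deterministic and structurally valid", {
  spec <- synthetic_spec(years = 1995:1999, seed = 11)
  w1 <- generate_weather(spec)
  w2 <- generate_weather(spec)
  expect_identical(w1, w2)
  expect_true(all(w1$tmin <= w1$tmax))
  expect_true(all(w1$rain >= 0))
  expect_equal(as.integer(diff(w1$date)), rep(1L, nrow(w1) - 1))
  expect_equal(nrow(w1), as.integer(sum(vapply(
    1995:1999, function(y) 365 + (y %% 4 == 0), numeric(1)))))
})

test_that("southern-hemisphere winter is colder than summer", {
  spec <- synthetic_spec(latitude = -35, temp_seasonal_amplitude = 8,
                         temp_mean_annual = 15, diurnal_range_mean = 10,
                         temp_noise_sd = 2, years = 1950:1959, seed = 1)
  w <- generate_weather(spec)
  mon <- format(w$date, "%m")
  jul <- mean(w$tmin[mon == "07"])
  jan <- mean(w$tmin[mon == "01"])
  expect_lt(jul, jan)
})

test_that("adding years does not perturb earlier years", {
  short <- generate_weather(synthetic_spec(years = 2000:2005, seed = 5))
  long <- generate_weather(synthetic_spec(years = 2000:2010, seed = 5))
  expect_identical(short, long[seq_len(nrow(short)), ])
})

test_that("invalid spec fields raise errors naming the field", {
  expect_error(synthetic_spec(rain_prob_per_day = 1.5), "rain_prob_per_day")
  expect_error(synthetic_spec(temp_seasonal_amplitude = -1), "temp_seasonal_amplitude")
  expect_error(synthetic_spec(implanted_tc = 25), "implanted_tc")
  expect_error(synthetic_spec(yield_cold_coef = -2), "yield_cold_coef")
})

test_that("yield generator reproduces exact arithmetic without noise", {
  spec <- synthetic_spec(yield_intercept = 1000, yield_rain_coef = 2,
                         yield_cold_coef = 10, yield_noise_sd = 0, seed = 1)
  out <- generate_yields(tibble::tibble(year = 2000, r = 100, p_cold = 20), spec)
  expect_equal(out$potential_yield, 1000) # 1000 + 200 - 200
})

test_that("a zero cold coefficient makes yields independent of cold days", {
  spec <- synthetic_spec(yield_cold_coef = 0, yield_noise_sd = 0, seed = 1)
  df <- tibble::tibble(year = 2000:2004, r = 100,
                       p_cold = c(0, 10, 40, 70, 100))
  out <- generate_yields(df, spec)
  expect_true(all(out$potential_yield == out$potential_yield[1]))
})

test_that("noise-free yields return the implanted coefficients under OLS", {
  spec <- synthetic_spec(yield_intercept = 1000, yield_rain_coef = 2,
                         yield_cold_coef = 5, yield_noise_sd = 0, seed = 9)
  set.seed(42)
  df <- tibble::tibble(year = 1950:2019,
                       r = runif(70, 40, 260),
                       p_cold = runif(70, 0, 80))
  out <- generate_yields(df, spec)
  beta <- ols_oracle(out$potential_yield, out$p_cold, out$r)$beta
  expect_equal(beta, c(1000, -5, 2), tolerance = 1e-9)
})

test_that("yield noise is drawn per year, stable under added years", {
  spec_a <- synthetic_spec(yield_noise_sd = 50, seed = 3)
  df <- tibble::tibble(year = 1960:1969, r = 100, p_cold = 10)
  y_a <- generate_yields(df, spec_a)$potential_yield
  y_b <- generate_yields(df[1:5, ], spec_a)$potential_yield
  expect_identical(y_a[1:5], y_b)
})
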