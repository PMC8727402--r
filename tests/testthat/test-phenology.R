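test_that("daily thermal time honours its cardinal-temperature identities", {
  cv <- plain_cultivar()
  expect_equal(daily_thermal_time(0, 0, cv), 0)   # at base
  expect_equal(daily_thermal_time(-5, -1, cv), 0) # below base
  expect_equal(daily_thermal_time(30, 30, cv), 30) # at optimum: opt - base
  expect_error(daily_thermal_time(10, 5, cv), "tmin")
})

test_that("daily thermal time equals the eight-point interpolation oracle", {
  cv <- plain_cultivar()
  oracle <- function(tmin, tmax) {
    k <- 1:8
    fr <- 0.92105 + 0.1140 * k - 0.0703 * k^2 + 0.0053 * k^3
    temps <- tmin + (tmax - tmin) * fr
    resp <- vapply(temps, function(t) {
      if (t <= 0 || t >= 40) 0
      else if (t <= 30) t
      else (40 - t) / 10 * 30
    }, numeric(1))
    mean(resp)
  }
  cases <- list(c(5, 15), c(-3, 12), c(20, 38), c(28, 40), c(0, 30))
  for (cs in cases) {
    expect_equal(daily_thermal_time(cs[1], cs[2], cv), oracle(cs[1], cs[2]),
                 tolerance = 1e-12)
  }
})

test_that("the soil-water modifier follows the linear multiplier above the boundary", {
  cv <- plain_cultivar()
  expect_equal(modify_thermal_time(10, 0.5, 5, cv), 10)   # below boundary
  expect_equal(modify_thermal_time(10, 0.65, 5, cv), 10)  # multiplier exactly 1
  expect_equal(modify_thermal_time(10, 1.0, 5, cv), 6.5)  # 10 * (1.65 - 1)
  expect_equal(modify_thermal_time(10, 1.0, 2, cv), 10)   # pre-emergence exempt
  # never exceeds the unmodified value
  fasw <- seq(0, 1, by = 0.05)
  expect_true(all(modify_thermal_time(8, fasw, 5, cv) <= 8 + 1e-12))
})

test_that("photoperiod factor ramps linearly between critical and saturating", {
  cv0 <- plain_cultivar()
  expect_equal(photoperiod_factor(c(8, 11, 15), cv0), c(1, 1, 1)) # insensitive
  cv <- cultivar_config(photoperiod_critical = 10, photoperiod_saturating = 14,
                        photoperiod_sensitivity = 0.4)
  expect_equal(photoperiod_factor(14, cv), 1)
  expect_equal(photoperiod_factor(16, cv), 1)
  expect_equal(photoperiod_factor(10, cv), 0.6)
  expect_equal(photoperiod_factor(12, cv), 0.8) # midpoint
})

test_that("day length behaves astronomically", {
  expect_equal(day_length(0, 172), 12, tolerance = 0.2 / 12)
  expect_lt(day_length(-35, 172), day_length(-35, 355)) # austral winter < summer
  expect_equal(day_length(-35, 80), 12, tolerance = 0.3 / 12)
  expect_error(day_length(-80, 100), "latitude")
})

test_that("sowing rule fires on rain + stored water, else forces the last day", {
  soil <- one_layer_soil()
  # immediate trigger: 25 mm on window day 1 with ample stored water
  w <- make_weather(40, rain = c(rep(0, 9), 25, rep(0, 30)),
                    start = as.Date("2000-05-01"))
  sw <- simulate_soil_water(w, soil, et_coef = 0, init = 160)
  win <- as.Date(c("2000-05-10", "2000-05-30"))
  out <- choose_sowing_date(w, sw, soil, win)
  expect_equal(out$sowing_date, as.Date("2000-05-10"))
  expect_false(out$forced)

  # no rain at all: forced to the window's last day
  w0 <- make_weather(40, rain = 0, start = as.Date("2000-05-01"))
  sw0 <- simulate_soil_water(w0, soil, et_coef = 0, init = 160)
  out0 <- choose_sowing_date(w0, sw0, soil, win)
  expect_equal(out0$sowing_date, win[2])
  expect_true(out0$forced)

  # 4 mm/day from the window start reaches a 28 mm trailing total on day 7
  rain <- c(rep(0, 9), rep(4, 31))
  w4 <- make_weather(40, rain = rain, start = as.Date("2000-05-01"))
  sw4 <- simulate_soil_water(w4, soil, et_coef = 0, init = 160)
  out4 <- choose_sowing_date(w4, sw4, soil, win)
  expect_equal(out4$sowing_date, as.Date("2000-05-16")) # window day 7
  expect_false(out4$forced)
})

test_that("phenology never advances without thermal time and flags incompleteness", {
  cv <- plain_cultivar()
  w <- make_weather(120, tmin = 0, tmax = 0)
  fasw <- tibble::tibble(date = w$date, fasw = 0.5)
  ph <- run_phenology(w, NULL, NULL, cv, w$date[1], fasw = fasw)
  expect_false(ph$complete)
  expect_true(all(ph$trace$stage == 2))
  expect_true(is.na(ph$flowering_start))
})

test_that("stage-entry days match hand accumulation with the 0.65 multiplier", {
  cv <- plain_cultivar() # targets 100 / 690 / 200, photoperiod off
  w <- make_weather(400, tmin = 10, tmax = 10) # tt = 10 Cd/day exactly
  fasw <- tibble::tibble(date = w$date, fasw = 1.0)
  sow <- w$date[1]
  ph <- run_phenology(w, NULL, NULL, cv, sow, fasw = fasw)
  expect_equal(as.numeric(ph$emergence - sow), 10)
  d_juv <- ceiling(690 / 6.5)
  d_fl <- ceiling(200 / 6.5)
  expect_equal(as.numeric(ph$flowering_start - sow), 10 + d_juv + d_fl)
  # stage sequence is non-decreasing and ttm never exceeds tt
  expect_true(all(diff(ph$trace$stage) >= 0))
  expect_true(all(ph$trace$ttm_day <= ph$trace$tt_day + 1e-12))
})

test_that("peak flowering is the floored mid-point of the flowering span", {
  cv <- plain_cultivar()
  w <- make_weather(500, tmin = 10, tmax = 10)
  fasw <- tibble::tibble(date = w$date, fasw = 0.5) # modifier off: 10 Cd/day
  ph <- run_phenology(w, NULL, NULL, cv, w$date[1], fasw = fasw)
  expect_true(ph$complete)
  span <- as.numeric(ph$flowering_end - ph$flowering_start)
  expect_equal(ph$peak_flowering, ph$flowering_start + floor(span / 2))
  expect_true(ph$flowering_start <= ph$peak_flowering &&
                ph$peak_flowering <= ph$flowering_end)
})

test_that("cumulative TTm matches a day-loop oracle on constant weather", {
  cv <- plain_cultivar()
  set.seed(7)
  for (rep in 1:5) {
    fasw_vals <- round(runif(30, 0.3, 1), 3)
    w <- make_weather(30, tmin = 12, tmax = 22)
    fasw <- tibble::tibble(date = w$date, fasw = fasw_vals)
    ph <- run_phenology(w, NULL, NULL, cv, w$date[1], fasw = fasw)
    tt_day <- daily_thermal_time(12, 22, cv)
    # oracle: day loop (accumulation starts the day after sowing) with
    # per-phase reset and the modifier active from stage 3
    stage <- 2; cum <- 0; cums <- numeric(0)
    targets <- c(NA, 100, 690, 200, 130, 260)
    for (d in 2:30) {
      inc <- if (stage >= 3 && fasw_vals[d] > 0.65) tt_day * (1.65 - fasw_vals[d]) else tt_day
      cum <- cum + inc
      cums <- c(cums, cum)
      if (stage <= 5 && !is.na(targets[stage]) && cum >= targets[stage]) {
        stage <- stage + 1
        if (stage != 6) cum <- 0
      }
    }
    expect_equal(ph$trace$cum_ttm, cums, tolerance = 1e-12)
  }
})

test_that("ttm equals tt whenever FASW stays below the activation boundary", {
  cv <- plain_cultivar()
  w <- make_weather(200, tmin = 8, tmax = 18)
  fasw <- tibble::tibble(date = w$date, fasw = 0.64)
  ph <- run_phenology(w, NULL, NULL, cv, w$date[1], fasw = fasw)
  expect_equal(ph$trace$ttm_day, ph$trace$tt_day)
})

test_that("wetter soil never flowers earlier (spot check)", {
  cv <- plain_cultivar()
  w <- make_weather(300, tmin = 10, tmax = 20)
  set.seed(21)
  for (i in 1:20) {
    base <- runif(300, 0.3, 1)
    d <- sample(30:150, 1) # after emergence
    lo <- runif(1, 0.65, 0.95)
    hi <- runif(1, lo, 1)
    fb <- base; fb[d] <- lo
    fa <- base; fa[d] <- hi
    ph_a <- run_phenology(w, NULL, NULL, cv, w$date[1],
                          fasw = tibble::tibble(date = w$date, fasw = fa))
    ph_b <- run_phenology(w, NULL, NULL, cv, w$date[1],
                          fasw = tibble::tibble(date = w$date, fasw = fb))
    expect_gte(as.numeric(ph_a$flowering_start), as.numeric(ph_b$flowering_start))
  }
})

test_that("sowing outside the weather span errors", {
  cv <- plain_cultivar()
  w <- make_weather(50)
  fasw <- tibble::tibble(date = w$date, fasw = 0.5)
  expect_error(run_phenology(w, NULL, NULL, cv, max(w$date) + 10, fasw = fasw),
               "weather span")
})
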