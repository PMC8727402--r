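#' Specification for the synthetic study generator
#'
#' Bundles every parameter of the synthetic data generator: the stochastic
#' daily weather model, and the linear yield model with an implanted
#' cold-temperature threshold. The defaults describe a frosty inland
#' south-eastern Australian site (a Wagga Wagga-like climate at 35 S) with a
#' sharp chilling effect implanted at 10 C so that the threshold-detection
#' machinery has a known truth to recover.
#'
#' The weather model is deliberately simple: daily mean temperature is an
#' annual sinusoid (coldest mid-year in the southern hemisphere) plus a
#' per-year interannual anomaly and an AR(1) daily anomaly whose persistence
#' produces the multi-day warm and cold spells real synoptic weather has; the
#' diurnal range has a constant mean with its own noise; rain is Bernoulli
#' occurrence times a Gamma amount. Frost incidence is controlled by (mean,
#' amplitude, noise), not a separate dial.
#'
#' Annual potential yield is
#' \deqn{Y_t = \gamma_0 + \gamma_2 R_t - \gamma_1 P_t(T_C) + \epsilon_t,}
#' where \eqn{R_t} is reproductive-period rainfall (mm), \eqn{P_t} the
#' percentage of reproductive-period days with minimum temperature at or below
#' the implanted threshold, and \eqn{\gamma_1 \ge 0} a loss magnitude
#' (kg/ha per percentage point).
#'
#' @param latitude Degrees; negative = southern hemisphere.
#' @param longitude Degrees east.
#' @param years Integer vector (inclusive range is taken) of calendar years.
#' @param temp_mean_annual Annual mean temperature, C.
#' @param temp_seasonal_amplitude Half peak-to-trough seasonal swing, C (>= 0).
#' @param diurnal_range_mean Mean daily tmax - tmin, C.
#' @param temp_noise_sd Stationary sd of the daily temperature anomaly, C.
#' @param temp_noise_ar1 Lag-1 autocorrelation of the daily anomaly in
#'   \[0, 1); 0 gives iid noise.
#' @param temp_interannual_sd Sd of the per-year mean-temperature anomaly, C.
#' @param rain_prob_per_day Probability any day is wet, in \[0, 1\].
#' @param rain_gamma_shape,rain_gamma_scale Gamma parameters of wet-day rain, mm.
#' @param yield_intercept Baseline yield gamma0, kg/ha.
#' @param yield_rain_coef gamma2, kg/ha per mm of reproductive-period rain.
#' @param yield_cold_coef gamma1 >= 0, kg/ha lost per 1 percentage-point
#'   increase in cold-day percentage.
#' @param implanted_tc Implanted cold threshold, C; must lie in \[0, 19\] so
#'   the detection grid can recover it.
#' @param yield_noise_sd Yield noise sd, kg/ha.
#' @param seed Master seed (all generator randomness derives from it).
#'
#' @return An object of class `synthetic_spec` (a named list).
#' @export
#' @examples
#' spec <- synthetic_spec(years = 1990:1999, seed = 42)
#' w <- generate_weather(spec)
#' head(w)
synthetic_spec <- function(latitude = -35,
                           longitude = 147,
                           years = 1950:2019,
                           temp_mean_annual = 16,
                           temp_seasonal_amplitude = 8.5,
                           diurnal_range_mean = 13,
                           temp_noise_sd = 2.5,
                           temp_noise_ar1 = 0.7,
                           temp_interannual_sd = 0.3,
                           rain_prob_per_day = 0.28,
                           rain_gamma_shape = 1.2,
                           rain_gamma_scale = 4.5,
                           yield_intercept = 1000,
                           yield_rain_coef = 2,
                           yield_cold_coef = 5,
                           implanted_tc = 10,
                           yield_noise_sd = 100,
                           seed = 1L) {
  check_number(latitude, "latitude", -66, 66)
  check_number(longitude, "longitude", -180, 360)
  if (length(years) < 1 || any(years != as.integer(years))) {
    abort("`years` must be a non-empty integer range.")
  }
  years <- seq.int(min(years), max(years))
  check_number(temp_mean_annual, "temp_mean_annual")
  check_number(temp_seasonal_amplitude, "temp_seasonal_amplitude", lower = 0)
  check_number(diurnal_range_mean, "diurnal_range_mean", lower = 0)
  check_number(temp_noise_sd, "temp_noise_sd", lower = 0)
  check_number(temp_noise_ar1, "temp_noise_ar1", 0, 1 - 1e-9)
  check_number(temp_interannual_sd, "temp_interannual_sd", lower = 0)
  check_number(rain_prob_per_day, "rain_prob_per_day", 0, 1)
  if (rain_gamma_shape <= 0) abort("`rain_gamma_shape` must be > 0.")
  if (rain_gamma_scale <= 0) abort("`rain_gamma_scale` must be > 0.")
  check_number(yield_intercept, "yield_intercept")
  check_number(yield_rain_coef, "yield_rain_coef")
  check_number(yield_cold_coef, "yield_cold_coef", lower = 0)
  check_number(implanted_tc, "implanted_tc", 0, 19)
  check_number(yield_noise_sd, "yield_noise_sd", lower = 0)
  check_number(seed, "seed")

  structure(list(
    latitude = latitude, longitude = longitude, years = years,
    temp_mean_annual = temp_mean_annual,
    temp_seasonal_amplitude = temp_seasonal_amplitude,
    diurnal_range_mean = diurnal_range_mean,
    temp_noise_sd = temp_noise_sd,
    temp_noise_ar1 = temp_noise_ar1,
    temp_interannual_sd = temp_interannual_sd,
    rain_prob_per_day = rain_prob_per_day,
    rain_gamma_shape = rain_gamma_shape,
    rain_gamma_scale = rain_gamma_scale,
    yield_intercept = yield_intercept,
    yield_rain_coef = yield_rain_coef,
    yield_cold_coef = yield_cold_coef,
    implanted_tc = implanted_tc,
    yield_noise_sd = yield_noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat("<synthetic_spec>\n")
  cat(sprintf("  site: lat %g, lon %g; years %d-%d\n",
              x$latitude, x$longitude, min(x$years), max(x$years)))
  cat(sprintf("  temperature: mean %g C, amplitude %g C, diurnal %g C, noise %g C (interannual %g C)\n",
              x$temp_mean_annual, x$temp_seasonal_amplitude,
              x$diurnal_range_mean, x$temp_noise_sd, x$temp_interannual_sd))
  cat(sprintf("  rain: p(wet) %g, Gamma(%g, %g) mm\n",
              x$rain_prob_per_day, x$rain_gamma_shape, x$rain_gamma_scale))
  cat(sprintf("  yield: %g + %g R - %g P(Tc = %g C) + N(0, %g^2) kg/ha\n",
              x$yield_intercept, x$yield_rain_coef, x$yield_cold_coef,
              x$implanted_tc, x$yield_noise_sd))
  invisible(x)
}

#' Generate a SILO-style daily weather series
#'
#' One row per calendar day over the spec's year range, with contiguous dates.
#' Temperature follows an annual sinusoid phased so the coldest period falls
#' mid-year in the southern hemisphere (January when `latitude >= 0`), with a
#' per-year anomaly and daily Gaussian noise. With all noise terms at zero the
#' series is the pure sinusoid. Radiation is a deterministic seasonal curve in
#' phase with temperature.
#'
#' @param spec A [synthetic_spec()].
#' @return A tibble with columns `date`, `tmin`, `tmax`, `rain`, `radn`.
#'   `tmin <= tmax` on every row and `rain >= 0`.
#' @export
generate_weather <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must be a synthetic_spec.")
  cold_doy <- if (spec$latitude < 0) 196 else 15
  per_year <- lapply(spec$years, function(y) {
    dates <- seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)), by = "day")
    nd <- length(dates)
    doy <- as.integer(format(dates, "%j"))
    tmean_season <- spec$temp_mean_annual -
      spec$temp_seasonal_amplitude * cos(2 * pi * (doy - cold_doy) / 365.25)
    draws <- with_substream(spec$seed, y, 1L, expr = {
      # AR(1) daily anomaly with stationary sd temp_noise_sd: persistence
      # produces the multi-day cold spells that drive chilling exposure
      rho <- spec$temp_noise_ar1
      innov <- rnorm(nd, 0, spec$temp_noise_sd * sqrt(1 - rho^2))
      tnoise <- numeric(nd)
      if (nd > 0) {
        tnoise[1] <- if (spec$temp_noise_sd > 0) {
          rnorm(1, 0, spec$temp_noise_sd)
        } else 0
        for (d in seq_len(nd - 1)) {
          tnoise[d + 1] <- rho * tnoise[d] + innov[d + 1]
        }
      }
      list(anom = rnorm(1, 0, spec$temp_interannual_sd),
           tnoise = tnoise,
           dnoise = rnorm(nd, 0, spec$temp_noise_sd),
           wet = rbinom(nd, 1, spec$rain_prob_per_day),
           amt = rgamma(nd, shape = spec$rain_gamma_shape, scale = spec$rain_gamma_scale))
    })
    # with temp_interannual_sd = 0 the anomaly draw is exactly 0
    tmean <- tmean_season + draws$anom + draws$tnoise
    rng <- pmax(0, spec$diurnal_range_mean + draws$dnoise)
    # radiation minimum coincides with the temperature minimum
    radn <- pmax(1, 18 - 8 * cos(2 * pi * (doy - cold_doy) / 365.25))
    tibble(
      date = dates,
      tmin = tmean - rng / 2,
      tmax = tmean + rng / 2,
      rain = draws$wet * draws$amt,
      radn = round(radn, 2)
    )
  })
  dplyr::bind_rows(per_year)
}

#' Generate annual potential yields with an implanted cold effect
#'
#' Applies the synthetic yield model
#' `gamma0 + gamma2 * r - gamma1 * p_cold + noise`, floored at zero, to a table
#' of per-year covariates. `p_cold` must be the cold-day percentage evaluated
#' at the spec's implanted threshold (see [percent_cold_days()]).
#'
#' @param data A data frame with one row per year and columns `year`, `r`
#'   (reproductive-period rainfall, mm) and `p_cold` (cold-day percentage at
#'   the implanted threshold).
#' @param spec A [synthetic_spec()]; supplies the coefficients, the noise sd
#'   and the seed (noise is drawn from a per-year substream, so adding years
#'   never changes earlier years).
#' @return The input tibble with a `potential_yield` column (kg/ha) appended.
#' @export
generate_yields <- function(data, spec) {
  if (!inherits(spec, "synthetic_spec")) abort("`spec` must be a synthetic_spec.")
  if (spec$yield_cold_coef < 0) abort("`yield_cold_coef` must be >= 0 (loss magnitude).")
  need <- c("year", "r", "p_cold")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) abort(paste0("data is missing column(s): ", paste(miss, collapse = ", ")))
  noise <- vapply(data$year, function(y) {
    with_substream(spec$seed, y, 2L, expr = rnorm(1, 0, spec$yield_noise_sd))
  }, numeric(1))
  y <- spec$yield_intercept + spec$yield_rain_coef * data$r -
    spec$yield_cold_coef * data$p_cold + noise
  dplyr::mutate(as_tibble(data), potential_yield = pmax(0, y))
}
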