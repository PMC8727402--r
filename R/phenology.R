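#' Cultivar phenology configuration
#'
#' Thermal-time targets (degree-days) for each developmental phase, cardinal
#' temperatures of the daily thermal-time response, the photoperiod response,
#' and the soil-water modifier constants. Growth stages are numbered
#' 1 sowing, 2 germination, 3 emergence, 4 end of juvenile phase, 5 flowering,
#' 6 end of flowering, 7 end of pod fill, 8 maturity.
#'
#' @param tt_sowing_to_emergence,tt_emergence_to_end_juvenile,tt_end_juvenile_to_flowering
#'   Phase thermal-time targets, degree-days (Cd).
#' @param tt_flowering_to_end_flowering,tt_flowering_to_end_podfill Targets
#'   measured from the start of flowering, Cd; pod fill must end after
#'   flowering ends.
#' @param base_temp,opt_temp,max_temp Cardinal temperatures, C
#'   (`base < opt < max`).
#' @param photoperiod_critical,photoperiod_saturating Day lengths (h) bounding
#'   the linear photoperiod ramp.
#' @param photoperiod_sensitivity Fraction in \[0, 1\]; 0 disables the
#'   photoperiod response.
#' @param fasw_threshold Fractional available soil water above which the
#'   soil-water modifier is active (default 0.65).
#' @param fasw_modifier_intercept Intercept of the linear multiplier
#'   `intercept - FASW` (default 1.65); must exceed `fasw_threshold` so the
#'   multiplier stays positive on \[threshold, 1\].
#' @param name Cultivar label carried into result tables.
#' @return An object of class `cultivar_config`.
#' @export
cultivar_config <- function(name = "synthetic",
                            tt_sowing_to_emergence = 120,
                            tt_emergence_to_end_juvenile = 690,
                            tt_end_juvenile_to_flowering = 40,
                            tt_flowering_to_end_flowering = 400,
                            tt_flowering_to_end_podfill = 800,
                            base_temp = 0,
                            opt_temp = 30,
                            max_temp = 40,
                            photoperiod_critical = 10,
                            photoperiod_saturating = 14,
                            photoperiod_sensitivity = 0,
                            fasw_threshold = 0.65,
                            fasw_modifier_intercept = 1.65) {
  tts <- c(tt_sowing_to_emergence, tt_emergence_to_end_juvenile,
           tt_end_juvenile_to_flowering, tt_flowering_to_end_flowering,
           tt_flowering_to_end_podfill)
  if (any(tts <= 0)) abort("all thermal-time targets must be > 0.")
  if (tt_flowering_to_end_podfill <= tt_flowering_to_end_flowering) {
    abort("`tt_flowering_to_end_podfill` must exceed `tt_flowering_to_end_flowering`.")
  }
  if (!(base_temp < opt_temp && opt_temp < max_temp)) {
    abort("cardinal temperatures must satisfy base_temp < opt_temp < max_temp.")
  }
  check_number(photoperiod_sensitivity, "photoperiod_sensitivity", 0, 1)
  if (photoperiod_critical >= photoperiod_saturating) {
    abort("`photoperiod_critical` must be below `photoperiod_saturating`.")
  }
  check_number(fasw_threshold, "fasw_threshold", 0, 1)
  if (fasw_modifier_intercept <= fasw_threshold) {
    abort("`fasw_modifier_intercept` must exceed `fasw_threshold`.")
  }
  structure(list(
    name = name,
    tt_sowing_to_emergence = tt_sowing_to_emergence,
    tt_emergence_to_end_juvenile = tt_emergence_to_end_juvenile,
    tt_end_juvenile_to_flowering = tt_end_juvenile_to_flowering,
    tt_flowering_to_end_flowering = tt_flowering_to_end_flowering,
    tt_flowering_to_end_podfill = tt_flowering_to_end_podfill,
    base_temp = base_temp, opt_temp = opt_temp, max_temp = max_temp,
    photoperiod_critical = photoperiod_critical,
    photoperiod_saturating = photoperiod_saturating,
    photoperiod_sensitivity = photoperiod_sensitivity,
    fasw_threshold = fasw_threshold,
    fasw_modifier_intercept = fasw_modifier_intercept
  ), class = "cultivar_config")
}

#' Shipped PBA HatTrick configuration
#'
#' The packaged desi chickpea reference cultivar. The
#' emergence-to-end-of-juvenile thermal time is 690 Cd; the remaining phase
#' targets and cardinal temperatures are synthetic calibration values chosen
#' so that a May sowing at a 35 S inland site flowers in September and
#' finishes pod fill in November, the phenology observed for this cultivar in
#' south-eastern Australia.
#'
#' @return A [cultivar_config()].
#' @export
cultivar_hattrick <- function() {
  cultivar_config(
    name = "PBA HatTrick",
    tt_sowing_to_emergence = 120,
    tt_emergence_to_end_juvenile = 690,
    tt_end_juvenile_to_flowering = 40,
    tt_flowering_to_end_flowering = 400,
    tt_flowering_to_end_podfill = 800,
    base_temp = 0, opt_temp = 30, max_temp = 40,
    photoperiod_critical = 10, photoperiod_saturating = 14,
    photoperiod_sensitivity = 0.15
  )
}

#' @export
print.cultivar_config <- function(x, ...) {
  cat(sprintf("<cultivar_config> %s\n", x$name))
  cat(sprintf("  TT targets (Cd): sow->emerg %g, emerg->juv %g, juv->flower %g, flower->end %g, flower->podfill %g\n",
              x$tt_sowing_to_emergence, x$tt_emergence_to_end_juvenile,
              x$tt_end_juvenile_to_flowering, x$tt_flowering_to_end_flowering,
              x$tt_flowering_to_end_podfill))
  cat(sprintf("  cardinal temps: %g/%g/%g C; photoperiod %g-%g h, sensitivity %g\n",
              x$base_temp, x$opt_temp, x$max_temp, x$photoperiod_critical,
              x$photoperiod_saturating, x$photoperiod_sensitivity))
  cat(sprintf("  soil-water modifier: TTm = TT x (%g - FASW) when FASW > %g\n",
              x$fasw_modifier_intercept, x$fasw_threshold))
  invisible(x)
}

# 3-hourly interpolation fractions between tmin and tmax (eight periods).
THREE_HOURLY_FRACS <- local({
  k <- 1:8
  0.92105 + 0.1140 * k - 0.0703 * k^2 + 0.0053 * k^3
})

#' Daily thermal time from minimum and maximum temperature
#'
#' Eight three-hourly temperatures are interpolated between `tmin` and `tmax`,
#' each is passed through a piecewise-linear temperature response (zero at the
#' base temperature, rising linearly to `opt_temp - base_temp` at the optimum,
#' falling linearly back to zero at the maximum), and the eight responses are
#' averaged. The result is in degree-days: non-negative, zero for days wholly
#' at or below the base temperature, and never above `opt_temp - base_temp`.
#'
#' @param tmin,tmax Daily extremes, C (vectorised; `tmin <= tmax`).
#' @param cultivar A [cultivar_config()] supplying the cardinal temperatures.
#' @return Numeric vector of daily thermal time, Cd.
#' @export
#' @examples
#' cv <- cultivar_config()
#' daily_thermal_time(5, 15, cv)
daily_thermal_time <- function(tmin, tmax, cultivar) {
  if (any(tmin > tmax)) abort("`tmin` must not exceed `tmax`.")
  resp <- function(temp) {
    r <- numeric(length(temp))
    up <- temp > cultivar$base_temp & temp <= cultivar$opt_temp
    dn <- temp > cultivar$opt_temp & temp < cultivar$max_temp
    r[up] <- temp[up] - cultivar$base_temp
    r[dn] <- (cultivar$max_temp - temp[dn]) / (cultivar$max_temp - cultivar$opt_temp) *
      (cultivar$opt_temp - cultivar$base_temp)
    r
  }
  acc <- 0
  for (f in THREE_HOURLY_FRACS) {
    acc <- acc + resp(tmin + (tmax - tmin) * f)
  }
  acc / 8
}

#' Soil-water modification of daily thermal time
#'
#' Wet soil slows perceived thermal time: once the crop has emerged
#' (stage >= 3) and fractional available soil water exceeds the activation
#' boundary, daily thermal time is multiplied by
#' `fasw_modifier_intercept - FASW` (default `1.65 - FASW`), a factor of 1 at
#' the boundary falling to 0.65 at field capacity. Below the boundary, or
#' before emergence, thermal time is returned unchanged. The boundary itself
#' is treated as unmodified, which is mathematically identical (the multiplier
#' there is exactly one) and numerically exact.
#'
#' @param tt_day Daily thermal time, Cd (vectorised, non-negative).
#' @param fasw Fractional available soil water in \[0, 1\] (vectorised).
#' @param stage Growth stage code (vectorised; see [cultivar_config()]).
#' @param cultivar A [cultivar_config()].
#' @return Modified daily thermal time, Cd; always `<= tt_day`.
#' @export
#' @examples
#' cv <- cultivar_config()
#' modify_thermal_time(10, fasw = 1.0, stage = 5, cv)  # 6.5
#' modify_thermal_time(10, fasw = 0.5, stage = 5, cv)  # unmodified
modify_thermal_time <- function(tt_day, fasw, stage, cultivar) {
  if (any(tt_day < 0)) abort("`tt_day` must be non-negative.")
  if (any(fasw < 0 | fasw > 1)) abort("`fasw` must lie in [0, 1].")
  active <- stage >= 3 & fasw > cultivar$fasw_threshold
  ifelse(active, tt_day * (cultivar$fasw_modifier_intercept - fasw), tt_day)
}

#' Photoperiod factor on thermal-time accumulation
#'
#' Linear ramp between the critical and saturating day lengths: 1 at or above
#' the saturating day length, `1 - photoperiod_sensitivity` at or below the
#' critical day length, linear in between. Short days therefore increase the
#' thermal-time requirement to reach a stage target. The factor multiplies the
#' (soil-water-modified) daily thermal time during post-emergence accumulation.
#'
#' @param day_length_h Day length, h (vectorised, in (0, 24\]).
#' @param cultivar A [cultivar_config()].
#' @return Factor in \[`1 - sensitivity`, 1\].
#' @export
photoperiod_factor <- function(day_length_h, cultivar) {
  if (any(day_length_h <= 0 | day_length_h > 24)) {
    abort("`day_length_h` must lie in (0, 24].")
  }
  s <- cultivar$photoperiod_sensitivity
  if (s == 0) return(rep(1, length(day_length_h)))
  frac <- (day_length_h - cultivar$photoperiod_critical) /
    (cultivar$photoperiod_saturating - cultivar$photoperiod_critical)
  1 - s * (1 - pmin(pmax(frac, 0), 1))
}

#' Astronomical day length
#'
#' Civil daylight hours (standard sunrise-equation day length, no twilight
#' correction) for a latitude and day of year.
#'
#' @param latitude Degrees, `|latitude| < 67` (polar day/night out of scope).
#' @param day_of_year Integer day of year, 1-366 (vectorised).
#' @return Day length in hours.
#' @export
day_length <- function(latitude, day_of_year) {
  if (abs(latitude) >= 67) abort("`latitude` must satisfy |latitude| < 67.")
  geosphere::daylength(latitude, day_of_year)
}

#' Rainfall- and soil-water-triggered sowing date
#'
#' Scans the sowing window for the first day whose trailing 7-day rainfall
#' total (inclusive of the day) is at least `rain_trigger` mm and whose
#' whole-profile plant-available water exceeds `paw_trigger` mm. If no day in
#' the window qualifies, sowing is forced on the last day of the window.
#'
#' @param weather Weather tibble covering the window (and the six days before
#'   it for the trailing rain total).
#' @param soilwater Soil-water series from [simulate_soil_water()].
#' @param soil The matching [soil_profile()].
#' @param window Length-2 Date vector, start and end of the sowing window.
#' @param rain_trigger 7-day cumulative rainfall threshold, mm (default 25).
#' @param paw_trigger Plant-available water threshold, mm (default 80;
#'   strictly exceeded).
#' @return One-row tibble with `sowing_date` and logical `forced`.
#' @export
choose_sowing_date <- function(weather, soilwater, soil, window,
                               rain_trigger = 25, paw_trigger = 80) {
  check_weather(weather)
  if (length(window) != 2 || !inherits(window, "Date")) {
    abort("`window` must be two Dates (start, end).")
  }
  if (window[1] > window[2]) abort("window start must not be after its end.")
  if (window[1] < min(weather$date) || window[2] > max(weather$date)) {
    abort("sowing window lies outside the weather span.")
  }
  rain7 <- as.numeric(stats::filter(weather$rain, rep(1, 7), sides = 1))
  rain7[is.na(rain7)] <- cumsum(weather$rain)[is.na(rain7)]
  summ <- soil_water_summary(soilwater, soil)
  idx <- which(weather$date >= window[1] & weather$date <= window[2])
  paw <- summ$paw[match(weather$date[idx], summ$date)]
  ok <- rain7[idx] >= rain_trigger & paw > paw_trigger
  if (any(ok)) {
    tibble(sowing_date = weather$date[idx[which(ok)[1]]], forced = FALSE)
  } else {
    tibble(sowing_date = window[2], forced = TRUE)
  }
}

#' Run the daily phenology engine from a sowing date
#'
#' Accumulates soil-water-modified, photoperiod-scaled thermal time day by day
#' and advances the growth stage whenever the current phase target is met
#' (accumulation restarts at each stage entry; flowering, end of flowering and
#' end of pod fill share the accumulator started at flowering). Before
#' emergence, raw thermal time drives the seed phase and neither the
#' soil-water modifier nor the photoperiod factor applies. Peak flowering is
#' the mid-point between the start and end of flowering, floored to a whole
#' day. If the weather series ends before pod fill completes, the trace is
#' truncated and flagged incomplete.
#'
#' @param weather Weather tibble spanning the sowing date.
#' @param soilwater Soil-water series from [simulate_soil_water()], or `NULL`
#'   when `fasw` is supplied.
#' @param soil The matching [soil_profile()] (ignored when `fasw` is supplied).
#' @param cultivar A [cultivar_config()].
#' @param sowing_date Date of sowing (within the weather span).
#' @param latitude Site latitude, degrees (for day length).
#' @param fasw Optional precomputed tibble with columns `date`, `fasw`
#'   (e.g. from [soil_water_summary()]); avoids recomputing FASW per call.
#' @param horizon Maximum crop-cycle length considered, days after sowing;
#'   a crop not completing pod fill within it is flagged incomplete.
#' @return An object of class `pheno_trace`: stage-entry dates
#'   (`sowing_date`, `emergence`, `end_juvenile`, `flowering_start`,
#'   `flowering_end`, `peak_flowering`, `podfill_end`), a `complete` flag, and
#'   a daily `trace` tibble (`date`, `stage`, `tt_day`, `ttm_day`, `fasw`,
#'   `cum_ttm`). Retrieve the daily table with [tidy()] and the key dates with
#'   [glance()].
#' @export
run_phenology <- function(weather, soilwater, soil, cultivar, sowing_date,
                          latitude = -35, fasw = NULL, horizon = 450) {
  check_weather(weather)
  if (!inherits(cultivar, "cultivar_config")) abort("`cultivar` must be a cultivar_config.")
  sowing_date <- as.Date(sowing_date)
  if (sowing_date > max(weather$date) || sowing_date < min(weather$date)) {
    abort("`sowing_date` lies outside the weather span.")
  }
  if (is.null(fasw)) {
    fasw <- soil_water_summary(soilwater, soil)[, c("date", "fasw")]
  }

  days <- weather[weather$date > sowing_date &
                    weather$date <= sowing_date + horizon, , drop = FALSE]
  fasw_day <- fasw$fasw[match(days$date, fasw$date)]
  if (anyNA(fasw_day)) abort("`fasw`/soil-water series does not cover the crop cycle.")
  doy <- as.integer(format(days$date, "%j"))
  pp <- photoperiod_factor(pmin(pmax(day_length(latitude, doy), 1e-6), 24), cultivar)
  tt <- daily_thermal_time(days$tmin, days$tmax, cultivar)

  n <- nrow(days)
  stage <- integer(n)
  ttm_rec <- numeric(n)
  cum_rec <- numeric(n)
  entry <- rep(as.Date(NA), 8)
  entry[1] <- sowing_date
  entry[2] <- sowing_date # germination treated as immediate at sowing
  cur <- 2L
  cum <- 0
  for (d in seq_len(n)) {
    stage[d] <- cur
    if (cur >= 3L) {
      inc <- modify_thermal_time(tt[d], min(max(fasw_day[d], 0), 1), cur, cultivar) * pp[d]
    } else {
      inc <- tt[d]
    }
    ttm_rec[d] <- inc
    cum <- cum + inc
    cum_rec[d] <- cum
    target <- switch(cur,
                     NA, # 1: not used, sowing handled above
                     cultivar$tt_sowing_to_emergence,
                     cultivar$tt_emergence_to_end_juvenile,
                     cultivar$tt_end_juvenile_to_flowering,
                     cultivar$tt_flowering_to_end_flowering,
                     cultivar$tt_flowering_to_end_podfill,
                     NA, NA)
    if (!is.na(target) && cum >= target) {
      cur <- cur + 1L
      entry[cur] <- days$date[d]
      # flowering, end-flowering and pod fill share one accumulator
      if (cur != 6L) cum <- 0
      if (cur == 7L) {
        entry[8] <- days$date[d]
        stage <- stage[seq_len(d)]
        ttm_rec <- ttm_rec[seq_len(d)]
        cum_rec <- cum_rec[seq_len(d)]
        days <- days[seq_len(d), , drop = FALSE]
        tt <- tt[seq_len(d)]
        fasw_day <- fasw_day[seq_len(d)]
        break
      }
    }
  }
  complete <- !is.na(entry[7])
  peak <- if (!is.na(entry[5]) && !is.na(entry[6])) {
    entry[5] + floor(as.numeric(entry[6] - entry[5]) / 2)
  } else as.Date(NA)

  structure(list(
    trace = tibble(date = days$date, stage = stage, tt_day = tt,
                   ttm_day = ttm_rec, fasw = fasw_day, cum_ttm = cum_rec),
    sowing_date = sowing_date,
    emergence = entry[3],
    end_juvenile = entry[4],
    flowering_start = entry[5],
    flowering_end = entry[6],
    peak_flowering = peak,
    podfill_end = entry[7],
    complete = complete,
    cultivar = cultivar$name
  ), class = "pheno_trace")
}

#' @export
print.pheno_trace <- function(x, ...) {
  cat(sprintf("<pheno_trace> %s, sown %s%s\n", x$cultivar,
              format(x$sowing_date), if (x$complete) "" else " [incomplete]"))
  cat(sprintf("  emergence %s | flowering %s - %s (peak %s) | pod fill ends %s\n",
              format(x$emergence), format(x$flowering_start),
              format(x$flowering_end), format(x$peak_flowering),
              format(x$podfill_end)))
  invisible(x)
}

#' @rdname run_phenology
#' @param x A `pheno_trace`.
#' @param ... Unused.
#' @export
tidy.pheno_trace <- function(x, ...) x$trace

#' @rdname run_phenology
#' @export
glance.pheno_trace <- function(x, ...) {
  tibble(
    sowing_date = x$sowing_date, emergence = x$emergence,
    end_juvenile = x$end_juvenile, flowering_start = x$flowering_start,
    flowering_end = x$flowering_end, peak_flowering = x$peak_flowering,
    podfill_end = x$podfill_end, complete = x$complete
  )
}
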