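#' Read and write the daily weather CSV dialect
#'
#' The on-disk dialect has a header row and columns `date` (ISO-8601),
#' `tmin`, `tmax`, `rain`, `radn`. Reading validates that dates parse, are
#' contiguous (every calendar day present) and that `tmin <= tmax` on every
#' row; a write followed by a read reproduces the series.
#'
#' @param path File path.
#' @return `read_weather_csv()` returns the weather tibble;
#'   `write_weather_csv()` invisibly returns `path`.
#' @export
read_weather_csv <- function(path) {
  w <- readr::read_csv(path, col_types = readr::cols(
    date = readr::col_date(), tmin = readr::col_double(),
    tmax = readr::col_double(), rain = readr::col_double(),
    radn = readr::col_double()
  ), progress = FALSE)
  if (anyNA(w$date)) abort(sprintf("unparseable date(s) in %s.", path))
  check_weather(w)
  w
}

#' @rdname read_weather_csv
#' @param weather Weather tibble to write.
#' @export
write_weather_csv <- function(weather, path) {
  check_weather(weather)
  readr::write_csv(weather, path, progress = FALSE)
  invisible(path)
}

# Sowing window for one calendar year from "mm-dd" bounds.
window_dates <- function(year, window) {
  as.Date(c(sprintf("%d-%s", year, window[1]), sprintf("%d-%s", year, window[2])))
}

#' Simulate the per-year season records for one site x cultivar x window
#'
#' For each year: find the sowing date inside the window (rainfall/soil-water
#' rule, forced to the window's last day otherwise), run the phenology engine,
#' and summarise the reproductive period (flowering start to end of pod fill):
#' its daily minimum temperatures, total rainfall and frost-event count.
#' Years whose crop fails to complete pod fill before the weather ends are
#' kept with missing phenology fields (and are excluded from threshold
#' detection downstream).
#'
#' @param weather Weather tibble covering all years.
#' @param soilwater Soil-water series from [simulate_soil_water()].
#' @param soil The matching [soil_profile()].
#' @param cultivar A [cultivar_config()].
#' @param window Sowing window as c("mm-dd", "mm-dd").
#' @param years Integer years to simulate (default: every full year in the
#'   weather series).
#' @param latitude Site latitude, degrees.
#' @return A tibble with one row per year: sowing/phenology dates, `forced`
#'   and `complete` flags, `rp_days`, `r` (RP rainfall, mm), `frost_events`,
#'   plus list-columns `rp_tmin` and `frost_doys`.
#' @export
simulate_seasons <- function(weather, soilwater, soil, cultivar,
                             window = c("05-01", "05-21"), years = NULL,
                             latitude = -35) {
  check_weather(weather)
  if (is.null(years)) {
    years <- sort(unique(as.integer(format(weather$date, "%Y"))))
  }
  summ <- soil_water_summary(soilwater, soil)
  fasw <- summ[, c("date", "fasw")]
  rain7 <- as.numeric(stats::filter(weather$rain, rep(1, 7), sides = 1))
  rain7[is.na(rain7)] <- cumsum(weather$rain)[is.na(rain7)]
  one_year <- function(y) {
    win <- window_dates(y, window)
    if (win[1] < min(weather$date) || win[2] > max(weather$date)) {
      abort(sprintf("sowing window for %d lies outside the weather span.", y))
    }
    idx <- which(weather$date >= win[1] & weather$date <= win[2])
    ok_day <- rain7[idx] >= 25 & summ$paw[idx] > 80
    sow <- if (any(ok_day)) {
      tibble(sowing_date = weather$date[idx[which(ok_day)[1]]], forced = FALSE)
    } else {
      tibble(sowing_date = win[2], forced = TRUE)
    }
    ph <- run_phenology(weather, soilwater, soil, cultivar,
                        sow$sowing_date, latitude = latitude, fasw = fasw)
    base <- tibble(
      year = y, sowing_date = sow$sowing_date, forced = sow$forced,
      flowering_start = ph$flowering_start, flowering_end = ph$flowering_end,
      peak_flowering = ph$peak_flowering, podfill_end = ph$podfill_end,
      complete = ph$complete
    )
    if (!ph$complete) {
      return(dplyr::mutate(base, rp_days = NA_integer_, r = NA_real_,
                           frost_events = NA_integer_,
                           rp_tmin = list(NULL), frost_doys = list(NULL)))
    }
    rp <- weather[weather$date >= ph$flowering_start &
                    weather$date <= ph$podfill_end, , drop = FALSE]
    frost <- count_frost_events(weather, c(ph$flowering_start, ph$podfill_end))
    dplyr::mutate(base, rp_days = nrow(rp), r = sum(rp$rain),
                  frost_events = frost$events,
                  rp_tmin = list(rp$tmin),
                  frost_doys = list(as.integer(format(frost$event_dates[[1]], "%j"))))
  }
  dplyr::bind_rows(lapply(years, one_year))
}

#' Run the full synthetic study for one site
#'
#' End-to-end pipeline on generated data: weather, bucket soil water (with
#' the 1 November reset), sowing rule, phenology, reproductive-period frost
#' counting, synthetic potential yields with the implanted cold effect, the
#' frost penalty, and threshold detection on the resulting frost-affected
#' yields.
#'
#' @param spec A [synthetic_spec()].
#' @param soil A [soil_profile()] (default: the packaged four-layer loam,
#'   [default_soil()]).
#' @param cultivar A [cultivar_config()] (default [cultivar_hattrick()]).
#' @param window Sowing window as c("mm-dd", "mm-dd") (default mid, 1-21 May).
#' @param loss_per_event,penalty_mode Frost penalty parameters (see
#'   [apply_frost_penalty()]); `loss_per_event = 0` disables the penalty.
#' @param grid_lo,grid_hi,step Threshold grid (see [scan_thresholds()]).
#' @return A list of class `site_study`: `records` (season records with
#'   `potential_yield` and `yf`), `threshold` (a `tc_result`), `scan`
#'   (the `tc_scan`), and `overlap` (frost/peak-flowering overlap report).
#' @export
simulate_study <- function(spec, soil = default_soil(),
                           cultivar = cultivar_hattrick(),
                           window = c("05-01", "05-21"),
                           loss_per_event = 0.05,
                           penalty_mode = "multiplicative",
                           grid_lo = 0, grid_hi = 19, step = 0.1) {
  weather <- generate_weather(spec)
  soilwater <- simulate_soil_water(weather, soil)
  seasons <- simulate_seasons(weather, soilwater, soil, cultivar,
                              window = window, years = spec$years,
                              latitude = spec$latitude)
  ok <- seasons[seasons$complete, , drop = FALSE]
  ok$p_cold <- vapply(ok$rp_tmin, function(v) percent_cold_days(v, spec$implanted_tc),
                      numeric(1))
  ok <- generate_yields(ok, spec)
  ok$yf <- apply_frost_penalty(ok$potential_yield, ok$frost_events,
                               loss_per_event = loss_per_event,
                               mode = penalty_mode)
  res <- detect_threshold(ok, grid_lo = grid_lo, grid_hi = grid_hi, step = step)
  overlap <- flowering_frost_overlap(
    as.integer(format(ok$peak_flowering, "%j")),
    unlist(ok$frost_doys)
  )
  structure(list(records = ok, threshold = res,
                 scan = attr(res, "scan"), overlap = overlap,
                 spec = spec, cultivar = cultivar$name, window = window),
            class = "site_study")
}

#' @export
print.site_study <- function(x, ...) {
  cat(sprintf("<site_study> %s, window %s..%s, %d seasons\n",
              x$cultivar, x$window[1], x$window[2], nrow(x$records)))
  print(x$threshold)
  invisible(x)
}

#' Packaged default soil profile
#'
#' A four-layer, 900 mm deep loam-over-clay profile with a plant available
#' water holding capacity of 150 mm, typical of chickpea soils in the
#' medium-rainfall Australian grain belt. Synthetic values, not a measured
#' profile.
#'
#' @return A [soil_profile()].
#' @export
default_soil <- function() {
  soil_profile(
    thickness = c(150, 150, 300, 300),
    ll15 = c(20, 20, 45, 45),
    dul  = c(45, 45, 95, 95),
    sat  = c(55, 55, 115, 115)
  )
}

#' Default sowing windows
#'
#' Named early / mid / late sowing windows (10-30 April, 1-21 May,
#' 22 May - 11 June) as "mm-dd" pairs.
#'
#' @return A named list of length-2 character vectors.
#' @export
default_sowing_windows <- function() {
  list(early = c("04-10", "04-30"),
       mid   = c("05-01", "05-21"),
       late  = c("05-22", "06-11"))
}

#' Build a multi-site scenario configuration
#'
#' @param locations A list of location entries; each is a list with `name`,
#'   `latitude`, `longitude`, a `weather` [synthetic_spec()] and a `soil`
#'   [soil_profile()].
#' @param cultivars Named list of [cultivar_config()]s.
#' @param sowing_windows Named list of c("mm-dd", "mm-dd") windows.
#' @param years Integer years simulated at every location.
#' @param loss_per_event,penalty_mode Frost penalty settings.
#' @param grid_lo,grid_hi,step Threshold-scan grid.
#' @param seed Master seed; per-location weather seeds are derived from it
#'   and the location name, so adding a location never changes another
#'   location's rows.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(locations, cultivars = list(hattrick = cultivar_hattrick()),
                            sowing_windows = default_sowing_windows(),
                            years = 1950:2019,
                            loss_per_event = 0.05,
                            penalty_mode = "multiplicative",
                            grid_lo = 0, grid_hi = 19, step = 0.1,
                            seed = 1L) {
  for (loc in locations) {
    if (is.null(loc$name) || is.null(loc$weather) || is.null(loc$soil)) {
      abort("each location needs `name`, `weather` (synthetic_spec) and `soil` (soil_profile).")
    }
    if (!inherits(loc$weather, "synthetic_spec")) abort("location weather must be a synthetic_spec.")
    if (!inherits(loc$soil, "soil_profile")) abort("location soil must be a soil_profile.")
  }
  if (is.null(names(cultivars)) || any(names(cultivars) == "")) {
    abort("`cultivars` must be a named list.")
  }
  structure(list(locations = locations, cultivars = cultivars,
                 sowing_windows = sowing_windows, years = years,
                 loss_per_event = loss_per_event, penalty_mode = penalty_mode,
                 grid_lo = grid_lo, grid_hi = grid_hi, step = step,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

#' Read a scenario configuration from a YAML file
#'
#' The file mirrors the arguments of [scenario_config()]: top-level `seed`,
#' `years` (two-element inclusive range), `sowing_windows`, `frost`
#' (`loss_per_event`, `mode`), `grid` (`lo`, `hi`, `step`), `cultivars`
#' (named; each either `"hattrick"` or a mapping of [cultivar_config()]
#' arguments) and `locations` (each with `name`, `latitude`, `longitude`,
#' `weather` mapping of [synthetic_spec()] arguments and `soil` mapping with
#' `thickness`/`ll15`/`dul`/`sat` lists). See
#' `system.file("extdata", "example_config.yaml", package = "chickcold")`.
#'
#' @param path YAML file path.
#' @return A `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  years <- seq.int(cfg$years[[1]], cfg$years[[2]])
  seed <- cfg$seed %||% 1L
  cultivars <- lapply(cfg$cultivars, function(cv) {
    if (identical(cv, "hattrick")) cultivar_hattrick()
    else do.call(cultivar_config, cv)
  })
  locations <- lapply(cfg$locations, function(loc) {
    wargs <- loc$weather %||% list()
    wargs$latitude <- loc$latitude
    wargs$longitude <- loc$longitude
    wargs$years <- years
    wargs$seed <- wargs$seed %||% substream_seed(seed, sum(utf8ToInt(loc$name)))
    list(name = loc$name, latitude = loc$latitude, longitude = loc$longitude,
         weather = do.call(synthetic_spec, wargs),
         soil = do.call(soil_profile, loc$soil))
  })
  windows <- lapply(cfg$sowing_windows %||% default_sowing_windows(),
                    function(w) c(w[[1]], w[[2]]))
  scenario_config(
    locations = locations, cultivars = cultivars, sowing_windows = windows,
    years = years,
    loss_per_event = cfg$frost$loss_per_event %||% 0.05,
    penalty_mode = cfg$frost$mode %||% "multiplicative",
    grid_lo = cfg$grid$lo %||% 0, grid_hi = cfg$grid$hi %||% 19,
    step = cfg$grid$step %||% 0.1,
    seed = seed
  )
}

#' Run every scenario combination end to end
#'
#' For each location x cultivar x sowing window: generate (or reuse) the
#' location's weather and soil water, choose sowing dates, run phenology,
#' count reproductive-period frosts, build synthetic yields, apply the frost
#' penalty, and detect the cold-temperature threshold. Detected thresholds
#' across locations are then regressed on latitude and longitude (when at
#' least three sites detect). Fully deterministic for a fixed configuration:
#' each location's weather seed is derived from the master seed and the
#' location name. Per-combination failures are logged and skipped, not fatal.
#'
#' @param config A [scenario_config()].
#' @param quiet Suppress the one-line-per-combination log.
#' @return A list of class `scenario_run`: `results` (one row per location x
#'   cultivar x window x year), `thresholds` (one summary row per
#'   combination, with detection, effect size and frost overlap), and
#'   `spatial` (a `geo_regression`, or `NULL` if fewer than 3 sites detect).
#' @export
run_scenarios <- function(config, quiet = FALSE) {
  if (!inherits(config, "scenario_config")) abort("`config` must be a scenario_config.")
  say <- function(...) if (!quiet) message(sprintf(...))
  results <- list()
  thresholds <- list()
  for (loc in config$locations) {
    spec <- loc$weather
    for (cv_name in names(config$cultivars)) {
      cv <- config$cultivars[[cv_name]]
      for (w_name in names(config$sowing_windows)) {
        win <- config$sowing_windows[[w_name]]
        study <- tryCatch(
          simulate_study(spec, soil = loc$soil, cultivar = cv, window = win,
                         loss_per_event = config$loss_per_event,
                         penalty_mode = config$penalty_mode,
                         grid_lo = config$grid_lo, grid_hi = config$grid_hi,
                         step = config$step),
          error = function(e) e
        )
        if (inherits(study, "error")) {
          say("[%s x %s x %s] skipped: %s", loc$name, cv_name, w_name,
              conditionMessage(study))
          next
        }
        rec <- dplyr::mutate(
          dplyr::select(study$records, -"rp_tmin", -"frost_doys"),
          location = loc$name, cultivar = cv_name, window = w_name,
          .before = 1
        )
        results[[length(results) + 1]] <- rec
        th <- study$threshold
        thresholds[[length(thresholds) + 1]] <- tibble(
          location = loc$name, latitude = loc$latitude,
          longitude = loc$longitude, cultivar = cv_name, window = w_name,
          detected = th$detected, tc = th$tc, beta0 = th$beta0,
          beta1 = th$beta1, beta2 = th$beta2, p_beta1 = th$p_beta1,
          q1 = th$q1, q3 = th$q3, n_years = nrow(study$records),
          overlap_coefficient = study$overlap$overlap_coefficient,
          no_frost = study$overlap$no_frost
        )
        say("[%s x %s x %s] seed %d: %d seasons, detected = %s",
            loc$name, cv_name, w_name, spec$seed, nrow(study$records),
            th$detected)
      }
    }
  }
  thresholds <- dplyr::bind_rows(thresholds)
  detected_sites <- dplyr::filter(thresholds, .data$detected)
  # one tc per location (best p) for the geography regression
  spatial <- NULL
  if (nrow(detected_sites) > 0) {
    per_site <- dplyr::slice_min(dplyr::group_by(detected_sites, .data$location),
                                 .data$p_beta1, n = 1, with_ties = FALSE)
    per_site <- dplyr::ungroup(per_site)
    if (nrow(per_site) >= 3) {
      spatial <- tryCatch(spatial_threshold_regression(per_site),
                          error = function(e) NULL)
    }
  }
  structure(list(results = dplyr::bind_rows(results), thresholds = thresholds,
                 spatial = spatial, config = config),
            class = "scenario_run")
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("<scenario_run> %d season rows, %d combinations (%d detected)\n",
              nrow(x$results), nrow(x$thresholds), sum(x$thresholds$detected)))
  if (!is.null(x$spatial)) print(x$spatial)
  invisible(x)
}

#' Write scenario results to CSV
#'
#' Writes `results.csv` (per-year rows) and `thresholds.csv` (per-combination
#' detection summaries) into `dir`. Output is byte-identical across reruns of
#' the same configuration and seed.
#'
#' @param run A [run_scenarios()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(run, dir) {
  if (!inherits(run, "scenario_run")) abort("`run` must be a scenario_run.")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("results.csv", "thresholds.csv"))
  readr::write_csv(run$results, paths[1], progress = FALSE)
  readr::write_csv(run$thresholds, paths[2], progress = FALSE)
  invisible(paths)
}
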