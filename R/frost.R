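#' Count frost events in an assessment window
#'
#' A frost event is a day whose screen (1.5 m) minimum temperature is at or
#' below `threshold` (default 0 C). Days are counted inside the closed window;
#' each qualifying day is one event.
#'
#' @param weather Weather tibble.
#' @param window Length-2 Date vector (start, end), within the weather span.
#' @param threshold Frost threshold, C.
#' @return A one-row tibble: `events`, `window_start`, `window_end`, plus the
#'   qualifying dates in a list-column `event_dates`.
#' @export
#' @examples
#' w <- tibble::tibble(
#'   date = as.Date("2001-06-01") + 0:4,
#'   tmin = c(1, -2, 0, 3, -1), tmax = 15, rain = 0
#' )
#' count_frost_events(w, range(w$date))$events  # 3
count_frost_events <- function(weather, window, threshold = 0) {
  check_weather(weather)
  if (length(window) != 2 || !inherits(as.Date(window), "Date")) {
    abort("`window` must be two Dates (start, end).")
  }
  window <- as.Date(window)
  if (window[1] > window[2]) abort("frost window is empty (start after end).")
  if (window[1] < min(weather$date) || window[2] > max(weather$date)) {
    abort("frost window lies outside the weather span.")
  }
  inside <- weather$date >= window[1] & weather$date <= window[2]
  hits <- weather$date[inside & weather$tmin <= threshold]
  tibble(events = length(hits), window_start = window[1],
         window_end = window[2], event_dates = list(hits))
}

#' Apply the per-event frost yield penalty
#'
#' Each post-flowering frost event costs about `loss_per_event` (default 5%)
#' of yield. Two compounding conventions are offered:
#' multiplicative (default), `YF = Y (1 - loss)^events`, which is bounded and
#' never negative; and additive, `YF = Y max(0, 1 - loss * events)`. The two
#' agree for a single event.
#'
#' @param potential_yield Yield before frost damage, kg/ha (vectorised,
#'   non-negative).
#' @param events Frost-event count (vectorised, non-negative integers).
#' @param loss_per_event Fractional loss per event, in \[0, 1\].
#' @param mode `"multiplicative"` or `"additive"`.
#' @return Frost-affected yield, kg/ha, in \[0, potential_yield\].
#' @export
#' @examples
#' apply_frost_penalty(1000, 1)                       # 950
#' apply_frost_penalty(1000, 30)                      # ~214.6
#' apply_frost_penalty(1000, 30, mode = "additive")   # 0
apply_frost_penalty <- function(potential_yield, events, loss_per_event = 0.05,
                                mode = c("multiplicative", "additive")) {
  mode <- match.arg(mode)
  if (any(potential_yield < 0)) abort("`potential_yield` must be non-negative.")
  if (any(events < 0)) abort("`events` must be non-negative.")
  check_number(loss_per_event, "loss_per_event", 0, 1)
  switch(mode,
         multiplicative = potential_yield * (1 - loss_per_event)^events,
         additive = potential_yield * pmax(0, 1 - loss_per_event * events))
}

#' Overlap between frost timing and peak flowering
#'
#' Quantifies frost risk as the overlap coefficient between the day-of-year
#' distributions of frost events and peak flowering across years: Gaussian
#' kernel density estimates (Silverman's rule) of both samples are evaluated
#' on a common day 1-366 grid and the coefficient is
#' \eqn{\sum \min(\hat f_{frost}, \hat f_{peak}) \Delta}. It is 1 when the
#' distributions coincide and 0 when they are disjoint (or when no frost was
#' observed at all, flagged by `no_frost`). Wrap-around at the year boundary
#' is ignored (mid-year events in the southern hemisphere).
#'
#' @param peak_flowering_doys Day-of-year of peak flowering, one per year
#'   (non-empty, values in \[1, 366\]).
#' @param frost_doys Day-of-year of frost events across years (may be empty).
#' @return One-row tibble: `overlap_coefficient`, `n_frost_days`, `n_years`,
#'   `no_frost`.
#' @export
flowering_frost_overlap <- function(peak_flowering_doys, frost_doys) {
  if (length(peak_flowering_doys) == 0) abort("`peak_flowering_doys` must be non-empty.")
  peak_flowering_doys <- peak_flowering_doys[!is.na(peak_flowering_doys)]
  frost_doys <- frost_doys[!is.na(frost_doys)]
  if (any(c(peak_flowering_doys, frost_doys) < 1) ||
      any(c(peak_flowering_doys, frost_doys) > 366)) {
    abort("day-of-year values must lie in [1, 366].")
  }
  n_years <- length(peak_flowering_doys)
  if (length(frost_doys) == 0) {
    return(tibble(overlap_coefficient = 0, n_frost_days = 0L,
                  n_years = n_years, no_frost = TRUE))
  }
  kde_grid <- function(x) {
    bw <- if (length(x) >= 2 && sd(x) > 0) stats::bw.nrd0(x) else 1
    density(x, bw = bw, from = 1, to = 366, n = 366)$y
  }
  f <- kde_grid(frost_doys)
  g <- kde_grid(peak_flowering_doys)
  step <- (366 - 1) / 365
  oc <- sum(pmin(f, g)) * step
  tibble(overlap_coefficient = min(oc, 1), n_frost_days = length(frost_doys),
         n_years = n_years, no_frost = FALSE)
}
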