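#' Define a layered soil profile
#'
#' A profile is an ordered set of layers, each with a depth `thickness` (mm)
#' and three water-holding constants in mm of stored water: `ll15` (water held
#' at 1.5 MPa suction, the crop lower limit), `dul` (drained upper limit,
#' field capacity) and `sat` (saturation). Plant available water holding
#' capacity is `pawc = sum(dul - ll15)`.
#'
#' @param thickness Layer depths, mm (top layer first).
#' @param ll15,dul,sat Per-layer water contents, mm; must satisfy
#'   `0 <= ll15 < dul <= sat`.
#' @return A tibble of class `soil_profile` with one row per layer and an
#'   attached `pawc` attribute.
#' @export
#' @examples
#' soil <- soil_profile(
#'   thickness = c(150, 150, 300, 300),
#'   ll15 = c(20, 20, 45, 45),
#'   dul  = c(45, 45, 95, 95),
#'   sat  = c(55, 55, 115, 115)
#' )
#' attr(soil, "pawc")
soil_profile <- function(thickness, ll15, dul, sat) {
  n <- length(thickness)
  if (n == 0) abort("soil profile must have at least one layer.")
  if (length(ll15) != n || length(dul) != n || length(sat) != n) {
    abort("thickness, ll15, dul and sat must have one value per layer.")
  }
  if (any(thickness <= 0)) abort("`thickness` must be positive in every layer.")
  if (any(ll15 < 0)) abort("`ll15` must be non-negative.")
  if (any(ll15 >= dul)) abort("each layer needs `ll15` < `dul`.")
  if (any(dul > sat)) abort("each layer needs `dul` <= `sat`.")
  out <- tibble(layer = seq_len(n), thickness = as.numeric(thickness),
                ll15 = as.numeric(ll15), dul = as.numeric(dul),
                sat = as.numeric(sat))
  attr(out, "pawc") <- sum(out$dul - out$ll15)
  class(out) <- c("soil_profile", class(out))
  out
}

#' Daily bucket soil-water balance
#'
#' A deliberately simple cascading-bucket stand-in for a full soil water
#' model: its only contract is a plausible daily fractional-available-soil-water
#' trajectory. Each day (in order): the stored state is the start-of-day water;
#' rain is added to the top layer; water above saturation overflows immediately
#' to the layer below; a fraction `drainage_frac` of any water above the
#' drained upper limit cascades downward (out of the profile from the bottom
#' layer); evapotranspiration demand `et_coef * max(0, tmean - et_base)` is
#' extracted top-down from the layers starting within `et_depth` mm of the
#' surface (evaporation does not mine deep moisture), never taking a layer
#' below `ll15`. On every 1 November
#' (start of day) the profile is reset so fractional available soil water
#' equals `reset_fasw`, mimicking the low water left after a winter fallow.
#'
#' @param weather Weather tibble (see [generate_weather()]); dates must be
#'   contiguous.
#' @param soil A [soil_profile()].
#' @param drainage_frac Fraction of above-DUL water moved down per day, in
#'   \[0, 1\].
#' @param et_coef Evapotranspiration demand per degree of daily mean
#'   temperature above `et_base`, mm/day/C.
#' @param et_base Base temperature for the ET demand, C.
#' @param et_depth Depth (mm) within which a layer must start to be subject
#'   to ET extraction.
#' @param init Initial per-layer water: `"dul"`, `"ll15"`, `"half"`, or a
#'   numeric vector of mm per layer.
#' @param reset_fasw Fractional available soil water imposed on 1 November,
#'   or `NULL` to disable the reset.
#' @return A long tibble with columns `date`, `layer`, `sw` (start-of-day
#'   soil water, mm); one row per day per layer.
#' @export
simulate_soil_water <- function(weather, soil, drainage_frac = 0.5,
                                et_coef = 0.08, et_base = 0, et_depth = 600,
                                init = "dul", reset_fasw = 0.5) {
  check_weather(weather)
  if (!inherits(soil, "soil_profile")) abort("`soil` must be a soil_profile.")
  check_number(drainage_frac, "drainage_frac", 0, 1)
  check_number(et_coef, "et_coef", lower = 0)
  n <- nrow(soil)
  sw <- if (is.numeric(init)) {
    if (length(init) != n) abort("numeric `init` needs one value per layer.")
    pmin(pmax(as.numeric(init), soil$ll15), soil$sat)
  } else {
    switch(match.arg(init, c("dul", "ll15", "half")),
           dul = soil$dul, ll15 = soil$ll15,
           half = soil$ll15 + 0.5 * (soil$dul - soil$ll15))
  }
  nd <- nrow(weather)
  layer_top <- cumsum(soil$thickness) - soil$thickness
  is_reset <- !is.null(reset_fasw) & format(weather$date, "%m-%d") == "11-01"
  tmean <- (weather$tmin + weather$tmax) / 2
  rain <- weather$rain
  out <- matrix(0, nrow = nd, ncol = n)
  for (d in seq_len(nd)) {
    if (is_reset[d]) {
      sw <- soil$ll15 + reset_fasw * (soil$dul - soil$ll15)
    }
    out[d, ] <- sw # start-of-day state
    # infiltration + saturation overflow + drainage cascade
    inflow <- rain[d]
    for (l in seq_len(n)) {
      sw[l] <- sw[l] + inflow
      over_sat <- max(0, sw[l] - soil$sat[l])
      drain <- drainage_frac * max(0, sw[l] - over_sat - soil$dul[l])
      sw[l] <- sw[l] - over_sat - drain
      inflow <- over_sat + drain
    }
    # top-down evapotranspiration extraction, floored at ll15
    demand <- et_coef * max(0, tmean[d] - et_base)
    for (l in which(layer_top < et_depth)) {
      if (demand <= 0) break
      take <- min(demand, sw[l] - soil$ll15[l])
      if (take > 0) {
        sw[l] <- sw[l] - take
        demand <- demand - take
      }
    }
  }
  tibble(
    date = rep(weather$date, each = n),
    layer = rep.int(seq_len(n), nd),
    sw = as.vector(t(out))
  )
}

# Per-layer weights for the top `depth_limit` mm of the profile, pro-rating
# the straddling layer. Warns (once per call) if the profile is shallower.
layer_depth_weights <- function(soil, depth_limit = 600) {
  depth_bottom <- cumsum(soil$thickness)
  depth_top <- depth_bottom - soil$thickness
  if (depth_limit > depth_bottom[length(depth_bottom)]) {
    warn(sprintf(
      "depth limit %g mm exceeds profile depth %g mm; using the whole profile.",
      depth_limit, depth_bottom[length(depth_bottom)]))
    return(rep(1, nrow(soil)))
  }
  pmin(pmax((depth_limit - depth_top) / soil$thickness, 0), 1)
}

#' Fractional available soil water over the top of the profile
#'
#' FASW is the plant-available water in the surface layers as a fraction of
#' their capacity:
#' \deqn{\mathrm{FASW} = \sum (sw - ll15) / \sum (dul - ll15)}
#' summed over the layers in the top `depth_limit` mm (default 600 mm, i.e.
#' the 60 cm soil surface), pro-rated for a layer straddling the limit, and
#' clipped to \[0, 1\]. It equals 1 at field capacity and 0 at the crop lower
#' limit.
#'
#' @param sw Per-layer soil water, mm (one value per profile layer).
#' @param soil A [soil_profile()].
#' @param depth_limit Depth over which FASW is evaluated, mm.
#' @return A single fraction in \[0, 1\].
#' @export
#' @examples
#' soil <- soil_profile(c(300, 300), ll15 = c(30, 40), dul = c(80, 90),
#'                      sat = c(95, 105))
#' compute_fasw(c(60, 50), soil)
compute_fasw <- function(sw, soil, depth_limit = 600) {
  if (!inherits(soil, "soil_profile")) abort("`soil` must be a soil_profile.")
  if (length(sw) != nrow(soil)) abort("`sw` needs one value per soil layer.")
  w <- layer_depth_weights(soil, depth_limit)
  avail <- sum(w * (sw - soil$ll15))
  cap <- sum(w * (soil$dul - soil$ll15))
  min(max(avail / cap, 0), 1)
}

#' Daily FASW and whole-profile plant-available water from a soil-water series
#'
#' Convenience summary of a [simulate_soil_water()] result: one row per day
#' with the top-600 mm FASW (clipped to \[0, 1\]) and the whole-profile
#' plant-available water `paw = sum(sw - ll15)` in mm.
#'
#' @param soilwater Long tibble from [simulate_soil_water()].
#' @param soil The matching [soil_profile()].
#' @param depth_limit Depth for the FASW numerator/denominator, mm.
#' @return A tibble with columns `date`, `fasw`, `paw`.
#' @export
soil_water_summary <- function(soilwater, soil, depth_limit = 600) {
  if (!inherits(soil, "soil_profile")) abort("`soil` must be a soil_profile.")
  w <- layer_depth_weights(soil, depth_limit)
  cap <- sum(w * (soil$dul - soil$ll15))
  m <- matrix(soilwater$sw, ncol = nrow(soil), byrow = TRUE)
  dates <- soilwater$date[seq(1, nrow(soilwater), by = nrow(soil))]
  avail_top <- as.vector(m %*% w) - sum(w * soil$ll15)
  paw <- rowSums(m) - sum(soil$ll15)
  tibble(date = dates, fasw = pmin(pmax(avail_top / cap, 0), 1), paw = paw)
}
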