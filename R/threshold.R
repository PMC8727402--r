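#' Percentage of cold days during the reproductive period
#'
#' The cold-day percentage at a candidate threshold is
#' \deqn{P(T_C) = 100 \times \#\{ \mathrm{days: } T_{min} \le T_C \} / \#\mathrm{days},}
#' evaluated over the reproductive-period daily minima. It is a non-decreasing
#' step function of the threshold, reaching 100 at or above the warmest
#' minimum.
#'
#' @param rp_tmin Daily minimum temperatures within the reproductive period,
#'   C (non-empty).
#' @param tc Candidate threshold(s), C (vectorised).
#' @return Percentage(s) in \[0, 100\].
#' @export
#' @examples
#' percent_cold_days(c(3, 5, 7, 9), 6)  # 50
percent_cold_days <- function(rp_tmin, tc) {
  if (length(rp_tmin) == 0) abort("`rp_tmin` must be non-empty (empty reproductive period).")
  vapply(tc, function(t) 100 * sum(rp_tmin <= t) / length(rp_tmin), numeric(1))
}

# Core OLS of yf on (P, R) with intercept, via QR; returns coefficients and
# the two-sided t-test p-value for the P coefficient (df = n - 3). `fittable`
# is FALSE when the design is rank deficient (e.g. P constant across years).
ols_py <- function(yf, p, r) {
  n <- length(yf)
  X <- cbind(`(Intercept)` = 1, P = p, R = r)
  qx <- qr(X)
  if (qx$rank < 3L || n < 4L) {
    return(list(fittable = FALSE, beta0 = NA_real_, beta1 = NA_real_,
                beta2 = NA_real_, p_beta1 = NA_real_, sigma = NA_real_,
                se_beta1 = NA_real_))
  }
  if (sd(yf) == 0) {
    # constant response: no association, residual-noise t-stats are meaningless
    return(list(fittable = TRUE, beta0 = yf[1], beta1 = 0, beta2 = 0,
                p_beta1 = 1, sigma = 0, se_beta1 = 0))
  }
  coefs <- qr.coef(qx, yf)
  res <- yf - X %*% coefs
  df <- n - 3L
  sigma2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  se1 <- sqrt(sigma2 * xtx_inv[2, 2])
  tval <- if (se1 > 0) coefs[2] / se1 else sign(coefs[2]) * Inf
  pval <- if (se1 > 0) 2 * pt(-abs(tval), df) else if (coefs[2] == 0) 1 else 0
  list(fittable = TRUE, beta0 = unname(coefs[1]), beta1 = unname(coefs[2]),
       beta2 = unname(coefs[3]), p_beta1 = unname(pval), sigma = sqrt(sigma2),
       se_beta1 = unname(se1))
}

check_records <- function(records) {
  need <- c("year", "yf", "r", "rp_tmin")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("season records are missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!is.list(records$rp_tmin)) abort("`rp_tmin` must be a list-column of daily minima.")
  invisible(records)
}

#' Fit the frost-affected-yield regression at one candidate threshold
#'
#' Ordinary least squares of frost-affected yield on the cold-day percentage
#' at `tc` and reproductive-period rainfall, with intercept:
#' \deqn{YF_t = \beta_0 + \beta_1 P_t(T_C) + \beta_2 R_t + e_t.}
#' The p-value for \eqn{\beta_1} is the two-sided t test with `n - 3` degrees
#' of freedom (residual error variance estimated from the fit). A design made
#' rank deficient by a constant cold-day percentage is reported as unfittable
#' rather than an error, so grid scans can skip it.
#'
#' @param records Season-record tibble with columns `year`, `yf` (kg/ha), `r`
#'   (mm) and list-column `rp_tmin` (daily reproductive-period minima, C);
#'   at least 4 rows.
#' @param tc Candidate threshold, C.
#' @return One-row tibble: `tc`, `fittable`, `beta0`, `beta1`, `beta2`,
#'   `p_beta1`, `sigma`.
#' @export
fit_yield_regression <- function(records, tc) {
  check_records(records)
  if (nrow(records) < 4) abort("need at least 4 season records (df = n - 3 >= 1).")
  p <- vapply(records$rp_tmin, function(v) percent_cold_days(v, tc), numeric(1))
  fit <- ols_py(records$yf, p, records$r)
  tibble(tc = tc, fittable = fit$fittable, beta0 = fit$beta0,
         beta1 = fit$beta1, beta2 = fit$beta2, p_beta1 = fit$p_beta1,
         sigma = fit$sigma)
}

#' Grid search of candidate cold-temperature thresholds
#'
#' Fits the yield regression of [fit_yield_regression()] at every candidate
#' threshold on the grid from `grid_lo` to `grid_hi` in steps of `step`
#' (endpoints included; the defaults give the 191 candidates 0.0, 0.1, ...,
#' 19.0 C), recording \eqn{\beta_1} and its p-value. Candidates whose design
#' is rank deficient (cold-day percentage constant across years) are marked
#' unfittable and carry `NA` estimates.
#'
#' @inheritParams fit_yield_regression
#' @param grid_lo,grid_hi Grid bounds, C.
#' @param step Grid step, C.
#' @return A tibble of class `tc_scan`, one row per candidate, with the
#'   columns of [fit_yield_regression()].
#' @export
scan_thresholds <- function(records, grid_lo = 0, grid_hi = 19, step = 0.1) {
  check_records(records)
  if (nrow(records) < 4) abort("need at least 4 season records (df = n - 3 >= 1).")
  if (grid_lo > grid_hi) abort("`grid_lo` must not exceed `grid_hi`.")
  if (step <= 0) abort("`step` must be positive.")
  grid <- round(grid_lo + step * (0:floor((grid_hi - grid_lo) / step + 1e-9)), 6)
  # P columns for all candidates at once (rows: years, cols: candidates)
  pmat <- vapply(records$rp_tmin,
                 function(v) percent_cold_days(v, grid),
                 numeric(length(grid)))
  pmat <- matrix(pmat, nrow = length(grid))
  fits <- lapply(seq_along(grid), function(i) {
    fit <- ols_py(records$yf, pmat[i, ], records$r)
    tibble(tc = grid[i], fittable = fit$fittable, beta0 = fit$beta0,
           beta1 = fit$beta1, beta2 = fit$beta2, p_beta1 = fit$p_beta1,
           sigma = fit$sigma)
  })
  out <- dplyr::bind_rows(fits)
  class(out) <- c("tc_scan", class(out))
  attr(out, "n_years") <- nrow(records)
  out
}

#' Select the cold-temperature threshold from a grid scan
#'
#' Implements the criteria-based selection: among fittable candidates the one
#' with the lowest \eqn{\beta_1} p-value is retained; if several candidates
#' share that lowest p-value (equal to within a relative tolerance of
#' 1e-12), the largest threshold among them is chosen. Detection then
#' requires (i) the p-value to be below 0.05 and (ii) the selected threshold
#' to lie between the first and third quartiles of the reproductive-period
#' minimum temperatures pooled across years (which keeps the cold-day
#' percentage away from 0 and 100). An empty effective scan (every candidate
#' unfittable) yields `detected = FALSE`, not an error.
#'
#' @param scan A [scan_thresholds()] result.
#' @param pooled_rp_tmin All reproductive-period daily minima pooled across
#'   years, C (for the quartile band; linear-interpolation quantiles).
#' @return An object of class `tc_result` with fields `detected`, `tc`,
#'   `beta0`, `beta1`, `beta2`, `p_beta1`, `q1`, `q3`. [tidy()] gives the
#'   coefficient table, [glance()] a one-row summary.
#' @export
select_threshold <- function(scan, pooled_rp_tmin) {
  if (!inherits(scan, "tc_scan")) abort("`scan` must come from scan_thresholds().")
  if (length(pooled_rp_tmin) == 0) abort("`pooled_rp_tmin` must be non-empty.")
  qs <- unname(quantile(pooled_rp_tmin, c(0.25, 0.75), type = 7))
  eff <- scan[scan$fittable, , drop = FALSE]
  if (nrow(eff) == 0) {
    out <- list(detected = FALSE, tc = NA_real_, beta0 = NA_real_,
                beta1 = NA_real_, beta2 = NA_real_, p_beta1 = NA_real_,
                q1 = qs[1], q3 = qs[2], reason = "no fittable candidate")
    return(structure(out, class = "tc_result"))
  }
  p_min <- min(eff$p_beta1)
  tied <- if (p_min == 0) eff$p_beta1 == 0 else eff$p_beta1 <= p_min * (1 + 1e-12)
  pick <- eff[which(tied), , drop = FALSE]
  pick <- pick[which.max(pick$tc), , drop = FALSE]
  detected <- pick$p_beta1 < 0.05 && pick$tc >= qs[1] && pick$tc <= qs[2]
  reason <- if (detected) NA_character_
  else if (!(pick$p_beta1 < 0.05)) "p >= 0.05"
  else "outside quartile band"
  structure(list(
    detected = detected, tc = pick$tc, beta0 = pick$beta0, beta1 = pick$beta1,
    beta2 = pick$beta2, p_beta1 = pick$p_beta1, q1 = qs[1], q3 = qs[2],
    reason = reason
  ), class = "tc_result")
}

#' Detect the cold-temperature threshold for a set of season records
#'
#' Convenience wrapper chaining [scan_thresholds()] and [select_threshold()]
#' with the quartile band computed from the records' pooled
#' reproductive-period minima.
#'
#' @inheritParams scan_thresholds
#' @return A `tc_result` (see [select_threshold()]) with the scan attached as
#'   attribute `scan`.
#' @export
detect_threshold <- function(records, grid_lo = 0, grid_hi = 19, step = 0.1) {
  scan <- scan_thresholds(records, grid_lo, grid_hi, step)
  res <- select_threshold(scan, unlist(records$rp_tmin))
  attr(res, "scan") <- scan
  res
}

#' Quantify the yield effect at the detected threshold
#'
#' Refits the yield regression at the selected threshold. \eqn{\beta_1} is the
#' change in frost-affected yield (kg/ha) when the cold-day percentage
#' increases by one percentage point with rainfall held fixed; a negative
#' estimate means a yield loss is expected whenever the minimum temperature
#' falls at or below the threshold.
#'
#' @param records Season-record tibble (see [fit_yield_regression()]).
#' @param result A detected `tc_result`.
#' @return One-row tibble: `tc`, `beta0`, `beta1`, `beta2`, `p_beta1`,
#'   `yield_loss_expected`.
#' @export
quantify_effect <- function(records, result) {
  if (!inherits(result, "tc_result")) abort("`result` must be a tc_result.")
  if (!isTRUE(result$detected)) {
    abort("no threshold was detected; cannot quantify an effect.")
  }
  fit <- fit_yield_regression(records, result$tc)
  dplyr::mutate(fit[, c("tc", "beta0", "beta1", "beta2", "p_beta1")],
                yield_loss_expected = .data$beta1 < 0)
}

#' Regress detected thresholds on geography
#'
#' Across sites with a detected threshold, fits the linear model
#' `tc ~ latitude + longitude` by ordinary least squares, describing how the
#' cold-temperature threshold varies spatially.
#'
#' @param sites Data frame with columns `latitude`, `longitude`, `tc`; at
#'   least 3 rows with non-collinear coordinates.
#' @return An object of class `geo_regression` wrapping the [stats::lm()]
#'   fit; `tidy()`/`glance()` apply.
#' @export
spatial_threshold_regression <- function(sites) {
  need <- c("latitude", "longitude", "tc")
  miss <- setdiff(need, names(sites))
  if (length(miss) > 0) abort(paste0("sites is missing column(s): ", paste(miss, collapse = ", ")))
  sites <- sites[!is.na(sites$tc), , drop = FALSE]
  if (nrow(sites) < 3) abort("need at least 3 sites with a detected threshold.")
  fit <- stats::lm(tc ~ latitude + longitude, data = sites)
  if (any(is.na(stats::coef(fit)))) abort("site coordinates are collinear.")
  structure(list(fit = fit, n_sites = nrow(sites)), class = "geo_regression")
}

#' @export
print.tc_result <- function(x, ...) {
  if (x$detected) {
    cat(sprintf("<tc_result> detected T_C = %.1f C (beta1 = %.2f kg/ha per %%, p = %.3g)\n",
                x$tc, x$beta1, x$p_beta1))
  } else {
    cat(sprintf("<tc_result> no detection (%s)\n", x$reason))
  }
  cat(sprintf("  quartile band of pooled RP minima: [%.2f, %.2f] C\n", x$q1, x$q3))
  invisible(x)
}

#' @rdname select_threshold
#' @param x A `tc_result`.
#' @param ... Unused.
#' @export
tidy.tc_result <- function(x, ...) {
  tibble(term = c("(Intercept)", "P", "R"),
         estimate = c(x$beta0, x$beta1, x$beta2),
         p.value = c(NA_real_, x$p_beta1, NA_real_))
}

#' @rdname select_threshold
#' @export
glance.tc_result <- function(x, ...) {
  tibble(detected = x$detected, tc = x$tc, beta1 = x$beta1,
         p_beta1 = x$p_beta1, q1 = x$q1, q3 = x$q3)
}

#' @export
print.geo_regression <- function(x, ...) {
  co <- stats::coef(x$fit)
  cat(sprintf("<geo_regression> T_C = %.3f %+.3f x Latitude %+.3f x Longitude (n = %d sites)\n",
              co[1], co[2], co[3], x$n_sites))
  invisible(x)
}

#' @rdname spatial_threshold_regression
#' @param x A `geo_regression`.
#' @param ... Unused.
#' @export
tidy.geo_regression <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @rdname spatial_threshold_regression
#' @export
glance.geo_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma, n_sites = x$n_sites)
}
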