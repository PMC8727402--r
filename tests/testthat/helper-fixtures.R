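# Small in-code fixtures shared across the suite.

# Constant-weather builder: n days from `start`, fixed tmin/tmax/rain.
make_weather <- function(n, tmin = 5, tmax = 15, rain = 0,
                         start = as.Date("2000-06-01")) {
  tibble::tibble(
    date = start + seq_len(n) - 1,
    tmin = rep_len(tmin, n), tmax = rep_len(tmax, n),
    rain = rep_len(rain, n), radn = 15
  )
}

# Single-layer 600 mm bucket used in hand-arithmetic soil tests.
one_layer_soil <- function(ll15 = 60, dul = 160, sat = 200) {
  soil_profile(thickness = 600, ll15 = ll15, dul = dul, sat = sat)
}

# Cultivar with photoperiod disabled and round targets for hand accumulation.
plain_cultivar <- function(...) {
  cultivar_config(
    name = "test",
    tt_sowing_to_emergence = 100,
    tt_emergence_to_end_juvenile = 690,
    tt_end_juvenile_to_flowering = 200,
    tt_flowering_to_end_flowering = 130,
    tt_flowering_to_end_podfill = 260,
    photoperiod_sensitivity = 0,
    ...
  )
}

# Season records with fully controlled covariates: rp_tmin lists, rainfall r
# and yields built as beta0 + b_p * P(tc_true) + b_r * r (+ noise).
make_records <- function(n_years = 10, tc_true = 10, beta0 = 1000,
                         b_p = -10, b_r = 2, noise_sd = 0, seed = 1,
                         rp_days = 40, tmin_centre = 10, tmin_spread = 6) {
  set.seed(seed)
  rp_tmin <- lapply(seq_len(n_years), function(i) {
    round(runif(rp_days, tmin_centre - tmin_spread, tmin_centre + tmin_spread), 2)
  })
  r <- round(runif(n_years, 50, 250), 1)
  p <- vapply(rp_tmin, function(v) 100 * mean(v <= tc_true), numeric(1))
  yf <- beta0 + b_p * p + b_r * r + rnorm(n_years, 0, noise_sd)
  tibble::tibble(year = seq_len(n_years), yf = yf, r = r, rp_tmin = rp_tmin)
}

# Independent OLS oracle: normal-equations solve plus closed-form t p-value.
ols_oracle <- function(y, p, r) {
  X <- cbind(1, p, r)
  xtx <- t(X) %*% X
  beta <- solve(xtx, t(X) %*% y)
  res <- y - X %*% beta
  df <- length(y) - 3
  s2 <- sum(res^2) / df
  se <- sqrt(diag(solve(xtx)) * s2)
  tstat <- beta / se
  list(beta = as.numeric(beta),
       p = as.numeric(2 * stats::pt(-abs(tstat), df)))
}
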