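#' Root mean square deviation between simulated and measured series
#'
#' \deqn{\mathrm{RMSD} = \sqrt{ \frac{1}{N-1} \sum_{i=1}^{N} (S_i - M_i)^2 }.}
#' The `N - 1` divisor is the convention used for model evaluation here; the
#' usual `1/N` form is available via `divisor = "n"`.
#'
#' @param simulated,measured Equal-length numeric vectors (`N >= 2` for the
#'   default divisor).
#' @param divisor `"n_minus_1"` (default) or `"n"`.
#' @return Non-negative scalar in the units of the inputs; 0 iff the series
#'   are identical.
#' @export
#' @examples
#' rmsd(c(2, 3, 4), c(1, 2, 3))  # sqrt(3/2)
rmsd <- function(simulated, measured, divisor = c("n_minus_1", "n")) {
  divisor <- match.arg(divisor)
  if (length(simulated) != length(measured)) abort("series lengths differ.")
  n <- length(simulated)
  if (divisor == "n_minus_1" && n < 2) abort("need at least 2 pairs (divisor N - 1).")
  if (n < 1) abort("need at least 1 pair.")
  d <- if (divisor == "n_minus_1") n - 1 else n
  sqrt(sum((simulated - measured)^2) / d)
}

#' Willmott's index of agreement
#'
#' \deqn{d = 1 - \frac{\sum (S_i - M_i)^2}
#'   {\sum (|S_i - \bar M| + |M_i - \bar M|)^2},}
#' with \eqn{\bar M} the mean of the measured values. Bounded in \[0, 1\];
#' 1 iff the series are identical. Note the asymmetry: the reference mean is
#' always taken on the measured side.
#'
#' @param simulated,measured Equal-length numeric vectors; undefined
#'   (returned as `NA` with a warning) when every value equals the measured
#'   mean.
#' @return Scalar in \[0, 1\], or `NA` when undefined.
#' @export
#' @examples
#' willmott_d(c(2, 0), c(0, 2))  # 0
willmott_d <- function(simulated, measured) {
  if (length(simulated) != length(measured)) abort("series lengths differ.")
  mbar <- mean(measured)
  denom <- sum((abs(simulated - mbar) + abs(measured - mbar))^2)
  if (denom == 0) {
    warn("Willmott's d is undefined: all values equal the measured mean.")
    return(NA_real_)
  }
  1 - sum((simulated - measured)^2) / denom
}

#' Coefficient of determination between simulated and measured series
#'
#' The squared Pearson correlation between the two series (not the regression
#' R squared through the 1:1 line).
#'
#' @param simulated,measured Equal-length numeric vectors with positive
#'   variance; undefined (returned as `NA` with a warning) otherwise.
#' @return Scalar in \[0, 1\], or `NA` when undefined.
#' @export
r_squared <- function(simulated, measured) {
  if (length(simulated) != length(measured)) abort("series lengths differ.")
  if (sd(simulated) == 0 || sd(measured) == 0) {
    warn("R squared is undefined: a series has zero variance.")
    return(NA_real_)
  }
  stats::cor(simulated, measured)^2
}

#' Goodness-of-fit report for paired simulated/measured values
#'
#' One-stop evaluation of a model against measurements: RMSD (with the
#' `N - 1` divisor by default), Willmott's index of agreement and the squared
#' Pearson correlation.
#'
#' @param data Data frame holding the two series.
#' @param simulated,measured Column names (strings) of the simulated and
#'   measured values in `data`.
#' @param rmsd_divisor Passed to [rmsd()].
#' @return One-row tibble: `rmsd`, `d`, `r_squared`, `n`.
#' @export
#' @examples
#' df <- data.frame(sim = c(1, 2, 3, 4), obs = c(1, 2, 3, 5))
#' evaluate_fit(df, "sim", "obs")
evaluate_fit <- function(data, simulated = "simulated", measured = "measured",
                         rmsd_divisor = c("n_minus_1", "n")) {
  miss <- setdiff(c(simulated, measured), names(data))
  if (length(miss) > 0) abort(paste0("data is missing column(s): ", paste(miss, collapse = ", ")))
  s <- data[[simulated]]
  m <- data[[measured]]
  keep <- !is.na(s) & !is.na(m)
  s <- s[keep]; m <- m[keep]
  tibble(rmsd = rmsd(s, m, divisor = rmsd_divisor),
         d = willmott_d(s, m),
         r_squared = r_squared(s, m),
         n = length(s))
}
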