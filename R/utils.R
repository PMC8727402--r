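#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pt density quantile rnorm rbinom rgamma sd setNames
#' @importFrom utils head tail
NULL

# Validate that `x` is a single finite number; `what` names the offending field
# in the error message.
check_number <- function(x, what, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", what))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", what,
                  format(lower), format(upper), format(x)))
  }
  invisible(x)
}

check_weather <- function(weather) {
  need <- c("date", "tmin", "tmax", "rain")
  miss <- setdiff(need, names(weather))
  if (length(miss) > 0) {
    abort(paste0("weather is missing column(s): ", paste(miss, collapse = ", ")))
  }
  if (!inherits(weather$date, "Date")) abort("weather$date must be a Date column.")
  if (nrow(weather) > 1) {
    gaps <- diff(as.integer(weather$date))
    if (any(gaps != 1L)) {
      first_gap <- weather$date[which(gaps != 1L)[1]]
      abort(sprintf("weather dates are not contiguous (gap after %s).",
                    format(first_gap)))
    }
  }
  bad <- which(weather$tmin > weather$tmax)
  if (length(bad) > 0) {
    abort(sprintf("tmin > tmax on row %d (%s).", bad[1], format(weather$date[bad[1]])))
  }
  invisible(weather)
}

# Deterministic substream seed below 2^31, keyed on a master seed plus integer
# tags (e.g. year, component) so that adding years/locations does not perturb
# draws for earlier ones.
substream_seed <- function(master, ...) {
  tags <- c(...)
  s <- (master %% 1048576) + 1
  for (t in tags) {
    s <- (s * 69069 + (t %% 1048576) + 1) %% 2147483629
  }
  as.integer(s)
}

# Evaluate an expression under a local RNG state seeded from a substream.
with_substream <- function(master, ..., expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(substream_seed(master, ...))
  expr
}
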