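#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_vline geom_hline
#'   geom_area labs theme_minimal scale_colour_manual after_stat
NULL

#' Plot a threshold scan
#'
#' The p-value profile of the cold-day coefficient across the candidate
#' threshold grid (on a -log10 scale), with the 0.05 criterion and, when
#' supplied, the selected threshold marked.
#'
#' @param object A `tc_scan` from [scan_thresholds()].
#' @param result Optional `tc_result` to mark the selected threshold.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tc_scan <- function(object, result = NULL, ...) {
  df <- dplyr::filter(as_tibble(object), .data$fittable)
  p <- ggplot(df, aes(x = .data$tc, y = -log10(pmax(.data$p_beta1, 1e-300)))) +
    geom_line(colour = "steelblue") +
    geom_hline(yintercept = -log10(0.05), linetype = "dashed", colour = "grey40") +
    labs(x = expression(paste("candidate ", T[C], " (", degree, "C)")),
         y = expression(-log[10](p(beta[1]))),
         title = "Cold-temperature threshold scan") +
    theme_minimal()
  if (!is.null(result) && isTRUE(result$detected)) {
    p <- p + geom_vline(xintercept = result$tc, colour = "firebrick",
                        linetype = "dotted")
  }
  p
}

#' Plot a phenology trace
#'
#' Cumulative modified thermal time within each phase, coloured by growth
#' stage, with stage-entry dates marked.
#'
#' @param object A `pheno_trace` from [run_phenology()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pheno_trace <- function(object, ...) {
  df <- object$trace
  marks <- c(flowering = object$flowering_start, `pod fill end` = object$podfill_end)
  p <- ggplot(df, aes(x = .data$date, y = .data$cum_ttm,
                      colour = factor(.data$stage))) +
    geom_line() +
    labs(x = NULL, y = "cumulative modified thermal time (°Cd)",
         colour = "stage",
         title = sprintf("%s sown %s", object$cultivar, format(object$sowing_date))) +
    theme_minimal()
  for (m in marks[!is.na(marks)]) {
    p <- p + geom_vline(xintercept = m, linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot frost and peak-flowering timing densities
#'
#' Kernel density estimates (day of year) of frost events and peak flowering
#' across years — the visual counterpart of the overlap coefficient from
#' [flowering_frost_overlap()]. An absent frost curve means the site recorded
#' no frost.
#'
#' @param peak_flowering_doys Day-of-year of peak flowering per year.
#' @param frost_doys Day-of-year of frost events across years (may be empty).
#' @return A ggplot object.
#' @export
plot_frost_overlap <- function(peak_flowering_doys, frost_doys) {
  df <- dplyr::bind_rows(
    tibble(doy = as.numeric(peak_flowering_doys), what = "peak flowering"),
    if (length(frost_doys) > 0) tibble(doy = as.numeric(frost_doys), what = "frost events")
  )
  ggplot(df, aes(x = .data$doy, colour = .data$what, fill = .data$what)) +
    ggplot2::geom_density(alpha = 0.15, bw = "nrd0") +
    scale_colour_manual(values = c(`peak flowering` = "firebrick",
                                   `frost events` = "steelblue"),
                        aesthetics = c("colour", "fill")) +
    ggplot2::xlim(1, 366) +
    labs(x = "day of year", y = "density", colour = NULL, fill = NULL,
         title = "Frost vs peak-flowering timing") +
    theme_minimal()
}
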