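#' Plot a trajectory
#'
#' Cumulative methane production and pH over time.
#'
#' @param object an `ad_trajectory`
#' @param ... unused
#' @return a ggplot object
#' @method autoplot ad_trajectory
#' @export
autoplot.ad_trajectory <- function(object, ...) {
  d <- object$derived
  dd <- tidyr::pivot_longer(
    dplyr::select(d, "time", `cumulative CH4 (M)` = "cum_ch4_M", pH = "pH"),
    -"time", names_to = "series", values_to = "value")
  ggplot2::ggplot(dd, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.6) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (d)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked speciation bar chart
#'
#' @param report tibble from [speciation_fractions()], possibly
#'   row-bound over several runs with an extra `run` column
#' @return a ggplot object
#' @export
plot_speciation <- function(report) {
  xvar <- if ("run" %in% names(report)) "run" else "metal"
  ggplot2::ggplot(report,
                  ggplot2::aes(x = factor(.data[[xvar]]), y = .data$fraction,
                               fill = .data$pool)) +
    ggplot2::geom_col(position = "stack") +
    { if (xvar == "run") ggplot2::facet_wrap(~metal) } +
    ggplot2::labs(x = xvar, y = "% of total metal", fill = "pool") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
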