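#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trajectory into a long tibble
#'
#' @param x an `ad_trajectory`
#' @param ... unused
#' @return tibble: `time`, `component`, `phase`, `unit`, `value`
#' @method tidy ad_trajectory
#' @export
tidy.ad_trajectory <- function(x, ...) {
  comp <- x$registry$components
  wide <- tibble::as_tibble(x$states)
  wide$time <- x$times
  long <- tidyr::pivot_longer(wide, -"time", names_to = "component",
                              values_to = "value")
  j <- match(long$component, comp$id)
  long$phase <- comp$phase[j]
  long$unit <- comp$unit[j]
  dplyr::select(long, "time", "component", "phase", "unit", "value")
}

#' One-row trajectory summary
#'
#' @param x an `ad_trajectory`
#' @param ... unused
#' @return tibble with horizon, final pH, cumulative methane and the
#'   magnitude of any derivative flux discarded by the negativity floor
#' @method glance ad_trajectory
#' @export
glance.ad_trajectory <- function(x, ...) {
  tibble::tibble(
    t_end = max(x$times),
    n_components = ncol(x$states),
    pH_final = utils::tail(x$derived$pH, 1),
    cum_ch4_M = utils::tail(x$derived$cum_ch4_M, 1),
    cum_ch4_L = utils::tail(x$derived$cum_ch4_L, 1),
    clipped_flux = abs(x$clip_audit %||% 0)
  )
}
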