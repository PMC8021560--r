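#' Per-metal speciation report
#'
#' Partitions each trace metal among its chemical pools at a chosen time:
#' free ion, biomass-bound (surface-sorbed plus bio-uptaken), inert-bound,
#' sulfide (sulfide minerals plus metal sorbed on FeS), carbonate and
#' phosphate minerals, EDTA complexes and VFA complexes, each as a percent
#' of the total metal inventory in the reactor. Pools are classified from
#' the registry's component metadata, so user-extended registries report
#' correctly as long as content columns are filled in.
#'
#' @param traj an `ad_trajectory`
#' @param t day at which to report (defaults to the trajectory end); the
#'   nearest stored time point is used
#' @param metals metals to report
#' @return tibble: `metal`, `pool`, `fraction` (percent); fractions are
#'   `NA` for a metal absent from the system
#' @export
speciation_fractions <- function(traj, t = NULL,
                                 metals = c("Fe", "Ni", "Co")) {
  t <- t %||% max(traj$times)
  if (t < min(traj$times) || t > max(traj$times)) {
    stop("t = ", t, " outside the stored trajectory", call. = FALSE)
  }
  k <- which.min(abs(traj$times - t))
  y <- pmax(traj$states[k, ], 0)
  comp <- traj$registry$components

  content_col <- c(Fe = "fe", Ni = "ni", Co = "co", Ca = "ca", Mg = "mg")
  pools <- c("free", "biomass", "inert", "sulfide", "carbonate",
             "phosphate", "edta", "vfa")

  classify <- function(row) {
    if (row$phase == "soluble") {
      if (row$id %in% unname(metal_state)) return("free")
      if (row$edta > 0) return("edta")
      return("vfa")
    }
    if (row$phase == "occupied_site") {
      if (row$adsorbent == "X_I") return("inert")
      if (row$adsorbent == "X_FeS") return("sulfide")
      return("biomass")
    }
    if (row$phase == "precipitate") {
      if (row$s > 0) return("sulfide")
      if (row$p > 0) return("phosphate")
      return("carbonate")
    }
    if (row$phase == "particulate") return("biomass")  # bio-uptaken pools
    NA_character_
  }

  out <- list()
  for (m in metals) {
    cc <- comp[[content_col[[m]]]]
    hold <- which(cc > 0)
    amounts <- stats::setNames(numeric(length(pools)), pools)
    for (j in hold) {
      pool <- classify(comp[j, ])
      if (!is.na(pool)) amounts[pool] <- amounts[pool] + cc[j] * y[j]
    }
    total <- sum(amounts)
    frac <- if (total > 0) 100 * amounts / total else rep(NA_real_,
                                                          length(pools))
    out[[m]] <- tibble::tibble(metal = m, pool = pools,
                               fraction = unname(frac))
  }
  dplyr::bind_rows(out)
}
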