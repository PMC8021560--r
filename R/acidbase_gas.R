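#' Kinetic acid-base interconversion rates
#'
#' Each conjugate pair relaxes to equilibrium with the fast kinetic law
#' `rho = k_AB * ([HA] - [A-][H+]/Ka)`; a positive rate converts acid to
#' base. The proton itself is not a state variable: pH follows from the
#' charge balance (see [solve_ph()]), so each pair conserves its total
#' (acid + base) amount exactly.
#'
#' @param state named state vector
#' @param params an `ad_parameters` object (section `acid_base`)
#' @param pH reactor pH; computed from the charge balance when `NULL`
#' @return named vector of pair rates (state units per day), one per pair,
#'   named `ab_<acid>`
#' @export
acid_base_rates <- function(state, params, pH = NULL) {
  ab <- params$acid_base
  if (is.null(pH)) pH <- solve_ph_value(state, params)
  H <- 10^(-pH)
  Ka <- 10^(-ab$pKa)
  acid <- pmax(state[ab$acid], 0)
  base <- pmax(state[ab$base], 0)
  rho <- ab$k_AB * (acid - base * H / Ka)
  stats::setNames(rho, paste0("ab_", sub("^S_", "", ab$acid)))
}

# Closed-form charge-balance pH. All ionic species are explicit states, so
# with Theta = sum(z_i * c_i) over the dissolved ions the balance
# Theta + [H+] - Kw/[H+] = 0 is a quadratic in [H+].
solve_ph_value <- function(state, params, registry = NULL,
                           charge_weights = NULL) {
  if (is.null(charge_weights)) {
    reg <- registry %||% build_default_registry(params)
    charge_weights <- registry_charge_weights(reg)
  }
  theta <- sum(pmax(state[names(charge_weights)], 0) * charge_weights)
  Kw <- params$phys$Kw
  H <- (-theta + sqrt(theta^2 + 4 * Kw)) / 2
  -log10(H)
}

registry_charge_weights <- function(reg) {
  comp <- reg$components
  sel <- comp$charge != 0 & comp$phase == "soluble"
  stats::setNames(comp$charge[sel] * comp$mol_per_unit[sel], comp$id[sel])
}

#' Charge-balance pH of a state
#'
#' Solves `sum(z_i * c_i) + [H+] - Kw/[H+] = 0` over the registry's charged
#' soluble components by root bracketing on pH in [1, 14].
#'
#' @param state named state vector
#' @param registry an `ad_registry` supplying per-component charges
#' @param params an `ad_parameters` object (for `Kw`)
#' @return pH value
#' @export
solve_ph <- function(state, registry, params = default_parameters()) {
  w <- registry_charge_weights(registry)
  theta <- sum(pmax(state[names(w)], 0) * w)
  Kw <- params$phys$Kw
  f <- function(pH) theta + 10^(-pH) - Kw / 10^(-pH)
  if (f(1) < 0 || f(14) > 0) {
    stop("charge balance has no root in pH [1, 14]; infeasible composition",
         call. = FALSE)
  }
  stats::uniroot(f, c(1, 14), tol = 1e-12)$root
}

#' Liquid-gas transfer rates
#'
#' Two-film transfer `rho_T = kLa * (S_liq - K_H * p_gas)` for H2, CH4, CO2
#' and H2S, in the units of the liquid-phase state (gCOD/L/d for H2 and
#' CH4, mol/L/d for CO2 and H2S). Headspace partial pressures follow the
#' ideal gas law from the molar headspace concentrations.
#'
#' @param state named liquid state vector
#' @param headspace named vector with `S_gas_h2`, `S_gas_ch4`, `S_gas_co2`,
#'   `S_gas_h2s` in mol/L gas
#' @param params an `ad_parameters` object (section `gas`)
#' @param temperature reactor temperature, degrees C
#' @return named vector `c(gt_h2, gt_ch4, gt_co2, gt_h2s)` of transfer
#'   rates out of the liquid
#' @export
gas_transfer_rates <- function(state, headspace, params,
                               temperature = 35) {
  g <- params$gas
  RT <- params$phys$R * (273.15 + temperature)
  p <- pmax(headspace[c("S_gas_h2", "S_gas_ch4", "S_gas_co2",
                        "S_gas_h2s")], 0) * RT
  c(
    gt_h2 = g$kLa * (max(state[["S_h2"]], 0) - 16 * g$K_H[["h2"]] * p[[1]]),
    gt_ch4 = g$kLa * (max(state[["S_ch4"]], 0) - 64 * g$K_H[["ch4"]] * p[[2]]),
    gt_co2 = g$kLa * (max(state[["S_co2"]], 0) - g$K_H[["co2"]] * p[[3]]),
    gt_h2s = g$kLa * (max(state[["S_h2s"]], 0) - g$K_H[["h2s"]] * p[[4]])
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
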