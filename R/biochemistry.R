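#' Trace-metal dose-response factor
#'
#' Rational dose-response function applied as a multiplier on methanogenic
#' uptake kinetics: `I(x) = (a1*x + a2) / (x^2 + b1*x + b2)` with
#' `x = TE_free + C_complexed` (free metal plus its EDTA-complexed fraction,
#' both bioavailable; surface-sorbed metal never enters). The value is
#' clipped to [0, 1] for use as a rate multiplier: the function stimulates
#' up to an optimum concentration and inhibits beyond it.
#'
#' @param TE_free free metal concentration, M
#' @param C_complexed bioavailable complexed metal concentration, M
#' @param a1,a2,b1,b2 dose-response constants (units consistent with M)
#' @return dimensionless factor in [0, 1]
#' @export
te_inhibition <- function(TE_free, C_complexed = 0, a1, a2, b1, b2) {
  stopifnot(all(TE_free >= 0), all(C_complexed >= 0))
  x <- TE_free + C_complexed
  den <- x^2 + b1 * x + b2
  if (any(den <= 0)) {
    stop("dose-response denominator not positive; check b1/b2", call. = FALSE)
  }
  pmin(pmax((a1 * x + a2) / den, 0), 1)
}

#' Dose-response constants peaking at a given optimum
#'
#' Convenience constructor: with `b2 = x_opt^2`, `b1 = breadth * x_opt`,
#' `a1 = (2 + breadth) * x_opt` and `a2 = 0` the factor equals 1 exactly
#' at `x_opt`, stays near 1 over roughly a `breadth`-fold band either side
#' (a wide dose plateau), and falls towards 0 at strong starvation or
#' overdose. `breadth = 0` gives the narrow symmetric variant.
#'
#' @param x_opt optimal bioavailable concentration, M
#' @param breadth width parameter of the dose plateau (default 10)
#' @return named numeric vector `c(a1, a2, b1, b2)`
#' @export
dose_response_constants <- function(x_opt, breadth = 10) {
  stopifnot(x_opt > 0, breadth >= 0)
  c(a1 = (2 + breadth) * x_opt, a2 = 0, b1 = breadth * x_opt,
    b2 = x_opt^2)
}

# per-metal dose-response table from vectors of optima and plateau widths
dose_response_table <- function(x_opt, breadth = 10) {
  breadth <- rep(breadth, length.out = length(x_opt))
  k <- t(mapply(dose_response_constants, x_opt, breadth))
  tibble::tibble(metal = names(x_opt), a1 = unname(k[, "a1"]),
                 a2 = unname(k[, "a2"]), b1 = unname(k[, "b1"]),
                 b2 = unname(k[, "b2"]))
}

#' Element source terms from composite disintegration
#'
#' Sulfur is released as bisulfide (HS-), phosphorus as hydrogen phosphate
#' (HPO4 2-) -- the dominant forms at digester pH -- and metals as free
#' divalent ions, each proportional to the disintegration rate.
#'
#' @param rate_dis disintegration rate, gCOD/L/d
#' @param release named vector of release coefficients, mol per gCOD of
#'   composite (names `S`, `P`, `Fe`, `Ni`, `Co`, `Ca`, `Mg`)
#' @return tibble with columns `component` and `source` (mol/L/d)
#' @export
disintegration_release <- function(rate_dis, release) {
  stopifnot(rate_dis >= 0, all(release >= 0))
  comp <- c(S = "S_hs", P = "S_hpo4", Fe = "S_fe", Ni = "S_ni",
            Co = "S_co", Ca = "S_ca", Mg = "S_mg")
  tibble::tibble(
    component = unname(comp[names(release)]),
    source = unname(release) * rate_dis
  )
}

# ADM1 lower-side pH inhibition, Hill form on the hydrogen ion: ~1 above
# pH_UL, 0.5 at the midpoint of the band, ~0 below pH_LL.
ph_inhibition <- function(pH, pH_UL, pH_LL) {
  n <- 3 / (pH_UL - pH_LL)
  K <- 10^(-(pH_UL + pH_LL) / 2)
  1 / (1 + (10^(-pH) / K)^n)
}

#' ADM1 biochemical process rates with trace-metal effects
#'
#' Computes the 19 ADM1 process rates (disintegration, hydrolysis, eight
#' Monod substrate uptakes, seven first-order biomass decays) together with
#' the three trace-metal bio-uptake rates that are proportional to the
#' acetate and hydrogen uptake rates. Methanogenic uptakes (acetate and
#' hydrogen) are additionally multiplied by the product of the per-metal
#' dose-response factors computed from free + EDTA-complexed Fe, Ni and Co.
#'
#' @param state named state vector (see [state_template()])
#' @param params an `ad_parameters` object
#' @param pH reactor pH; computed from the charge balance when `NULL`
#' @return named vector of process rates (gCOD/L/d for biochemical
#'   processes; mol/L/d for the `upt_te_*` metal uptakes), named by the
#'   registry `rate_ref` / reaction ids
#' @export
biochemical_rates <- function(state, params, pH = NULL) {
  b <- params$biochem
  y <- pmax(state, 0)
  if (is.null(pH)) pH <- solve_ph_value(state, params)

  S_IN <- y[["S_nh4"]] + y[["S_nh3"]]
  I_IN <- S_IN / (S_IN + b$K_S_IN)
  I_pH_aa <- ph_inhibition(pH, b$pH_UL_aa, b$pH_LL_aa)
  I_pH_ac <- ph_inhibition(pH, b$pH_UL_ac, b$pH_LL_ac)
  I_pH_h2 <- ph_inhibition(pH, b$pH_UL_h2, b$pH_LL_h2)
  I_h2_fa <- 1 / (1 + y[["S_h2"]] / b$K_I_h2_fa)
  I_h2_c4 <- 1 / (1 + y[["S_h2"]] / b$K_I_h2_c4)
  I_h2_pro <- 1 / (1 + y[["S_h2"]] / b$K_I_h2_pro)
  I_nh3 <- 1 / (1 + y[["S_nh3"]] / b$K_I_nh3)

  I_te <- te_inhibition_product(state, params)

  monod <- function(k_m, S, K_S, X) k_m * S / (K_S + S) * X

  # total VFA pools drive Monod saturation; uptake draws on the anion form
  S_va_t <- y[["S_va"]] + y[["S_hva"]]
  S_bu_t <- y[["S_bu"]] + y[["S_hbu"]]
  S_pro_t <- y[["S_pro"]] + y[["S_hpro"]]
  S_ac_t <- y[["S_ac"]] + y[["S_hac"]]

  r <- c(
    dis = b$k_dis * y[["X_c"]],
    dis_dec = b$k_dis * y[["X_c_dec"]],
    hyd_ch = b$k_hyd_ch * y[["X_ch"]],
    hyd_pr = b$k_hyd_pr * y[["X_pr"]],
    hyd_li = b$k_hyd_li * y[["X_li"]],
    upt_su = monod(b$k_m_su, y[["S_su"]], b$K_S_su, y[["X_su"]]) *
      I_pH_aa * I_IN,
    upt_aa = monod(b$k_m_aa, y[["S_aa"]], b$K_S_aa, y[["X_aa"]]) *
      I_pH_aa * I_IN,
    upt_fa = monod(b$k_m_fa, y[["S_fa"]], b$K_S_fa, y[["X_fa"]]) *
      I_pH_aa * I_IN * I_h2_fa,
    upt_va = monod(b$k_m_c4, S_va_t, b$K_S_c4, y[["X_c4"]]) *
      (S_va_t / (S_va_t + S_bu_t + 1e-10)) * I_pH_aa * I_IN * I_h2_c4,
    upt_bu = monod(b$k_m_c4, S_bu_t, b$K_S_c4, y[["X_c4"]]) *
      (S_bu_t / (S_va_t + S_bu_t + 1e-10)) * I_pH_aa * I_IN * I_h2_c4,
    upt_pro = monod(b$k_m_pro, S_pro_t, b$K_S_pro, y[["X_pro"]]) *
      I_pH_aa * I_IN * I_h2_pro,
    upt_ac = monod(b$k_m_ac, S_ac_t, b$K_S_ac, y[["X_ac"]]) *
      I_pH_ac * I_IN * I_nh3 * I_te,
    upt_h2 = monod(b$k_m_h2, y[["S_h2"]], b$K_S_h2, y[["X_h2"]]) *
      I_pH_h2 * I_IN * I_te
  )
  dec <- b$k_dec * y[biomass_ids]
  names(dec) <- paste0("dec_", biomass_ids)

  # metal uptake proportional to the methanogenic substrate turnover, with
  # a saturation guard so an exhausted metal pool cannot go negative
  drive <- r[["upt_ac"]] + r[["upt_h2"]]
  upt <- b$uptake
  te <- c(
    upt_te_fe = upt[["Fe"]] * drive * y[["S_fe"]] / (y[["S_fe"]] + b$K_uptake),
    upt_te_ni = upt[["Ni"]] * drive * y[["S_ni"]] / (y[["S_ni"]] + b$K_uptake),
    upt_te_co = upt[["Co"]] * drive * y[["S_co"]] / (y[["S_co"]] + b$K_uptake)
  )

  c(r, te, dec)
}

# Product of the per-metal dose-response factors over Fe, Ni, Co.
te_inhibition_product <- function(state, params) {
  inh <- params$inhibition
  cx <- c(Fe = "S_feedta", Ni = "S_niedta", Co = "S_coedta")
  free <- c(Fe = "S_fe", Ni = "S_ni", Co = "S_co")
  out <- 1
  for (i in seq_len(nrow(inh))) {
    m <- inh$metal[i]
    out <- out * te_inhibition(max(state[[free[[m]]]], 0),
                               max(state[[cx[[m]]]], 0),
                               inh$a1[i], inh$a2[i], inh$b1[i], inh$b2[i])
  }
  out
}
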