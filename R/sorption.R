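#' Free binding-site generation from adsorbent growth
#'
#' New sorption surface (biomass growth, inert formation, FeS
#' precipitation) carries fresh free binding sites in proportion to the
#' surface's binding-site density. Negative growth (decay, dissolution)
#' removes free and occupied sites proportionally and is handled by the
#' decay/shedding reactions, not by this source term.
#'
#' @param adsorbent_growth adsorbent dry-mass growth rate, g/L/d
#' @param delta binding-site density, mol sites per g
#' @return free-site source, mol sites/L/d
#' @export
site_generation_rate <- function(adsorbent_growth, delta) {
  stopifnot(delta >= 0)
  delta * adsorbent_growth
}

#' Sorption rate onto free binding sites
#'
#' Bilinear (second-order overall) sorption law
#' `rho_ads = K_a_d * k_ads * X_ads * S_TE`.
#'
#' @param S_TE free metal concentration, M
#' @param X_ads free binding-site concentration, mol sites/L
#' @param k_ads sorption rate constant, 1/(M d)
#' @param K_a_d dimensionless saturation multiplier
#' @return sorption rate, mol sites/L/d
#' @export
sorption_rate <- function(S_TE, X_ads, k_ads, K_a_d = 1) {
  K_a_d * k_ads * pmax(X_ads, 0) * pmax(S_TE, 0)
}

#' Desorption rate from occupied binding sites
#'
#' First-order desorption law `rho_des = K_a_d * k_des * X_occ`.
#'
#' @param X_occ occupied binding-site concentration, mol sites/L
#' @param k_des desorption rate constant, 1/d
#' @param K_a_d dimensionless saturation multiplier
#' @return desorption rate, mol sites/L/d
#' @export
desorption_rate <- function(X_occ, k_des, K_a_d = 1) {
  K_a_d * k_des * pmax(X_occ, 0)
}

#' Net sorption fluxes for every metal-surface pair
#'
#' All metals compete for the shared free-site pool of each surface; the
#' net flux per pair is `sorption_rate - desorption_rate`. With a single
#' metal this reduces to the reversible pair, and at equilibrium the
#' occupancies solve the multi-species Langmuir system.
#'
#' @param state named state vector
#' @param registry an `ad_registry`
#' @param params an `ad_parameters` object (section `sorption`)
#' @return tibble with one row per pair: `surface`, `adsorbent`, `metal`,
#'   `rho_ads`, `rho_des`, `net` (mol sites/L/d, net positive = sorption)
#' @export
competition_assembly <- function(state, registry, params) {
  pairs <- sorption_pair_index(registry, params)
  rho_a <- sorption_rate(state[pairs$metal_id], state[pairs$free_id],
                         pairs$k_ads, params$sorption$K_a_d)
  rho_d <- desorption_rate(state[pairs$occ_id], pairs$k_des,
                           params$sorption$K_a_d)
  tibble::tibble(
    surface = pairs$surface, adsorbent = pairs$adsorbent,
    metal = pairs$metal,
    rho_ads = unname(rho_a), rho_des = unname(rho_d),
    net = unname(rho_a - rho_d)
  )
}

# Expanded pair table: one row per (adsorbent component, metal) with state
# ids and rate constants resolved.
sorption_pair_index <- function(registry, params) {
  comp <- registry$components
  occ <- comp[comp$phase == "occupied_site", ]
  cls <- ifelse(occ$adsorbent == "X_I", "inert",
                ifelse(occ$adsorbent == "X_FeS", "fes", "biomass"))
  key <- paste(cls, occ$site_metal)
  ptab <- params$sorption$pairs
  pk <- paste(ptab$surface, ptab$metal)
  j <- match(key, pk)
  tibble::tibble(
    surface = cls,
    adsorbent = occ$adsorbent,
    metal = occ$site_metal,
    metal_id = unname(metal_state[occ$site_metal]),
    free_id = free_site_id(occ$adsorbent),
    occ_id = occ$id,
    k_ads = ptab$k_ads[j],
    k_des = ptab$k_des[j]
  )
}

#' Metal release and site turnover on biomass decay
#'
#' Decaying biomass loses its binding sites in proportion to the decayed
#' fraction; metals on the lost occupied sites return to the free pool,
#' and the decayed mass ultimately regenerates inert surface (carrying
#' fresh inert sites) through the composite disintegration step. This
#' decay pathway is distinct from desorption.
#'
#' @param biomass_decay_rate decay rate of the biomass, gCOD/L/d
#' @param biomass biomass concentration, gCOD/L
#' @param free_sites free sites on that biomass, mol/L
#' @param occupied named vector of occupied sites on that biomass, mol/L
#' @param I_delta inert binding-site density, mol/g
#' @param f_xI inert fraction of the disintegrated composite
#' @return list with `metal_release` (named mol/L/d, per occupied-site
#'   pool), `free_site_loss`, `occupied_site_loss` (mol/L/d) and
#'   `inert_site_generation` (mol/L/d, realised after re-disintegration)
#' @export
decay_release <- function(biomass_decay_rate, biomass, free_sites, occupied,
                          I_delta = 2e-3, f_xI = 0.2) {
  stopifnot(biomass_decay_rate >= 0)
  frac <- if (biomass > 0) biomass_decay_rate / biomass else 0
  list(
    metal_release = occupied * frac,
    free_site_loss = free_sites * frac,
    occupied_site_loss = occupied * frac,
    inert_site_generation = I_delta * f_xI * biomass_decay_rate
  )
}
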