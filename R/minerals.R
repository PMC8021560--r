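# The parameter table states each solubility product in its classic
# lattice-ion convention (S2-, CO3 2-, PO4 3-). Those anions sit many
# orders of magnitude below their protonated parents at digester pH, so
# the working rate laws are recast onto the dominant forms (HS-, HCO3-,
# HPO4 2-) with the corresponding acid-base constant folded into an
# operational solubility product and an explicit proton power:
#   [Me][S2-] / Ksp  ==  [Me][HS-] / ([H+] * Ksp/Ka2).
# The equilibrium is identical; the numerics are well conditioned.
operational_mineral_table <- function(params) {
  ab <- params$acid_base
  pka_of <- function(acid, base) ab$pKa[ab$acid == acid & ab$base == base]
  subs <- list(
    S_s2 = list(parent = "S_hs", pKa = pka_of("S_hs", "S_s2")),
    S_co3 = list(parent = "S_hco3", pKa = pka_of("S_hco3", "S_co3")),
    S_po4 = list(parent = "S_hpo4", pKa = pka_of("S_hpo4", "S_po4"))
  )
  mn <- params$minerals
  ions_op <- vector("list", nrow(mn))
  h_power <- numeric(nrow(mn))
  log_op <- mn$log10_Ksp
  for (i in seq_len(nrow(mn))) {
    ions <- mn$ions[[i]]
    shift <- 0; hp <- 0
    for (nm in names(ions)) {
      if (nm %in% names(subs)) {
        su <- subs[[nm]]
        shift <- shift + ions[[nm]] * su$pKa
        hp <- hp + ions[[nm]]
        names(ions)[names(ions) == nm] <- su$parent
      }
    }
    # merge duplicated ion names after substitution
    ions <- tapply(unname(ions), names(ions), sum)
    ions_op[[i]] <- stats::setNames(as.numeric(ions), names(ions))
    h_power[i] <- hp
    log_op[i] <- mn$log10_Ksp[i] + shift
  }
  tibble::tibble(mineral = mn$mineral, ions = ions_op, h_power = h_power,
                 log10_Ksp_op = log_op, k_prec = mn$k_prec,
                 k_dissol = rep(mn$k_dissol, length.out = nrow(mn)))
}

state_ph <- function(state, params) {
  comps <- td_cache_components()
  sel <- comps$charge != 0 & comps$phase == "soluble"
  ids <- comps$id[sel]
  w <- comps$charge[sel] * comps$mol_per_unit[sel]
  theta <- sum(pmax(state[ids], 0) * w, na.rm = TRUE)
  Kw <- params$phys$Kw
  -log10((-theta + sqrt(theta^2 + 4 * Kw)) / 2)
}

td_cache <- new.env(parent = emptyenv())
td_cache_components <- function() {
  if (is.null(td_cache$components)) {
    td_cache$components <- build_components(default_parameters())
  }
  td_cache$components
}

#' Mineral saturation state
#'
#' Ratio of the ion activity product to the solubility product,
#' `Omega = IAP / Ksp`, evaluated over the mineral's lattice ions
#' (concentrations are used as activities). `Omega > 1` marks
#' supersaturation, `Omega < 1` undersaturation. Internally the product is
#' computed on the dominant protonation form of each lattice anion with
#' the matching acid-base constant folded in, which leaves the value
#' identical when the ladder is at equilibrium at the given pH.
#'
#' @param state named state vector
#' @param mineral precipitate component id (e.g. `"X_FeS"`)
#' @param params an `ad_parameters` object (section `minerals`)
#' @param pH pH at which to evaluate; computed from the state's charge
#'   balance when `NULL`
#' @return dimensionless saturation state
#' @export
saturation_state <- function(state, mineral, params, pH = NULL) {
  op <- operational_mineral_table(params)
  i <- match(mineral, op$mineral)
  if (is.na(i)) stop("unknown mineral: ", mineral, call. = FALSE)
  pH <- pH %||% state_ph(state, params)
  H <- 10^(-pH)
  ions <- op$ions[[i]]
  iap <- prod(pmax(state[names(ions)], 0)^ions) / H^op$h_power[i]
  iap / 10^op$log10_Ksp_op[i]
}

#' Kinetic precipitation rate
#'
#' Second-order law in the supersaturation driving force,
#' `rho_prec = k_prec * (sqrt(Omega) - 1)^2` for `Omega > 1`, zero
#' otherwise; it vanishes smoothly at equilibrium. A linear alternative
#' `k_prec * (Omega - 1)` clipped at zero is available via `law`.
#'
#' @param state named state vector
#' @param mineral precipitate component id
#' @param params an `ad_parameters` object
#' @param pH pH at which to evaluate (`NULL`: from the charge balance)
#' @param law `"sqrt"` (default) or `"linear"`
#' @return precipitation rate, mol/L/d (non-negative)
#' @export
precipitation_rate <- function(state, mineral, params, pH = NULL,
                               law = c("sqrt", "linear")) {
  law <- match.arg(law)
  i <- match(mineral, params$minerals$mineral)
  if (is.na(i)) stop("unknown mineral: ", mineral, call. = FALSE)
  omega <- saturation_state(state, mineral, params, pH)
  k <- params$minerals$k_prec[i]
  if (omega <= 1) return(0)
  if (law == "sqrt") k * (sqrt(omega) - 1)^2 else k * (omega - 1)
}

#' Kinetic dissolution rate
#'
#' First order in the precipitate inventory and the undersaturation,
#' `rho_dissol = k_dissol * X_p * (1 - Omega)` for `Omega < 1` and
#' `X_p > 0`, zero otherwise. Dissolution stops when either the solution
#' reaches saturation or the solid is exhausted.
#'
#' @param state named state vector (the precipitate concentration is read
#'   from it under the mineral id)
#' @param mineral precipitate component id
#' @param params an `ad_parameters` object
#' @param pH pH at which to evaluate (`NULL`: from the charge balance)
#' @return dissolution rate, mol/L/d (non-negative)
#' @export
dissolution_rate <- function(state, mineral, params, pH = NULL) {
  i <- match(mineral, params$minerals$mineral)
  if (is.na(i)) stop("unknown mineral: ", mineral, call. = FALSE)
  xp <- max(state[[mineral]], 0)
  if (xp <= 0) return(0)
  omega <- saturation_state(state, mineral, params, pH)
  if (omega >= 1) return(0)
  params$minerals$k_dissol[i] * xp * (1 - omega)
}
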