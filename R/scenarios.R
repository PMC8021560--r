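#' Base batch initial state
#'
#' The common initial composition of the batch simulation scenarios:
#' 2 gCOD/L composite organic matter, the seven ADM1 biomass guilds at
#' 0.12 gCOD/L, ammonium 6 mM, carbonate 4 mM, Ca and Mg 2.5 mM, Fe 1e-4,
#' Ni 1e-5 and Co 1e-7 M, phosphate 6 mM, bisulfide 1 mM, EDTA 1e-4 M and
#' zero VFAs. Free binding sites are initialised at site density times the
#' initial adsorbent dry mass with no occupancy, and an inert counter-ion
#' (`S_cat`/`S_an`) is added so the initial charge balance sits at pH 7.
#'
#' @param registry an `ad_registry`
#' @param params an `ad_parameters`
#' @param overrides named numeric vector of component overrides applied
#'   before site initialisation and charge balancing
#' @return named initial state vector
#' @export
base_initial_state <- function(registry, params, overrides = NULL) {
  y <- state_template(registry)
  y["X_c"] <- 2
  y[biomass_ids] <- 0.12
  y["S_nh4"] <- 0.006
  y["S_co3"] <- 0.004
  y["S_ca"] <- 0.0025
  y["S_mg"] <- 0.0025
  y["S_ni"] <- 1e-5
  y["S_co"] <- 1e-7
  y["S_fe"] <- 1e-4
  y["S_po4"] <- 0.006
  y["S_hs"] <- 0.001
  y["S_edta"] <- 1e-4
  if (!is.null(overrides)) {
    y[names(overrides)] <- overrides
  }
  initialise_sites_and_charge(y, registry, params)
}

# Distribute each acid-base ladder's total over its forms at the given pH
# so the simulation does not start with an artificial relaxation transient.
equilibrate_acid_base <- function(y, params, pH = 7) {
  H <- 10^(-pH)
  ladders <- list(
    c("S_hva", "S_va"), c("S_hbu", "S_bu"), c("S_hpro", "S_pro"),
    c("S_hac", "S_ac"),
    c("S_co2", "S_hco3", "S_co3"),
    c("S_nh4", "S_nh3"),
    c("S_h3po4", "S_h2po4", "S_hpo4", "S_po4"),
    c("S_h2s", "S_hs", "S_s2"),
    c("S_hso4", "S_so4"),
    c("S_h2edta", "S_hedta", "S_edta")
  )
  ab <- params$acid_base
  for (forms in ladders) {
    total <- sum(y[forms])
    if (total <= 0) next
    # cumulative deprotonation factors relative to the most protonated form
    fac <- 1
    for (k in seq_len(length(forms) - 1)) {
      i <- which(ab$acid == forms[k] & ab$base == forms[k + 1])
      Ka <- 10^(-ab$pKa[i])
      fac <- c(fac, fac[k] * Ka / H)
    }
    y[forms] <- total * fac / sum(fac)
  }
  y
}

# Partition the initial EDTA pool over the metals at the (fixed) initial
# pH so integration does not start with a violent complexation transient.
# Solves the shared-ligand equilibrium U + sum(MeL) = EDTA_total with
# MeL = T_m K_m L / (1 + K_m L), L = alpha4 * U.
equilibrate_edta <- function(y, params, pH = 7) {
  cx <- params$complexes[params$complexes$ligand %in%
                           c("S_edta", "S_hedta"), ]
  if (nrow(cx) == 0) return(y)
  total_L <- sum(y[c("S_h2edta", "S_hedta", "S_edta")]) +
    sum(y[cx$complex])
  if (total_L <= 0) return(y)
  totals <- y[cx$metal] + y[cx$complex]
  K <- 10^cx$log10_K
  H <- 10^(-pH)
  ab <- params$acid_base
  Ka3 <- 10^(-ab$pKa[ab$acid == "S_h2edta"])
  Ka4 <- 10^(-ab$pKa[ab$acid == "S_hedta"])
  fac <- c(1, Ka3 / H, Ka3 * Ka4 / H^2)
  alpha_lig <- fac[2] / sum(fac)   # HEDTA3- fraction of uncomplexed EDTA
  resid <- function(U) {
    L <- alpha_lig * U
    U + sum(totals * K * L / (1 + K * L)) - total_L
  }
  U <- stats::uniroot(resid, c(0, total_L), tol = 1e-18)$root
  L <- alpha_lig * U
  bound <- totals * K * L / (1 + K * L)
  y[cx$complex] <- bound
  y[cx$metal] <- totals - bound
  y[c("S_h2edta", "S_hedta", "S_edta")] <- U * fac / sum(fac)
  y
}

initialise_sites_and_charge <- function(y, registry, params) {
  y <- equilibrate_acid_base(y, params, pH = 7)
  y <- equilibrate_edta(y, params, pH = 7)
  srt <- params$sorption
  for (bb in biomass_ids) {
    y[free_site_id(bb)] <- srt$B_delta * srt$cod_to_dw_biomass * y[[bb]]
  }
  y[free_site_id("X_I")] <- srt$I_delta * srt$cod_to_dw_inert * y[["X_I"]]
  y[free_site_id("X_FeS")] <- srt$P_delta * srt$M_FeS * y[["X_FeS"]]
  # neutralise the initial charge imbalance with an inert counter-ion so
  # the simulation starts near pH 7 (salts are dosed with counter-ions)
  w <- registry_charge_weights(registry)
  y["S_cat"] <- 0; y["S_an"] <- 0
  theta <- sum(y[names(w)] * w)
  if (theta < 0) y["S_cat"] <- -theta else y["S_an"] <- theta
  y
}

scenario_table <- function() {
  list(
    "1" = list(target = "X_c",
               values = c(1, 2, 3, 4, 5)),
    "2fe" = list(target = "S_fe",
                 values = c(5e-6, 9e-6, 3e-5, 7e-5, 1e-4, 5e-4, 9e-4, 3e-3)),
    "2ni" = list(target = "S_ni",
                 values = c(5e-7, 9e-7, 3e-6, 7e-6, 1e-5, 5e-5, 9e-5, 3e-4)),
    "2co" = list(target = "S_co",
                 values = c(5e-9, 9e-9, 3e-8, 7e-8, 1e-7, 5e-7, 9e-7, 3e-6)),
    "3" = list(target = "camg",
               values = c(1e-3, 1.5e-3, 2e-3, 2.5e-3, 3e-3, 3.5e-3, 4e-3, 4.5e-3)),
    "4" = list(target = "S_edta",
               values = c(1e-5, 2e-5, 3e-5, 4e-5, 5e-5, 6e-5, 7e-5, 8e-5,
                          9e-5, 1e-4)),
    "5b" = list(target = "B_delta",
                values = 2 * 10^c(1, 0, -1, -2, -3, -4, -5, -6, -7)),
    "5i" = list(target = "I_delta",
                values = 2 * 10^c(1, 0, -1, -2, -3, -4, -5, -6, -7)),
    "5p" = list(target = "P_delta",
                values = 2 * 10^c(-1, -2, -3, -4, -5, -6, -7, -8))
  )
}

#' Build a preset batch scenario
#'
#' Five scenario families vary one input at a time over the common batch
#' base state: `"1"` the composite organic loading (1-5 gCOD/L),
#' `"2fe"`/`"2ni"`/`"2co"` the initial concentration of one trace metal,
#' `"3"` the initial Ca and Mg (jointly), `"4"` the initial EDTA, and
#' `"5b"`/`"5i"`/`"5p"` the biomass/inert/precipitate binding-site density.
#' The reactor is a 0.75 L working volume batch digester with 0.25 L
#' headspace at 35 degrees C run for 100 days.
#'
#' @param scenario scenario code (see Details); integers are accepted for
#'   `1`, `3`, `4`
#' @param run run index within the scenario's value ladder
#' @param params base parameter set
#' @param t_end horizon in days (default 100)
#' @return list with `config`, `initial`, `params`, `registry` and the
#'   applied `overrides`
#' @export
build_scenario <- function(scenario, run, params = default_parameters(),
                           t_end = 100) {
  tab <- scenario_table()
  key <- tolower(as.character(scenario))
  if (!key %in% names(tab)) {
    stop("unknown scenario '", scenario, "'; one of: ",
         paste(names(tab), collapse = ", "), call. = FALSE)
  }
  sc <- tab[[key]]
  if (!(run %in% seq_along(sc$values))) {
    stop("run index ", run, " out of range 1..", length(sc$values),
         " for scenario ", key, call. = FALSE)
  }
  value <- sc$values[run]

  state_overrides <- NULL
  if (sc$target %in% c("B_delta", "I_delta", "P_delta")) {
    params <- modify_parameters(params,
                                list(sorption = stats::setNames(list(value),
                                                                sc$target)))
  } else if (sc$target == "camg") {
    state_overrides <- c(S_ca = value, S_mg = value)
  } else {
    state_overrides <- stats::setNames(value, sc$target)
  }

  registry <- build_default_registry(params)
  initial <- base_initial_state(registry, params, state_overrides)
  config <- reactor_config(V_liq = 0.75, V_gas = 0.25, temperature = 35,
                           mode = "batch", t_end = t_end)
  list(config = config, initial = initial, params = params,
       registry = registry, overrides = state_overrides, scenario = key,
       run = run)
}

#' Run a preset scenario
#'
#' Convenience wrapper: [build_scenario()] followed by
#' [simulate_reactor()].
#'
#' @inheritParams build_scenario
#' @return an `ad_trajectory`
#' @export
run_scenario <- function(scenario, run, params = default_parameters(),
                         t_end = 100) {
  sc <- build_scenario(scenario, run, params = params, t_end = t_end)
  simulate_reactor(sc$config, sc$initial, sc$registry, sc$params)
}

#' Continuous food-waste digestion under trace-metal starvation
#'
#' A bench-scale CSTR digesting food waste with no trace-metal dosing:
#' 3 L working volume with 1 L headspace (4 L total), 37 degrees C, organic
#' loading rate 1.45 gVS/L/d at a 50-day hydraulic retention time, run for
#' 120 days. Influent COD follows the substrate characterisation
#' (TS 28.1%, VS 95.5% of TS, total COD 450 mg per g wet weight, so about
#' 1.68 gCOD/gVS); sulfur and phosphorus contents of the feed are 6e-7 and
#' 6e-8 mol/gCOD; influent and initial EDTA are zero. Feed trace-metal
#' release and the dose-response optima are the starvation-case
#' calibration (see the package vignette).
#'
#' @param params base parameter set; the starvation-case overrides are
#'   applied on top
#' @param t_end horizon, days
#' @return list with `config`, `initial`, `params`, `registry`, and the
#'   organic loading rate `olr_gvs` (gVS/L/d) used for yield reporting
#' @export
build_continuous_case <- function(params = default_parameters(),
                                  t_end = 120, spin_up = 150) {
  ts_frac <- 0.281; vs_of_ts <- 0.955
  cod_per_g <- 0.450                       # gCOD per g wet weight
  cod_per_vs <- cod_per_g / (ts_frac * vs_of_ts)  # ~1.68 gCOD/gVS
  olr <- 1.45                              # gVS/L/d
  hrt <- 50                                # d
  V_liq <- 3; V_gas <- 1
  q <- V_liq / hrt

  # feed characterisation: protein share from TKN (3.77% of TS, as
  # protein-N at 0.007 mol N/gCOD protein), remaining degradable COD
  # split 75/25 carbohydrate/lipid; feed nitrogen rides in the protein
  n_per_gcod <- 0.0377 / 14 / cod_per_vs * (1 / vs_of_ts)
  f_pr <- n_per_gcod / 0.007
  f_sI <- 0.10; f_xI <- 0.10   # food waste is highly degradable
  f_ch <- 0.75 * (1 - f_sI - f_xI - f_pr)
  f_li <- 0.25 * (1 - f_sI - f_xI - f_pr)

  params <- modify_parameters(params, list(
    biochem = list(
      f_sI_xc = f_sI, f_xI_xc = f_xI, f_pr_xc = f_pr, f_ch_xc = f_ch,
      f_li_xc = f_li,
      N_xc = n_per_gcod + 1e-4, N_I = 1e-4 / (f_sI + f_xI),
      release = c(S = 6e-7, P = 6e-8, Fe = 2e-8, Ni = 2e-9, Co = 2e-10,
                  Ca = 0, Mg = 0)
    ),
    inhibition = starvation_inhibition_table()
  ))
  registry <- build_default_registry(params)

  influent <- state_template(registry)
  influent["X_c"] <- olr * cod_per_vs * hrt   # gCOD/L of feed
  influent["S_cat"] <- 0.02                   # feed alkalinity counter-ion

  config <- reactor_config(V_liq = V_liq, V_gas = V_gas, temperature = 37,
                           mode = "continuous", q_in = q, q_out = q,
                           influent = influent, t_end = t_end)

  # start-up per the comparison protocol: the reactor is run to (near)
  # steady state on the same loading with trace metals supplemented, and
  # the starvation simulation departs from that state with a TE-free feed
  seed <- state_template(registry)
  seed["X_c"] <- 2
  seed[biomass_ids] <- 1
  seed["S_nh4"] <- 0.1
  seed["S_hco3"] <- 0.1
  seed["S_po4"] <- 0.002
  seed["S_hs"] <- 5e-4
  seed["S_fe"] <- 1e-4; seed["S_ni"] <- 1e-5; seed["S_co"] <- 1e-6
  seed <- initialise_sites_and_charge(seed, registry, params)
  initial <- seed
  if (spin_up > 0) {
    dosed <- influent
    dosed["S_fe"] <- 1e-4; dosed["S_ni"] <- 1e-5; dosed["S_co"] <- 1e-6
    cfg_spin <- reactor_config(V_liq = V_liq, V_gas = V_gas,
                               temperature = 37, mode = "continuous",
                               q_in = q, q_out = q, influent = dosed,
                               t_end = spin_up, output_dt = 5)
    # supplemented operation runs at the dose-response optimum: the factor
    # is held flat during start-up, and the starvation optima are then
    # pinned to the start-up steady state's bioavailable levels
    params_spin <- params
    params_spin$inhibition <- flat_inhibition_table()
    spin <- simulate_reactor(cfg_spin, seed, registry, params_spin)
    initial <- spin$states[nrow(spin$states), ]
    x_ss <- c(Fe = initial[["S_fe"]] + initial[["S_feedta"]],
              Ni = initial[["S_ni"]] + initial[["S_niedta"]],
              Co = initial[["S_co"]] + initial[["S_coedta"]])
    # optimum pinned at the supplemented steady state's level, so the
    # factor sits on its plateau at starvation onset and the progressive
    # depletion of the metal inventory crosses into limitation after
    # roughly two retention times
    params$inhibition <- dose_response_table(pmax(1.2 * x_ss, 1e-12),
                                             breadth = 2)
  }

  list(config = config, initial = initial, params = params,
       registry = registry, olr_gvs = olr, cod_per_vs = cod_per_vs)
}

# dose-response switched off (factor identically ~1 over the physical
# concentration range)
flat_inhibition_table <- function() {
  tibble::tibble(metal = c("Fe", "Ni", "Co"), a1 = 0, a2 = 1, b1 = 0, b2 = 1)
}

# Dose-response optima for the starvation comparison: a continuous
# digester holds its bioavailable metals orders of magnitude below batch
# dosing levels (the inert surface pool buffers them), so the optima are
# recalibrated near the TE-replete steady-state levels and the response is
# kept narrow so that progressive washout of the metal inventory
# translates into failure on the experiment's ~100-day horizon.
starvation_inhibition_table <- function() {
  dose_response_table(c(Fe = 1e-8, Ni = 1e-9, Co = 1e-10), breadth = 2)
}

#' Run the continuous starvation case
#'
#' @inheritParams build_continuous_case
#' @return an `ad_trajectory` with the loading rate attached as
#'   `attr(, "olr_gvs")`
#' @export
run_continuous_case <- function(params = default_parameters(), t_end = 120) {
  cc <- build_continuous_case(params = params, t_end = t_end)
  traj <- simulate_reactor(cc$config, cc$initial, cc$registry, cc$params)
  attr(traj, "olr_gvs") <- cc$olr_gvs
  traj
}

#' Specific methane yield time series
#'
#' Daily methane production (litres of CH4 at reactor temperature and
#' atmospheric pressure) per gram of volatile solids fed, computed from
#' the cumulative liquid-to-gas CH4 transfer.
#'
#' @param traj an `ad_trajectory` from a continuous run
#' @param olr_gvs organic loading rate, gVS/L/d; taken from the trajectory
#'   attribute when missing
#' @return tibble: `time`, `yield_L_per_gVS`
#' @export
specific_methane_yield <- function(traj, olr_gvs = NULL) {
  olr_gvs <- olr_gvs %||% attr(traj, "olr_gvs")
  if (is.null(olr_gvs)) stop("supply olr_gvs", call. = FALSE)
  cm <- cumulative_methane(traj)
  dt <- diff(cm$time)
  rate_L <- diff(cm$ch4_L) / dt            # L CH4/d (whole reactor)
  fed <- olr_gvs * traj$config$V_liq       # gVS/d
  tibble::tibble(time = cm$time[-1], yield_L_per_gVS = rate_L / fed)
}
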