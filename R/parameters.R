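#' Default model parameter set
#'
#' Assembles the full parameter set of the simulator: ADM1 biochemical
#' constants (mesophilic benchmark values at 35 degrees C), the trace-metal
#' dose-response constants, acid-base dissociation constants and kinetic
#' interconversion rates, gas-transfer constants, mineral solubility products
#' and precipitation/dissolution rate constants, metal-ligand stability
#' constants, and the binding-site/sorption constants.
#'
#' Units follow ADM1 convention: organic matter and biomass in gCOD/L,
#' inorganic species and metals in mol/L (M), time in days. Binding-site
#' densities are mol sites per gram dry adsorbent.
#'
#' @param overrides optional named list; entries replace the corresponding
#'   top-level sections or, when a section entry is itself a named list,
#'   individual values inside a section.
#' @return an object of class `ad_parameters` (a named list of sections:
#'   `biochem`, `inhibition`, `acid_base`, `gas`, `minerals`, `complexes`,
#'   `sorption`, `phys`).
#' @export
default_parameters <- function(overrides = NULL) {
  biochem <- list(
    # composite disintegration fractions (sum to 1); the soluble +
    # particulate inert share characterises the feedstock
    f_sI_xc = 0.15, f_xI_xc = 0.2, f_ch_xc = 0.205, f_pr_xc = 0.185,
    f_li_xc = 0.26,
    # nitrogen contents, mol N per gCOD
    N_xc = 0.0376 / 14, N_I = 0.06 / 14, N_aa = 0.007, N_bac = 0.08 / 14,
    # carbon contents, mol C per gCOD
    C_xc = 0.02786, C_sI = 0.03, C_ch = 0.0313, C_pr = 0.03, C_li = 0.022,
    C_xI = 0.03, C_su = 0.0313, C_aa = 0.03, C_fa = 0.0217, C_va = 0.024,
    C_bu = 0.025, C_pro = 0.0268, C_ac = 0.0313, C_bac = 0.0313, C_ch4 = 0.0156,
    # first-order extracellular steps, 1/d; disintegration of the
    # composite is the rate-limiting step for complex feedstocks
    k_dis = 0.25, k_hyd_ch = 10, k_hyd_pr = 10, k_hyd_li = 10,
    # Monod uptake kinetics (k_m 1/d, K_S gCOD/L) and yields (gCOD/gCOD)
    k_m_su = 30, K_S_su = 0.5, Y_su = 0.10,
    f_h2_su = 0.19, f_bu_su = 0.13, f_pro_su = 0.27, f_ac_su = 0.41,
    k_m_aa = 50, K_S_aa = 0.3, Y_aa = 0.08,
    f_h2_aa = 0.06, f_va_aa = 0.23, f_bu_aa = 0.26, f_pro_aa = 0.05, f_ac_aa = 0.40,
    k_m_fa = 6, K_S_fa = 0.4, Y_fa = 0.06, K_I_h2_fa = 5e-6,
    k_m_c4 = 20, K_S_c4 = 0.2, Y_c4 = 0.06, K_I_h2_c4 = 1e-5,
    k_m_pro = 13, K_S_pro = 0.1, Y_pro = 0.04, K_I_h2_pro = 3.5e-6,
    k_m_ac = 8, K_S_ac = 0.15, Y_ac = 0.05, K_I_nh3 = 0.0018,
    k_m_h2 = 35, K_S_h2 = 7e-6, Y_h2 = 0.06,
    k_dec = 0.02,
    K_S_IN = 1e-4,
    # pH inhibition (lower-limit Hill form); the acetoclastic band admits
    # the moderately acidic optimum of Methanosarcina-dominated digesters
    pH_UL_aa = 5.5, pH_LL_aa = 4, pH_UL_ac = 6.5, pH_LL_ac = 5.0,
    pH_UL_h2 = 6, pH_LL_h2 = 5,
    # element release on disintegration, mol per gCOD of composite;
    # zero by default: batch scenarios supply S, P and metals as initial
    # conditions. The continuous preset overrides these.
    release = c(S = 0, P = 0, Fe = 0, Ni = 0, Co = 0, Ca = 0, Mg = 0),
    # metal bio-uptake tied to acetate + hydrogen uptake, mol per gCOD consumed
    uptake = c(Fe = 5e-7, Ni = 5e-8, Co = 5e-9),
    # half-saturation for uptake availability limitation, M
    K_uptake = 1e-8
  )

  # dose-response constants per metal: I(x) = (a1*x + a2)/(x^2 + b1*x + b2)
  # with x = free + EDTA-complexed metal. Defaults give I(x_opt) = 1 at the
  # optimum x_opt (a1 = 2*x_opt, b2 = x_opt^2) and I -> 0 at both extremes.
  # methanogenesis is near-insensitive to Fe dose over a wide band, very
  # sensitive to Ni, mildly sensitive to Co; plateau widths encode that
  x_opt <- c(Fe = 1e-4, Ni = 1e-5, Co = 1e-7)
  inhibition <- dose_response_table(x_opt, breadth = c(300, 15, 50))

  acid_base <- tibble::tibble(
    acid = c("S_hva", "S_hbu", "S_hpro", "S_hac",
             "S_co2", "S_hco3", "S_nh4",
             "S_h3po4", "S_h2po4", "S_hpo4",
             "S_h2s", "S_hs", "S_hso4",
             "S_h2edta", "S_hedta"),
    base = c("S_va", "S_bu", "S_pro", "S_ac",
             "S_hco3", "S_co3", "S_nh3",
             "S_h2po4", "S_hpo4", "S_po4",
             "S_hs", "S_s2", "S_so4",
             "S_hedta", "S_edta"),
    pKa = c(4.86, 4.82, 4.88, 4.76,
            6.31, 10.33, 8.95,
            2.15, 7.20, 12.35,
            6.99, 13.90, 1.99,
            6.16, 10.26),
    k_AB = 1e5
  )

  gas <- list(
    kLa = 200,                      # 1/d
    K_H = c(h2 = 7.38e-4, ch4 = 1.16e-3, co2 = 2.71e-2, h2s = 8.9e-2), # M/bar
    k_p = 200,                      # gas outflow coefficient, L/(bar d)
    P_atm = 1.013,                  # bar
    p_h2o = 0.0557                  # bar, water vapour at 35 C
  )

  minerals <- tibble::tibble(
    mineral = c("X_FeS", "X_NiS", "X_CoS",
                "X_FeCO3", "X_NiCO3", "X_CoCO3", "X_CaCO3", "X_MgCO3",
                "X_Fe3PO4_2", "X_Ca3PO4_2", "X_Mg3PO4_2",
                "X_MgNH4PO4", "X_CaHPO4"),
    log10_Ksp = c(-18.1, -19.4, -21.3,
                  -10.89, -6.87, -9.98, -8.48, -8.03,
                  -36.0, -28.92, -23.28,
                  -13.26, -6.90),
    k_prec = c(1e-5, 1e-6, 1e-7,
               1e-5, 1e-6, 1e-7, 1e-3, 1e-3,
               1e-6, 1e-4, 1e-4,
               1e-4, 1e-4),
    k_dissol = 1,
    ions = list(
      c(S_fe = 1, S_s2 = 1), c(S_ni = 1, S_s2 = 1), c(S_co = 1, S_s2 = 1),
      c(S_fe = 1, S_co3 = 1), c(S_ni = 1, S_co3 = 1), c(S_co = 1, S_co3 = 1),
      c(S_ca = 1, S_co3 = 1), c(S_mg = 1, S_co3 = 1),
      c(S_fe = 3, S_po4 = 2), c(S_ca = 3, S_po4 = 2), c(S_mg = 3, S_po4 = 2),
      c(S_mg = 1, S_nh4 = 1, S_po4 = 1), c(S_ca = 1, S_hpo4 = 1)
    )
  )

  complexes <- tibble::tibble(
    complex = c("S_feedta", "S_niedta", "S_coedta", "S_caedta", "S_mgedta",
                "S_feac", "S_niac", "S_coac",
                "S_fepro", "S_nipro", "S_copro",
                "S_febu", "S_nibu", "S_cobu",
                "S_niva"),
    metal = c("S_fe", "S_ni", "S_co", "S_ca", "S_mg",
              "S_fe", "S_ni", "S_co",
              "S_fe", "S_ni", "S_co",
              "S_fe", "S_ni", "S_co",
              "S_ni"),
    # the EDTA ligand is the mono-protonated anion HEDTA3-, the dominant
    # uncomplexed form across digester pH; its stability constants are
    # operational values on that scale, preserving the binding order
    # Ni > Co > Fe > Ca > Mg on which the metal partition depends
    ligand = c(rep("S_hedta", 5),
               rep("S_ac", 3), rep("S_pro", 3), rep("S_bu", 3), "S_va"),
    log10_K = c(7.1, 9.0, 8.3, 3.6, 2.5,
                1.4, 1.1, 1.0,
                1.2, 0.9, 0.8,
                1.0, 0.7, 0.5,
                0.6),
    k1 = NA_real_                 # filled below
  )
  # forward rate 1e8 1/(M d) unless the implied dissociation rate k1/K
  # would fall below 1/d: complexes must release ligand on ~day timescales
  # or the shared EDTA pool is kinetically frozen on whichever metal binds
  # it first and never reaches the K-ordered partition
  complexes$k1 <- pmax(1e8, 10^complexes$log10_K)

  sorption <- list(
    B_delta = 2e-3,   # mol sites / g dry biomass
    I_delta = 2e-3,   # mol sites / g inert
    P_delta = 2e-5,   # mol sites / g FeS
    K_a_d = 1,        # dimensionless saturation multiplier on both rates
    cod_to_dw_biomass = 1 / 1.42,  # g dry weight per gCOD (C5H7O2N)
    cod_to_dw_inert = 1,           # g per gCOD
    M_FeS = 87.9,                  # g/mol
    pairs = sorption_pair_table()
  )

  phys <- list(
    Kw = 1e-14,       # ion product of water
    R = 0.08314       # bar L / (mol K)
  )

  p <- structure(
    list(biochem = biochem, inhibition = inhibition, acid_base = acid_base,
         gas = gas, minerals = minerals, complexes = complexes,
         sorption = sorption, phys = phys),
    class = "ad_parameters"
  )
  if (!is.null(overrides)) p <- modify_parameters(p, overrides)
  p
}

# Per surface-class x metal sorption rate constants. k_des (1/d) is common;
# k_ads (1/(M d)) sets the pair equilibrium constant K = k_ads/k_des. Values
# give K ~ 1e4-1e5 1/M for the trace metals and weaker binding for the
# alkali-earth competitors.
sorption_pair_table <- function() {
  k_des <- 10
  tibble::tibble(
    surface = c(rep("biomass", 5), rep("inert", 5), rep("fes", 2)),
    metal = c("Fe", "Ni", "Co", "Ca", "Mg",
              "Fe", "Ni", "Co", "Ca", "Mg",
              "Ni", "Co"),
    k_ads = c(5e6, 3e5, 3e5, 3e3, 3e3,
              5e6, 3e5, 3e5, 3e3, 3e3,
              1e5, 1e5),
    k_des = k_des
  )
}

#' Modify a parameter set
#'
#' Deep-merges a named list of overrides into an `ad_parameters` object.
#' Top-level names address sections; list values merge element-wise into the
#' section, any other value replaces the section entry outright.
#'
#' @param params an `ad_parameters` object
#' @param overrides named list of replacements
#' @return the modified `ad_parameters` object
#' @export
modify_parameters <- function(params, overrides) {
  stopifnot(inherits(params, "ad_parameters"), is.list(overrides))
  for (section in names(overrides)) {
    if (!section %in% names(params)) {
      stop("unknown parameter section: ", section, call. = FALSE)
    }
    value <- overrides[[section]]
    if (is.list(value) && !is.data.frame(value)) {
      for (nm in names(value)) params[[section]][[nm]] <- value[[nm]]
    } else {
      params[[section]] <- value
    }
  }
  params
}

#' @export
print.ad_parameters <- function(x, ...) {
  cat("<ad_parameters>\n")
  cat("  sections:", paste(names(x), collapse = ", "), "\n")
  cat("  minerals:", nrow(x$minerals), " complexes:", nrow(x$complexes),
      " sorption pairs:", nrow(x$sorption$pairs), "\n")
  invisible(x)
}

#' Write a parameter set to a YAML file
#'
#' @param params an `ad_parameters` object
#' @param path file path to write
#' @return `path`, invisibly
#' @export
write_parameters <- function(params, path) {
  ser <- serialize_node(unclass(params))
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

serialize_node <- function(x) {
  if (is.data.frame(x)) {
    rows <- lapply(seq_len(nrow(x)), function(i) {
      row <- lapply(x, function(col) col[[i]])
      lapply(row, serialize_node)
    })
    list(.table = rows)
  } else if (is.list(x)) {
    lapply(x, serialize_node)
  } else if (is.numeric(x) && !is.null(names(x))) {
    c(list(.named = TRUE), as.list(x))
  } else x
}

deserialize_node <- function(x) {
  if (is.list(x) && !is.null(names(x)) && identical(names(x)[1], ".table")) {
    rows <- lapply(x$.table, deserialize_node)
    cols <- names(rows[[1]])
    out <- lapply(cols, function(cn) {
      vals <- lapply(rows, `[[`, cn)
      if (all(vapply(vals, function(v) is.atomic(v) && length(v) == 1 &&
                       is.null(names(v)), TRUE))) {
        unlist(vals)
      } else vals
    })
    names(out) <- cols
    tibble::as_tibble(out)
  } else if (is.list(x) && !is.null(names(x)) && identical(names(x)[1], ".named")) {
    unlist(x[-1])
  } else if (is.list(x)) {
    lapply(x, deserialize_node)
  } else x
}

#' Read a parameter set from a YAML file written by [write_parameters()]
#'
#' @param path file path
#' @return an `ad_parameters` object
#' @export
read_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  structure(deserialize_node(raw), class = "ad_parameters")
}
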