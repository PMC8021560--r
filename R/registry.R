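#' Build the default component and reaction registry
#'
#' Constructs the catalogue of every dynamic quantity tracked by the
#' simulator (soluble, particulate, precipitate, gas and binding-site
#' components) and every reaction with its stoichiometry: 19 ADM1
#' biochemical processes plus trace-metal uptake and decay-coupled site
#' turnover, 15 kinetic acid-base pairs, 15 metal-ligand complexation
#' reactions, 13 mineral precipitation/dissolution pairs, 42 reversible
#' sorption/desorption pairs (7 biomass species x 5 metals, inert x 5
#' metals, FeS x Ni/Co) and 4 liquid-gas transfer reactions.
#'
#' Stoichiometric coefficients that depend on parameters (disintegration
#' fractions, binding-site densities, element release and uptake
#' coefficients) are taken from `params`, so element conservation holds
#' reaction by reaction in the returned registry.
#'
#' @param params an `ad_parameters` object; defaults to [default_parameters()]
#' @return an object of class `ad_registry`: a list with `components`
#'   (tibble), `reactions` (tibble with a `stoichiometry` list-column) and
#'   `index` (named integer positions into the state vector)
#' @export
build_default_registry <- function(params = default_parameters()) {
  components <- build_components(params)
  reactions <- build_reactions(params, components)

  index <- seq_len(nrow(components))
  names(index) <- components$id

  reg <- structure(
    list(components = components, reactions = reactions, index = index),
    class = "ad_registry"
  )
  validate_registry(reg)
  reg
}

metal_names <- c("Fe", "Ni", "Co", "Ca", "Mg")
metal_state <- c(Fe = "S_fe", Ni = "S_ni", Co = "S_co", Ca = "S_ca", Mg = "S_mg")
biomass_ids <- c("X_su", "X_aa", "X_fa", "X_c4", "X_pro", "X_ac", "X_h2")

build_components <- function(params) {
  rel <- params$biochem$release
  rows <- list()
  add <- function(id, phase, unit, charge = 0, mol_per_unit = 0,
                  fe = 0, ni = 0, co = 0, ca = 0, mg = 0, s = 0, p = 0,
                  edta = 0, cod = 0, adsorbent = NA_character_,
                  site_metal = NA_character_) {
    if (cod == 0 && unit == "gCOD_per_L") cod <- 1
    rows[[length(rows) + 1]] <<- tibble::tibble(
      id = id, phase = phase, unit = unit, charge = charge,
      mol_per_unit = mol_per_unit, fe = fe, ni = ni, co = co, ca = ca,
      mg = mg, s = s, p = p, edta = edta, cod = cod, adsorbent = adsorbent,
      site_metal = site_metal
    )
  }

  # --- soluble organics, gCOD/L; VFA acid/base forms tracked separately.
  # mol_per_unit converts gCOD to mol for the charge balance.
  add("S_su", "soluble", "gCOD_per_L")
  add("S_aa", "soluble", "gCOD_per_L")
  add("S_fa", "soluble", "gCOD_per_L")
  add("S_hva", "soluble", "gCOD_per_L")
  add("S_va", "soluble", "gCOD_per_L", charge = -1, mol_per_unit = 1 / 208)
  add("S_hbu", "soluble", "gCOD_per_L")
  add("S_bu", "soluble", "gCOD_per_L", charge = -1, mol_per_unit = 1 / 160)
  add("S_hpro", "soluble", "gCOD_per_L")
  add("S_pro", "soluble", "gCOD_per_L", charge = -1, mol_per_unit = 1 / 112)
  add("S_hac", "soluble", "gCOD_per_L")
  add("S_ac", "soluble", "gCOD_per_L", charge = -1, mol_per_unit = 1 / 64)
  add("S_h2", "soluble", "gCOD_per_L")
  add("S_ch4", "soluble", "gCOD_per_L")
  add("S_I", "soluble", "gCOD_per_L")

  # --- inorganic solubles, M
  add("S_co2", "soluble", "M", 0, 1)
  add("S_hco3", "soluble", "M", -1, 1)
  add("S_co3", "soluble", "M", -2, 1)
  add("S_nh4", "soluble", "M", +1, 1)
  add("S_nh3", "soluble", "M", 0, 1)
  add("S_h3po4", "soluble", "M", 0, 1, p = 1)
  add("S_h2po4", "soluble", "M", -1, 1, p = 1)
  add("S_hpo4", "soluble", "M", -2, 1, p = 1)
  add("S_po4", "soluble", "M", -3, 1, p = 1)
  add("S_h2s", "soluble", "M", 0, 1, s = 1)
  add("S_hs", "soluble", "M", -1, 1, s = 1)
  add("S_s2", "soluble", "M", -2, 1, s = 1)
  add("S_hso4", "soluble", "M", -1, 1, s = 1)
  add("S_so4", "soluble", "M", -2, 1, s = 1)
  add("S_h2edta", "soluble", "M", -2, 1, edta = 1)
  add("S_hedta", "soluble", "M", -3, 1, edta = 1)
  add("S_edta", "soluble", "M", -4, 1, edta = 1)
  add("S_fe", "soluble", "M", +2, 1, fe = 1)
  add("S_ni", "soluble", "M", +2, 1, ni = 1)
  add("S_co", "soluble", "M", +2, 1, co = 1)
  add("S_ca", "soluble", "M", +2, 1, ca = 1)
  add("S_mg", "soluble", "M", +2, 1, mg = 1)
  add("S_cat", "soluble", "M", +1, 1)   # inert cation (e.g. Na+)
  add("S_an", "soluble", "M", -1, 1)    # inert anion (e.g. Cl-)

  # --- metal-ligand complexes, M
  add("S_feedta", "soluble", "M", -2, 1, fe = 1, edta = 1)
  add("S_niedta", "soluble", "M", -2, 1, ni = 1, edta = 1)
  add("S_coedta", "soluble", "M", -2, 1, co = 1, edta = 1)
  add("S_caedta", "soluble", "M", -2, 1, ca = 1, edta = 1)
  add("S_mgedta", "soluble", "M", -2, 1, mg = 1, edta = 1)
  add("S_feac", "soluble", "M", +1, 1, cod = 64, fe = 1)
  add("S_niac", "soluble", "M", +1, 1, cod = 64, ni = 1)
  add("S_coac", "soluble", "M", +1, 1, cod = 64, co = 1)
  add("S_fepro", "soluble", "M", +1, 1, cod = 112, fe = 1)
  add("S_nipro", "soluble", "M", +1, 1, cod = 112, ni = 1)
  add("S_copro", "soluble", "M", +1, 1, cod = 112, co = 1)
  add("S_febu", "soluble", "M", +1, 1, cod = 160, fe = 1)
  add("S_nibu", "soluble", "M", +1, 1, cod = 160, ni = 1)
  add("S_cobu", "soluble", "M", +1, 1, cod = 160, co = 1)
  add("S_niva", "soluble", "M", +1, 1, cod = 208, ni = 1)

  # --- particulates, gCOD/L; the composite carries the element release
  # coefficients as content so disintegration conserves elements.
  add("X_c", "particulate", "gCOD_per_L",
      fe = rel[["Fe"]], ni = rel[["Ni"]], co = rel[["Co"]],
      ca = rel[["Ca"]], mg = rel[["Mg"]], s = rel[["S"]], p = rel[["P"]])
  # decayed-biomass composite: same degradation fractions as the feed
  # composite but carries no element release (biomass metals are tracked
  # in the bio-uptake pools and on binding sites)
  add("X_c_dec", "particulate", "gCOD_per_L")
  add("X_ch", "particulate", "gCOD_per_L")
  add("X_pr", "particulate", "gCOD_per_L")
  add("X_li", "particulate", "gCOD_per_L")
  for (b in biomass_ids) add(b, "particulate", "gCOD_per_L")
  add("X_I", "particulate", "gCOD_per_L")

  # --- intracellular (bio-uptaken) metal pools, mol/L
  add("X_fe_bio", "particulate", "M", fe = 1)
  add("X_ni_bio", "particulate", "M", ni = 1)
  add("X_co_bio", "particulate", "M", co = 1)

  # --- mineral precipitates, mol/L
  add("X_FeS", "precipitate", "M", fe = 1, s = 1)
  add("X_NiS", "precipitate", "M", ni = 1, s = 1)
  add("X_CoS", "precipitate", "M", co = 1, s = 1)
  add("X_FeCO3", "precipitate", "M", fe = 1)
  add("X_NiCO3", "precipitate", "M", ni = 1)
  add("X_CoCO3", "precipitate", "M", co = 1)
  add("X_CaCO3", "precipitate", "M", ca = 1)
  add("X_MgCO3", "precipitate", "M", mg = 1)
  add("X_Fe3PO4_2", "precipitate", "M", fe = 3, p = 2)
  add("X_Ca3PO4_2", "precipitate", "M", ca = 3, p = 2)
  add("X_Mg3PO4_2", "precipitate", "M", mg = 3, p = 2)
  add("X_MgNH4PO4", "precipitate", "M", mg = 1, p = 1)
  add("X_CaHPO4", "precipitate", "M", ca = 1, p = 1)

  # --- headspace gases, mol/L gas phase
  add("S_gas_h2", "gas", "M", cod = 16)
  add("S_gas_ch4", "gas", "M", cod = 64)
  add("S_gas_co2", "gas", "M")
  add("S_gas_h2s", "gas", "M", s = 1)

  # --- binding sites, mol sites/L
  for (ads in c(biomass_ids, "X_I", "X_FeS")) {
    add(paste0("FB_", sub("^X_", "X", ads)), "free_site", "mol_per_L_sites",
        adsorbent = ads)
  }
  occ_metals <- function(ads) if (ads == "X_FeS") c("Ni", "Co") else metal_names
  for (ads in c(biomass_ids, "X_I", "X_FeS")) {
    for (m in occ_metals(ads)) {
      add(paste0("OB_", sub("^X_", "X", ads), "_", m),
          "occupied_site", "mol_per_L_sites",
          fe = as.numeric(m == "Fe"), ni = as.numeric(m == "Ni"),
          co = as.numeric(m == "Co"), ca = as.numeric(m == "Ca"),
          mg = as.numeric(m == "Mg"),
          adsorbent = ads, site_metal = m)
    }
  }

  dplyr::bind_rows(rows)
}

free_site_id <- function(ads) paste0("FB_", sub("^X_", "X", ads))
occupied_site_id <- function(ads, metal) {
  paste0("OB_", sub("^X_", "X", ads), "_", metal)
}

build_reactions <- function(params, components) {
  b <- params$biochem
  srt <- params$sorption
  rows <- list()
  add <- function(id, family, stoich, rate_ref = id) {
    stoich <- stoich[stoich != 0]
    rows[[length(rows) + 1]] <<- tibble::tibble(
      id = id, family = family, rate_ref = rate_ref,
      stoichiometry = list(stoich)
    )
  }

  rel <- b$release
  # disintegration: composite -> fractions + element release + inert sites
  dis <- c(
    X_c = -1, S_I = b$f_sI_xc, X_ch = b$f_ch_xc, X_pr = b$f_pr_xc,
    X_li = b$f_li_xc, X_I = b$f_xI_xc,
    S_hs = rel[["S"]], S_hpo4 = rel[["P"]],
    S_fe = rel[["Fe"]], S_ni = rel[["Ni"]], S_co = rel[["Co"]],
    S_ca = rel[["Ca"]], S_mg = rel[["Mg"]],
    S_nh4 = b$N_xc - b$f_sI_xc * b$N_I - b$f_xI_xc * b$N_I - b$f_pr_xc * b$N_aa,
    S_co2 = b$C_xc - b$f_sI_xc * b$C_sI - b$f_ch_xc * b$C_ch -
      b$f_pr_xc * b$C_pr - b$f_li_xc * b$C_li - b$f_xI_xc * b$C_xI
  )
  dis[free_site_id("X_I")] <- srt$I_delta * b$f_xI_xc * srt$cod_to_dw_inert
  add("dis", "biochemical", dis)

  dis2 <- c(
    X_c_dec = -1, S_I = b$f_sI_xc, X_ch = b$f_ch_xc, X_pr = b$f_pr_xc,
    X_li = b$f_li_xc, X_I = b$f_xI_xc,
    S_nh4 = b$N_xc - b$f_sI_xc * b$N_I - b$f_xI_xc * b$N_I - b$f_pr_xc * b$N_aa,
    S_co2 = b$C_xc - b$f_sI_xc * b$C_sI - b$f_ch_xc * b$C_ch -
      b$f_pr_xc * b$C_pr - b$f_li_xc * b$C_li - b$f_xI_xc * b$C_xI
  )
  dis2[free_site_id("X_I")] <- srt$I_delta * b$f_xI_xc * srt$cod_to_dw_inert
  add("dis_dec", "biochemical", dis2)

  add("hyd_ch", "biochemical", c(X_ch = -1, S_su = 1,
                                 S_co2 = b$C_ch - b$C_su))
  add("hyd_pr", "biochemical", c(X_pr = -1, S_aa = 1))
  add("hyd_li", "biochemical", c(X_li = -1, S_fa = 0.95, S_su = 0.05,
                                 S_co2 = b$C_li - 0.95 * b$C_fa - 0.05 * b$C_su))

  # uptake of sugars
  add("upt_su", "biochemical", {
    st <- c(
      S_su = -1,
      S_bu = (1 - b$Y_su) * b$f_bu_su, S_pro = (1 - b$Y_su) * b$f_pro_su,
      S_ac = (1 - b$Y_su) * b$f_ac_su, S_h2 = (1 - b$Y_su) * b$f_h2_su,
      X_su = b$Y_su, S_nh4 = -b$Y_su * b$N_bac,
      S_co2 = b$C_su - (1 - b$Y_su) * (b$f_bu_su * b$C_bu +
        b$f_pro_su * b$C_pro + b$f_ac_su * b$C_ac) - b$Y_su * b$C_bac
    )
    st[free_site_id("X_su")] <- srt$B_delta * srt$cod_to_dw_biomass * b$Y_su
    st
  })

  add("upt_aa", "biochemical", {
    st <- c(
      S_aa = -1,
      S_va = (1 - b$Y_aa) * b$f_va_aa, S_bu = (1 - b$Y_aa) * b$f_bu_aa,
      S_pro = (1 - b$Y_aa) * b$f_pro_aa, S_ac = (1 - b$Y_aa) * b$f_ac_aa,
      S_h2 = (1 - b$Y_aa) * b$f_h2_aa,
      X_aa = b$Y_aa, S_nh4 = b$N_aa - b$Y_aa * b$N_bac,
      S_co2 = b$C_aa - (1 - b$Y_aa) * (b$f_va_aa * b$C_va + b$f_bu_aa * b$C_bu +
        b$f_pro_aa * b$C_pro + b$f_ac_aa * b$C_ac) - b$Y_aa * b$C_bac
    )
    st[free_site_id("X_aa")] <- srt$B_delta * srt$cod_to_dw_biomass * b$Y_aa
    st
  })
  add("upt_fa", "biochemical", {
    st <- c(
      S_fa = -1, S_ac = (1 - b$Y_fa) * 0.7, S_h2 = (1 - b$Y_fa) * 0.3,
      X_fa = b$Y_fa, S_nh4 = -b$Y_fa * b$N_bac,
      S_co2 = b$C_fa - (1 - b$Y_fa) * 0.7 * b$C_ac - b$Y_fa * b$C_bac
    )
    st[free_site_id("X_fa")] <- srt$B_delta * srt$cod_to_dw_biomass * b$Y_fa
    st
  })
  add("upt_va", "biochemical", {
    st <- c(
      S_va = -1, S_pro = (1 - b$Y_c4) * 0.54, S_ac = (1 - b$Y_c4) * 0.31,
      S_h2 = (1 - b$Y_c4) * 0.15,
      X_c4 = b$Y_c4, S_nh4 = -b$Y_c4 * b$N_bac,
      S_co2 = b$C_va - (1 - b$Y_c4) * (0.54 * b$C_pro + 0.31 * b$C_ac) -
        b$Y_c4 * b$C_bac
    )
    st[free_site_id("X_c4")] <- srt$B_delta * srt$cod_to_dw_biomass * b$Y_c4
    st
  })
  add("upt_bu", "biochemical", {
    st <- c(
      S_bu = -1, S_ac = (1 - b$Y_c4) * 0.8, S_h2 = (1 - b$Y_c4) * 0.2,
      X_c4 = b$Y_c4, S_nh4 = -b$Y_c4 * b$N_bac,
      S_co2 = b$C_bu - (1 - b$Y_c4) * 0.8 * b$C_ac - b$Y_c4 * b$C_bac
    )
    st[free_site_id("X_c4")] <- srt$B_delta * srt$cod_to_dw_biomass * b$Y_c4
    st
  })
  add("upt_pro", "biochemical", {
    st <- c(
      S_pro = -1, S_ac = (1 - b$Y_pro) * 0.57, S_h2 = (1 - b$Y_pro) * 0.43,
      X_pro = b$Y_pro, S_nh4 = -b$Y_pro * b$N_bac,
      S_co2 = b$C_pro - (1 - b$Y_pro) * 0.57 * b$C_ac - b$Y_pro * b$C_bac
    )
    st[free_site_id("X_pro")] <- srt$B_delta * srt$cod_to_dw_biomass * b$Y_pro
    st
  })
  add("upt_ac", "biochemical", {
    st <- c(
      S_ac = -1, S_ch4 = 1 - b$Y_ac,
      X_ac = b$Y_ac, S_nh4 = -b$Y_ac * b$N_bac,
      S_co2 = b$C_ac - (1 - b$Y_ac) * b$C_ch4 - b$Y_ac * b$C_bac
    )
    st[free_site_id("X_ac")] <- srt$B_delta * srt$cod_to_dw_biomass * b$Y_ac
    st
  })
  add("upt_h2", "biochemical", {
    st <- c(
      S_h2 = -1, S_ch4 = 1 - b$Y_h2,
      X_h2 = b$Y_h2, S_nh4 = -b$Y_h2 * b$N_bac,
      S_co2 = -(1 - b$Y_h2) * b$C_ch4 - b$Y_h2 * b$C_bac
    )
    st[free_site_id("X_h2")] <- srt$B_delta * srt$cod_to_dw_biomass * b$Y_h2
    st
  })

  # trace-metal bio-uptake, driven by acetate + hydrogen uptake rates
  add("upt_te_fe", "biochemical", c(S_fe = -1, X_fe_bio = 1))
  add("upt_te_ni", "biochemical", c(S_ni = -1, X_ni_bio = 1))
  add("upt_te_co", "biochemical", c(S_co = -1, X_co_bio = 1))

  # biomass decay to composite, with C/N rebalancing
  for (bio in biomass_ids) {
    st <- c(-1, 1,
            b$N_bac - b$N_xc,
            b$C_bac - b$C_xc)
    names(st) <- c(bio, "X_c_dec", "S_nh4", "S_co2")
    add(paste0("dec_", bio), "biochemical", st)
  }

  # decay-coupled binding-site turnover: free sites are destroyed with the
  # decaying biomass; occupied sites release their metal to solution
  for (bio in biomass_ids) {
    st <- c(-1); names(st) <- free_site_id(bio)
    add(paste0("dec_sites_", bio), "biochemical", st,
        rate_ref = paste0("dec_sites_free_", bio))
    for (m in metal_names) {
      st <- c(-1, 1)
      names(st) <- c(occupied_site_id(bio, m), metal_state[[m]])
      add(paste0("dec_sites_", bio, "_", m), "biochemical", st,
          rate_ref = paste0("dec_sites_occ_", bio, "_", m))
    }
  }

  # acid-base pairs (kinetic)
  for (i in seq_len(nrow(params$acid_base))) {
    acid <- params$acid_base$acid[i]; base <- params$acid_base$base[i]
    st <- c(-1, 1); names(st) <- c(acid, base)
    add(paste0("ab_", sub("^S_", "", acid)), "acid_base", st,
        rate_ref = paste0("ab_", i))
  }

  # complexation (net forward-reverse handled in the rate)
  vfa_gcod <- c(S_ac = 64, S_pro = 112, S_bu = 160, S_va = 208)
  for (i in seq_len(nrow(params$complexes))) {
    cx <- params$complexes[i, ]
    lig_coef <- if (cx$ligand %in% names(vfa_gcod)) -vfa_gcod[[cx$ligand]] else -1
    st <- c(1, -1, lig_coef)
    names(st) <- c(cx$complex, cx$metal, cx$ligand)
    add(paste0("cmplx_", sub("^S_", "", cx$complex)), "complexation", st,
        rate_ref = paste0("cmplx_", i))
  }

  # mineral precipitation / dissolution (stoichiometry on the dominant
  # protonation forms; see operational_mineral_table())
  op_min <- operational_mineral_table(params)
  for (i in seq_len(nrow(op_min))) {
    mn <- op_min$mineral[i]
    ions <- op_min$ions[[i]]
    st <- c(-ions, 1); names(st)[length(st)] <- mn
    if (mn == "X_FeS") {
      st[free_site_id("X_FeS")] <- srt$P_delta * srt$M_FeS
    }
    add(paste0("prec_", mn), "precipitation", st)
    st2 <- -st
    if (mn == "X_FeS") {
      # site loss on dissolution is tracked by the shedding reactions below
      st2 <- st2[names(st2) != free_site_id("X_FeS")]
    }
    add(paste0("diss_", mn), "dissolution", st2)
  }
  # FeS shrinkage sheds its sites proportionally; occupied sites release metal
  st <- c(-1); names(st) <- free_site_id("X_FeS")
  add("shed_fes_free", "dissolution", st)
  for (m in c("Ni", "Co")) {
    st <- c(-1, 1); names(st) <- c(occupied_site_id("X_FeS", m), metal_state[[m]])
    add(paste0("shed_fes_", m), "dissolution", st,
        rate_ref = paste0("shed_fes_occ_", m))
  }

  # sorption / desorption pairs
  surfaces <- list(biomass = biomass_ids, inert = "X_I", fes = "X_FeS")
  for (cls in names(surfaces)) {
    for (ads in surfaces[[cls]]) {
      mets <- if (cls == "fes") c("Ni", "Co") else metal_names
      for (m in mets) {
        st <- c(-1, -1, 1)
        names(st) <- c(metal_state[[m]], free_site_id(ads),
                       occupied_site_id(ads, m))
        add(paste0("ads_", ads, "_", m), "sorption", st)
        add(paste0("des_", ads, "_", m), "desorption", -st)
      }
    }
  }

  # liquid-gas transfer (liquid side per L liquid; the reactor scales the
  # headspace rows by V_liq/V_gas)
  add("gt_h2", "gas_transfer", c(S_h2 = -1, S_gas_h2 = 1 / 16))
  add("gt_ch4", "gas_transfer", c(S_ch4 = -1, S_gas_ch4 = 1 / 64))
  add("gt_co2", "gas_transfer", c(S_co2 = -1, S_gas_co2 = 1))
  add("gt_h2s", "gas_transfer", c(S_h2s = -1, S_gas_h2s = 1))

  dplyr::bind_rows(rows)
}

validate_registry <- function(reg) {
  comp <- reg$components
  if (anyDuplicated(comp$id)) stop("duplicate component ids", call. = FALSE)
  solidish <- comp$phase %in% c("particulate", "precipitate", "gas",
                                "free_site", "occupied_site")
  # gaseous H2S is uncharged; all non-soluble phases must be uncharged
  if (any(comp$charge[solidish] != 0)) {
    stop("non-soluble component with non-zero charge", call. = FALSE)
  }
  occ <- comp[comp$phase == "occupied_site", ]
  if (any(is.na(occ$adsorbent)) || any(is.na(occ$site_metal))) {
    stop("occupied site without adsorbent/metal", call. = FALSE)
  }
  # every stoichiometry id must exist; elements conserve per reaction
  ok <- vapply(reg$reactions$stoichiometry, function(st) {
    all(names(st) %in% comp$id)
  }, TRUE)
  if (!all(ok)) stop("reaction references unknown component", call. = FALSE)
  bad <- element_imbalance(reg)
  if (any(abs(bad) > 1e-12)) {
    stop("element conservation violated in reaction(s): ",
         paste(unique(rownames(bad)[rowSums(abs(bad) > 1e-12) > 0]),
               collapse = ", "), call. = FALSE)
  }
  invisible(reg)
}

#' Per-reaction elemental balance of a registry
#'
#' @param reg an `ad_registry`
#' @param elements which element content columns to check
#' @return matrix (reactions x elements) of signed content sums; all zero in
#'   a conservative registry
#' @export
element_imbalance <- function(reg,
                              elements = c("fe", "ni", "co", "ca", "mg",
                                           "s", "p", "edta")) {
  comp <- reg$components
  out <- t(vapply(reg$reactions$stoichiometry, function(st) {
    idx <- match(names(st), comp$id)
    vapply(elements, function(el) sum(st * comp[[el]][idx]), 0)
  }, stats::setNames(numeric(length(elements)), elements)))
  rownames(out) <- reg$reactions$id
  out
}

#' Reaction-family counts of a registry
#'
#' @param reg an `ad_registry`
#' @return named integer vector: number of sorption/desorption pairs,
#'   mineral precipitation/dissolution pairs and complexation reactions
#' @export
registry_counts <- function(reg) {
  fam <- reg$reactions$family
  prec <- sub("^prec_", "", reg$reactions$id[fam == "precipitation"])
  diss <- sub("^diss_", "", reg$reactions$id[fam == "dissolution" &
                                               grepl("^diss_", reg$reactions$id)])
  c(
    sorption_pairs = sum(fam == "sorption"),
    desorption = sum(fam == "desorption"),
    mineral_pairs = length(intersect(prec, diss)),
    complexation = sum(fam == "complexation"),
    acid_base = sum(fam == "acid_base"),
    gas_transfer = sum(fam == "gas_transfer")
  )
}

#' Zero state vector for a registry
#'
#' @param registry an `ad_registry`
#' @return named numeric vector of zeros, one entry per component
#' @export
state_template <- function(registry) {
  stats::setNames(numeric(nrow(registry$components)),
                  registry$components$id)
}

#' Look up state values by component id
#'
#' @param state named state vector (as produced by [state_template()])
#' @param ids component ids
#' @return numeric values
#' @export
state_lookup <- function(state, ids) {
  miss <- setdiff(ids, names(state))
  if (length(miss) > 0) {
    stop("unknown component id(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  state[ids]
}

#' Serialize a registry to a YAML file
#'
#' @param reg an `ad_registry`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_registry <- function(reg, path) {
  comp <- lapply(seq_len(nrow(reg$components)), function(i) {
    row <- as.list(reg$components[i, ])
    row[!vapply(row, function(v) is.na(v) || identical(v, 0), TRUE)]
  })
  rxn <- lapply(seq_len(nrow(reg$reactions)), function(i) {
    list(id = reg$reactions$id[i],
         family = reg$reactions$family[i],
         rate_ref = reg$reactions$rate_ref[i],
         stoichiometry = as.list(reg$reactions$stoichiometry[[i]]))
  })
  yaml::write_yaml(list(components = comp, reactions = rxn), path,
                   precision = 15)
  invisible(path)
}

#' Parse a registry from a YAML file written by [write_registry()]
#'
#' @param path file path
#' @return an `ad_registry`
#' @export
read_registry <- function(path) {
  raw <- yaml::read_yaml(path)
  comp <- dplyr::bind_rows(lapply(raw$components, function(row) {
    proto <- list(id = NA_character_, phase = NA_character_,
                  unit = NA_character_, charge = 0, mol_per_unit = 0,
                  fe = 0, ni = 0, co = 0, ca = 0, mg = 0, s = 0, p = 0,
                  edta = 0, cod = 0, adsorbent = NA_character_,
                  site_metal = NA_character_)
    proto[names(row)] <- row
    tibble::as_tibble(proto)
  }))
  rxn <- dplyr::bind_rows(lapply(raw$reactions, function(row) {
    tibble::tibble(id = row$id, family = row$family, rate_ref = row$rate_ref,
                   stoichiometry = list(unlist(row$stoichiometry)))
  }))
  index <- seq_len(nrow(comp)); names(index) <- comp$id
  structure(list(components = comp, reactions = rxn, index = index),
            class = "ad_registry")
}

#' @export
print.ad_registry <- function(x, ...) {
  cat("<ad_registry> ", nrow(x$components), " components, ",
      nrow(x$reactions), " reactions\n", sep = "")
  print(registry_counts(x))
  invisible(x)
}
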