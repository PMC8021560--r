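test_that("scenario presets apply the tabulated overrides", {
  s4 <- build_scenario(4, 1)
  expect_equal(unname(s4$overrides[["S_edta"]]), 1e-5)
  s2fe <- build_scenario("2fe", 8)
  expect_equal(unname(s2fe$overrides[["S_fe"]]), 3e-3)
  s1 <- build_scenario(1, 5)
  expect_equal(unname(s1$initial[["X_c"]]), 5)
  s3 <- build_scenario(3, 8)
  expect_equal(unname(s3$initial[["S_ca"]] + s3$initial[["S_caedta"]]),
               4.5e-3)
  s5 <- build_scenario("5p", 8)
  expect_equal(s5$params$sorption$P_delta, 2e-8)

  expect_error(build_scenario(1, 9), "out of range")
  expect_error(build_scenario("9x", 1), "unknown scenario")
})

test_that("the batch base state honours the common initial composition", {
  reg <- default_registry_cached()
  params <- default_parameters()
  y <- base_initial_state(reg, params)
  # metals as dosed (Fe partly complexed with EDTA at the pre-equilibrium)
  expect_equal(unname(y[["S_ni"]] + y[["S_niedta"]]), 1e-5)
  expect_equal(unname(y[["S_co"]] + y[["S_coedta"]]), 1e-7)
  expect_equal(unname(y[["S_fe"]] + y[["S_feedta"]]), 1e-4)
  expect_equal(sum(y[c("S_h2s", "S_hs", "S_s2")]), 1e-3)
  expect_equal(sum(y[c("S_co2", "S_hco3", "S_co3")]), 4e-3)
  # charge balanced at pH 7 and biomass sites pre-loaded
  expect_equal(solve_ph(y, reg, params), 7, tolerance = 1e-6)
  expect_equal(unname(y[[free_site_id("X_su")]]),
               params$sorption$B_delta / 1.42 * 0.12, tolerance = 1e-12)
  # VFAs start at zero
  expect_true(all(y[c("S_va", "S_bu", "S_pro", "S_ac")] == 0))
})

test_that("the continuous preset reflects the operating protocol", {
  cc <- build_continuous_case(spin_up = 0)
  expect_equal(cc$config$V_gas, 1)
  expect_equal(cc$config$V_liq + cc$config$V_gas, 4)
  expect_equal(cc$config$temperature, 37)
  expect_equal(cc$olr_gvs, 1.45)
  expect_equal(cc$config$q_in, cc$config$V_liq / 50)  # 50-day HRT
  # starvation: no metal and no EDTA in the feed
  infl <- cc$config$influent
  expect_true(all(infl[c("S_fe", "S_ni", "S_co", "S_edta", "S_hedta")] == 0))
  # feed carbon ~1.68 gCOD per gVS at OLR 1.45 and HRT 50
  expect_equal(unname(infl[["X_c"]]), 1.45 * 50 * 0.450 / (0.281 * 0.955),
               tolerance = 1e-12)
  # feed element content
  rel <- cc$params$biochem$release
  expect_equal(unname(rel[["S"]]), 6e-7)
  expect_equal(unname(rel[["P"]]), 6e-8)
})

test_that("speciation fractions classify pools and sum to 100", {
  reg <- default_registry_cached()
  # synthetic trajectory: all nickel free
  states <- matrix(0, 2, nrow(reg$components),
                   dimnames = list(NULL, reg$components$id))
  states[, "S_ni"] <- 1e-5
  traj <- structure(list(times = c(0, 1), states = states, registry = reg),
                    class = "ad_trajectory")
  sp <- speciation_fractions(traj, 1, metals = "Ni")
  expect_equal(sp$fraction[sp$pool == "free"], 100)
  expect_equal(sum(sp$fraction), 100, tolerance = 1e-9)

  # mixed pools: occupied sites, minerals, complexes
  states[, "OB_XI_Ni"] <- 1e-5          # inert-bound
  states[, "OB_XFeS_Ni"] <- 1e-5        # sorbed on FeS -> sulfide pool
  states[, "X_NiS"] <- 1e-5
  states[, "S_niedta"] <- 1e-5
  traj$states <- states
  sp <- speciation_fractions(traj, 1, metals = "Ni")
  get <- function(pool) sp$fraction[sp$pool == pool]
  expect_equal(get("free"), 20)
  expect_equal(get("inert"), 20)
  expect_equal(get("sulfide"), 40)   # mineral + FeS-sorbed
  expect_equal(get("edta"), 20)
  expect_equal(sum(sp$fraction), 100, tolerance = 1e-9)

  # absent metal reports NA
  sp0 <- speciation_fractions(traj, 1, metals = "Co")
  expect_true(all(is.na(sp0$fraction)))
  expect_error(speciation_fractions(traj, 99), "outside")
})

test_that("trace-metal dose shapes methane stimulation then toxicity", {
  # cumulative methane at the nickel optimum is at least that of strongly
  # under- and over-dosed runs (scenario-2 Ni ladder endpoints)
  opt <- cached_scenario("2ni", 5)
  low <- cached_scenario("2ni", 1)
  high <- cached_scenario("2ni", 8)
  ch4 <- function(tr) utils::tail(tr$derived$cum_ch4_M, 1)
  expect_gte(ch4(opt) * (1 + 1e-3), ch4(low))
  expect_gte(ch4(opt) * (1 + 1e-3), ch4(high))
})

test_that("methane production rises with the organic loading", {
  ch4 <- vapply(c(1, 3, 5), function(r) {
    utils::tail(cached_scenario(1, r)$derived$cum_ch4_M, 1)
  }, 0)
  expect_true(all(diff(ch4) > 0))
})

test_that("EDTA addition strips iron off surfaces and sulfide", {
  lo <- speciation_fractions(cached_scenario(4, 1))
  hi <- speciation_fractions(cached_scenario(4, 10))
  g <- function(sp, m, p) sp$fraction[sp$metal == m & sp$pool == p]
  # chelation pulls Fe out of the inert-bound pool into the complex pool
  expect_lt(g(hi, "Fe", "inert"), g(lo, "Fe", "inert"))
  expect_gt(g(hi, "Fe", "edta"), g(lo, "Fe", "edta"))
  expect_lt(g(hi, "Fe", "free"), 10)
})

test_that("inert site density controls the inert-bound iron fraction", {
  # scenario 5 (inert ladder): lower density, lower inert-bound Fe
  hi <- speciation_fractions(cached_scenario("5i", 5))   # default 2e-3
  lo <- speciation_fractions(cached_scenario("5i", 8))   # 2e-6
  g <- function(sp) sp$fraction[sp$metal == "Fe" & sp$pool == "inert"]
  expect_gt(g(hi), g(lo))
})
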