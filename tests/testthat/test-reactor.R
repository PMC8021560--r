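test_that("zero state gives zero derivatives in batch mode", {
  params <- default_parameters()
  reg <- default_registry_cached()
  config <- reactor_config(V_liq = 1, V_gas = 0.5, t_end = 1)
  out <- assemble_derivatives(0, state_template(reg), config, reg, params)
  expect_true(all(out$dstate == 0))
  expect_equal(out$q_gas, 0)
})

test_that("reaction terms conserve every metal at arbitrary states", {
  # conservation is a property of the stoichiometric matrix: with flows
  # off, the content-weighted derivative is zero whatever the rates
  params <- default_parameters()
  reg <- default_registry_cached()
  config <- reactor_config(V_liq = 1, V_gas = 1e9, t_end = 1)
  # (a huge headspace makes the gas-outflow term negligible; no metal is
  # gaseous anyway)
  set.seed(11)
  for (k in 1:5) {
    y <- state_template(reg)
    y[] <- 10^runif(length(y), -9, -2)
    out <- assemble_derivatives(0, y, config, reg, params)
    for (m in c("fe", "ni", "co", "ca", "mg", "edta")) {
      dm <- sum(out$dstate * reg$components[[m]])
      scale <- sum(abs(out$dstate) * reg$components[[m]]) + 1e-12
      expect_lt(abs(dm) / scale, 1e-10)
    }
  }
})

test_that("fast compiled core equals the reference assembly exactly", {
  sc <- build_scenario(1, 2, t_end = 1)
  ctx <- tracedigest:::compile_model(sc$registry, sc$params, sc$config)
  core <- tracedigest:::make_core(ctx)
  set.seed(3)
  for (k in 1:5) {
    y <- unname(sc$initial[sc$registry$components$id])
    y <- y * (1 + 0.5 * runif(length(y)))
    a <- core(0, y)
    b <- tracedigest:::derivative_core(0, y, ctx)
    expect_identical(a$dy, b$dy)
    expect_identical(a$rates, b$rates)
  }
  # and against the module-level reference functions
  y <- unname(sc$initial[sc$registry$components$id])
  names(y) <- sc$registry$components$id
  out <- assemble_derivatives(0, y, sc$config, sc$registry, sc$params)
  pH <- solve_ph(y, sc$registry, sc$params)
  expect_equal(out$pH, pH, tolerance = 1e-9)
  ab_ref <- acid_base_rates(y, sc$params, pH = out$pH)
  a <- unname(out$rates[paste0("ab_", sub("^S_", "",
                                          sc$params$acid_base$acid))])
  expect_lt(max(abs(a - unname(ab_ref))),
            1e-9 * max(abs(ab_ref)) + 1e-12)
  cx_ref <- complexation_rates(y, sc$params)
  a <- unname(out$rates[paste0("cmplx_", sub("^S_", "",
                                             sc$params$complexes$complex))])
  expect_lt(max(abs(a - unname(cx_ref))),
            1e-9 * max(abs(cx_ref)) + 1e-15)
  bio_ref <- biochemical_rates(y, sc$params, pH = out$pH)
  a <- unname(out$rates[names(bio_ref)])
  expect_lt(max(abs(a - unname(bio_ref))),
            1e-9 * max(abs(bio_ref)) + 1e-15)
})

test_that("t_end = 0 returns the initial state only", {
  params <- default_parameters()
  reg <- default_registry_cached()
  y <- state_template(reg); y["S_ac"] <- 1
  config <- reactor_config(V_liq = 1, V_gas = 0.5, t_end = 0)
  traj <- simulate_reactor(config, y, reg, params)
  expect_identical(traj$times, 0)
  expect_equal(unname(traj$states[1, "S_ac"]), 1)
})

test_that("a biologically inert tracer washes out as exp(-t/HRT) in a CSTR", {
  params <- default_parameters()
  reg <- default_registry_cached()
  y <- state_template(reg)
  y["S_I"] <- 1
  influent <- state_template(reg)
  config <- reactor_config(V_liq = 2, V_gas = 0.5, mode = "continuous",
                           q_in = 0.1, q_out = 0.1, influent = influent,
                           t_end = 40, output_dt = 5)
  traj <- simulate_reactor(config, y, reg, params)
  hrt <- 2 / 0.1
  expect_equal(unname(traj$states[, "S_I"]), exp(-traj$times / hrt),
               tolerance = 1e-5)
})

test_that("batch configuration rejects nonzero flow", {
  expect_error(reactor_config(V_liq = 1, V_gas = 1, mode = "batch",
                              q_in = 0.1, q_out = 0.1),
               "batch mode requires")
})

test_that("cumulative methane is monotone and matches headspace bookkeeping", {
  traj <- cached_scenario(1, 2, t_end = 40)
  cm <- cumulative_methane(traj)
  expect_true(all(diff(cm$ch4_M) >= -1e-12))
  # dual bookkeeping: transferred = headspace content + outflow
  lhs <- traj$aux[, "cum_ch4_transfer"] * traj$config$V_liq
  rhs <- traj$states[, "S_gas_ch4"] * traj$config$V_gas +
    traj$aux[, "cum_ch4_out"]
  expect_equal(lhs, rhs, tolerance = 1e-7)

  # no methanogenesis -> no methane
  params <- default_parameters()
  reg <- default_registry_cached()
  y <- state_template(reg); y["S_su"] <- 1
  config <- reactor_config(V_liq = 1, V_gas = 0.5, t_end = 5)
  tr0 <- simulate_reactor(config, y, reg, params)
  expect_equal(utils::tail(cumulative_methane(tr0)$ch4_M, 1), 0,
               tolerance = 1e-12)
})

test_that("solver tolerances do not move the 40-day methane answer", {
  sc <- build_scenario(1, 2, t_end = 40)
  t1 <- simulate_reactor(sc$config, sc$initial, sc$registry, sc$params)
  sc$config$rtol <- sc$config$rtol / 2
  sc$config$atol <- sc$config$atol / 2
  t2 <- simulate_reactor(sc$config, sc$initial, sc$registry, sc$params)
  a <- utils::tail(t1$derived$cum_ch4_M, 1)
  b <- utils::tail(t2$derived$cum_ch4_M, 1)
  expect_lt(abs(a - b) / a, 1e-3)
})

test_that("trajectory tidiers and plots work", {
  traj <- cached_scenario(1, 2, t_end = 40)
  td <- tidy(traj)
  expect_true(all(c("time", "component", "phase", "unit", "value") %in%
                    names(td)))
  expect_equal(nrow(td), length(traj$times) * ncol(traj$states))
  g <- glance(traj)
  expect_equal(nrow(g), 1)
  expect_gt(g$cum_ch4_M, 0)
  p <- ggplot2::autoplot(traj)
  expect_s3_class(p, "ggplot")
  sp <- speciation_fractions(traj)
  expect_s3_class(plot_speciation(sp), "ggplot")
})
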