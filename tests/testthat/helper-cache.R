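# Shared simulation cache: several test files interrogate the same scenario
# trajectories, so each is integrated once per test run.
.sim_cache <- new.env(parent = emptyenv())

cached_scenario <- function(scenario, run, t_end = 100) {
  key <- paste0("s", scenario, "_r", run, "_t", t_end)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- run_scenario(scenario, run, t_end = t_end)
  }
  .sim_cache[[key]]
}

cached_continuous <- function(t_end = 120) {
  key <- paste0("cont_", t_end)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- run_continuous_case(t_end = t_end)
  }
  .sim_cache[[key]]
}

default_registry_cached <- function() {
  if (is.null(.sim_cache$registry)) {
    .sim_cache$registry <- build_default_registry()
  }
  .sim_cache$registry
}

# metal inventory of a state row (mol/L) from registry content columns
metal_total <- function(states_row, registry, metal = c("fe", "ni", "co", "ca", "mg")) {
  metal <- match.arg(metal)
  cc <- registry$components[[metal]]
  sum(states_row[registry$components$id] * cc)
}
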