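#' Write trajectory tables
#'
#' Writes the trajectory as a wide delimited table (one row per stored
#' time, one column per component, plus pH/gas columns) and a tidy long
#' table (one row per time x component).
#'
#' @param traj an `ad_trajectory`
#' @param wide_path path for the wide CSV (skipped when `NULL`)
#' @param tidy_path path for the tidy CSV (skipped when `NULL`)
#' @return invisibly, the paths written
#' @export
write_trajectory <- function(traj, wide_path = NULL, tidy_path = NULL) {
  written <- character()
  if (!is.null(wide_path)) {
    wide <- cbind(data.frame(time = traj$times), as.data.frame(traj$states),
                  as.data.frame(traj$derived[, c("pH", "q_gas",
                                                 "cum_ch4_M")]))
    utils::write.csv(wide, wide_path, row.names = FALSE)
    written <- c(written, wide_path)
  }
  if (!is.null(tidy_path)) {
    utils::write.csv(tidy(traj), tidy_path, row.names = FALSE)
    written <- c(written, tidy_path)
  }
  invisible(written)
}

#' Read a wide trajectory table back into a minimal trajectory
#'
#' Reconstructs enough of an `ad_trajectory` from a wide CSV written by
#' [write_trajectory()] to run [speciation_fractions()] on it. The default
#' registry supplies the component metadata.
#'
#' @param path wide CSV path
#' @param registry an `ad_registry` matching the columns
#' @return an `ad_trajectory`-like object
#' @export
read_trajectory <- function(path, registry = build_default_registry()) {
  d <- utils::read.csv(path, check.names = FALSE)
  ids <- registry$components$id
  missing <- setdiff(ids, names(d))
  if (length(missing) > 0) {
    stop("trajectory file lacks component column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  traj <- list(times = d$time, states = as.matrix(d[, ids]),
               registry = registry,
               derived = tibble::tibble(time = d$time, pH = d$pH,
                                        q_gas = d$q_gas,
                                        cum_ch4_M = d$cum_ch4_M))
  class(traj) <- "ad_trajectory"
  traj
}

#' Command-line entry point
#'
#' Subcommands:
#' \describe{
#'   \item{`run-scenario --scenario S --run K [--out DIR]`}{simulate a
#'     preset batch scenario and write trajectory + speciation tables}
#'   \item{`run-continuous [--out DIR]`}{simulate the continuous
#'     starvation case}
#'   \item{`simulate --config FILE [--out DIR]`}{simulate from a YAML
#'     configuration (sections `reactor:` and `initial:`; optional
#'     `parameters:` path)}
#'   \item{`report --traj FILE --day D`}{speciation report from a stored
#'     wide trajectory CSV}
#' }
#'
#' @param args character vector of command-line arguments
#' @return integer exit code (0 on success), invisibly
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: tracedigest <run-scenario|run-continuous|simulate|report> [options]",
    "  run-scenario  --scenario S --run K [--out DIR]",
    "  run-continuous [--out DIR]",
    "  simulate      --config FILE [--out DIR]",
    "  report        --traj FILE --day D",
    sep = "\n")
  if (length(args) == 0 || args[1] %in% c("--help", "-h", "help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  opt <- function(flag, default = NULL) {
    j <- which(args == flag)
    if (length(j) == 1 && j < length(args)) args[j + 1] else default
  }
  res <- tryCatch({
    cmd <- args[1]
    out_dir <- opt("--out", ".")
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (cmd == "run-scenario") {
      scen <- opt("--scenario"); run <- opt("--run")
      if (is.null(scen) || is.null(run)) stop("need --scenario and --run")
      traj <- run_scenario(scen, as.integer(run))
      stem <- file.path(out_dir, paste0("scenario_", scen, "_run", run))
      write_trajectory(traj, paste0(stem, "_trajectory.csv"))
      utils::write.csv(speciation_fractions(traj),
                       paste0(stem, "_speciation.csv"), row.names = FALSE)
      message("wrote ", stem, "_{trajectory,speciation}.csv")
      0L
    } else if (cmd == "run-continuous") {
      traj <- run_continuous_case()
      stem <- file.path(out_dir, "continuous_starvation")
      write_trajectory(traj, paste0(stem, "_trajectory.csv"))
      utils::write.csv(specific_methane_yield(traj),
                       paste0(stem, "_methane_yield.csv"), row.names = FALSE)
      message("wrote ", stem, "_{trajectory,methane_yield}.csv")
      0L
    } else if (cmd == "simulate") {
      cfg_path <- opt("--config")
      if (is.null(cfg_path)) stop("need --config FILE")
      raw <- yaml::read_yaml(cfg_path)
      params <- if (!is.null(raw$parameters)) {
        read_parameters(raw$parameters)
      } else default_parameters()
      registry <- build_default_registry(params)
      rc <- raw$reactor
      influent <- NULL
      if (!is.null(rc$influent)) influent <- unlist(rc$influent)
      config <- reactor_config(
        V_liq = rc$V_liq, V_gas = rc$V_gas,
        temperature = rc$temperature %||% 35,
        mode = rc$mode %||% "batch",
        q_in = rc$q_in %||% 0, q_out = rc$q_out %||% 0,
        influent = influent, t_end = rc$t_end %||% 100,
        output_dt = rc$output_dt %||% 1)
      y <- state_template(registry)
      init <- unlist(raw$initial)
      y[names(init)] <- init
      y <- initialise_sites_and_charge(y, registry, params)
      traj <- simulate_reactor(config, y, registry, params)
      stem <- file.path(out_dir, "simulation")
      write_trajectory(traj, paste0(stem, "_trajectory.csv"))
      utils::write.csv(speciation_fractions(traj),
                       paste0(stem, "_speciation.csv"), row.names = FALSE)
      message("wrote ", stem, "_{trajectory,speciation}.csv")
      0L
    } else if (cmd == "report") {
      traj_path <- opt("--traj"); day <- opt("--day")
      if (is.null(traj_path) || is.null(day)) stop("need --traj and --day")
      traj <- read_trajectory(traj_path)
      rep <- speciation_fractions(traj, as.numeric(day))
      utils::write.csv(rep, stdout(), row.names = FALSE)
      0L
    } else {
      stop("unknown subcommand: ", cmd)
    }
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    message(usage)
    1L
  })
  invisible(res)
}
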