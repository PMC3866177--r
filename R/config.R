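# Configuration handling: a single JSON file covering initial stocks,
# behavioral parameters, intervention settings and simulation controls, plus
# CSV output writers and the run manifest.

.CONFIG_SECTIONS <- c("initial_state", "params", "intervention", "simulation")

.INTERVENTION_KEYS <- c("magnitude", "discount", "psi_a", "psi_c",
                        "ramp_horizon")

.SIMULATION_KEYS <- c("dt", "horizon", "integrator", "record_every")

#' Path to the shipped default configuration
#'
#' The file documents the package's calibrated baseline (see the methods
#' vignette for how each value was chosen) and serves as a template for user
#' configurations.
#'
#' @return Path to `default_config.json` inside the installed package.
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.json", package = "obesitydyn",
              mustWork = TRUE)
}

#' Load and validate a model configuration
#'
#' Reads a JSON configuration, fills unspecified entries from the shipped
#' defaults, rejects unknown keys, and validates every value through the
#' domain constructors, so errors name the offending key and its constraint.
#' An empty configuration (`{}`) yields the full default configuration.
#'
#' @param path Path to a JSON configuration, or `NULL` for the defaults.
#' @return A list of class `"obesity_config"` with elements `initial_state`
#'   (a [population_state()]), `params` (a [behavior_params()]),
#'   `intervention` (magnitude, discount, psi_a, psi_c, ramp_horizon) and
#'   `simulation` (a [sim_config()]).
#' @examples
#' cfg <- load_config()
#' cfg$params
#' @export
load_config <- function(path = NULL) {
  defaults <- jsonlite::read_json(default_config_path(), simplifyVector = TRUE)
  user <- if (is.null(path)) {
    list()
  } else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  }

  unknown <- setdiff(names(user), .CONFIG_SECTIONS)
  if (length(unknown)) {
    stop(sprintf("unknown config section '%s' (known: %s)", unknown[1L],
                 paste(.CONFIG_SECTIONS, collapse = ", ")), call. = FALSE)
  }
  merged <- defaults
  for (sec in names(user)) {
    known <- names(defaults[[sec]])
    bad <- setdiff(names(user[[sec]]), known)
    if (length(bad)) {
      stop(sprintf("unknown key '%s' in config section '%s' (known: %s)",
                   bad[1L], sec, paste(known, collapse = ", ")),
           call. = FALSE)
    }
    merged[[sec]][names(user[[sec]])] <- user[[sec]]
  }

  initial <- do.call(population_state, as.list(merged$initial_state))
  params <- do.call(behavior_params, as.list(merged$params))
  iv <- merged$intervention
  for (key in c("magnitude", "discount", "psi_a", "psi_c")) {
    v <- iv[[key]]
    if (!is.numeric(v) || !is.finite(v) || v < 0 || v > 1) {
      stop(sprintf("intervention key '%s' must lie in [0, 1] (got %s)",
                   key, format(v)), call. = FALSE)
    }
  }
  if (!is.numeric(iv$ramp_horizon) || iv$ramp_horizon <= 0) {
    stop("intervention key 'ramp_horizon' must be > 0", call. = FALSE)
  }
  sim <- do.call(sim_config, as.list(merged$simulation))

  structure(list(initial_state = initial, params = params,
                 intervention = iv[.INTERVENTION_KEYS], simulation = sim),
            class = "obesity_config")
}

#' @export
print.obesity_config <- function(x, ...) {
  cat("Model configuration\n")
  print(x$initial_state)
  print(x$params)
  print(x$simulation)
  cat(sprintf("  intervention: magnitude %.2g, discount %.2g, psi_a %.2g, psi_c %.2g, ramp %g wk\n",
              x$intervention$magnitude, x$intervention$discount,
              x$intervention$psi_a, x$intervention$psi_c,
              x$intervention$ramp_horizon))
  invisible(x)
}

#' Write a trajectory to tidy CSV
#'
#' Columns: `time_weeks`, the six stocks, `adult_prevalence_pct`,
#' `child_prevalence_pct`.
#'
#' @param traj An `"obesity_trajectory"`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "obesity_trajectory"))
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Write a sensitivity grid to long-format CSV
#'
#' Columns: `beta_ac`, `beta_cc`, `final_prevalence_pct` (two decimals).
#'
#' @param grid A `"sensitivity_grid"` from [run_sensitivity()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "sensitivity_grid"))
  df <- as.data.frame(grid)
  df$final_prevalence_pct <- round(df$final_prevalence_pct, 2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write sweep results (with per-scenario ranks) to CSV
#'
#' Columns: `scenario`, `alternative`, `final_prevalence_pct` (two decimals),
#' `rank` (within scenario, baseline unranked).
#'
#' @param results A `"sweep_result"` from [run_sweep()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_sweep_csv <- function(results, path) {
  stopifnot(is.data.frame(results))
  df <- data.frame(scenario = results$scenario,
                   alternative = results$alternative,
                   final_prevalence_pct =
                     round(results$final_child_prevalence_pct, 2),
                   rank = NA_integer_)
  for (sc in unique(df$scenario)) {
    ranked <- rank_alternatives(results, sc)
    idx <- match(paste(sc, ranked$alternative),
                 paste(df$scenario, df$alternative))
    df$rank[idx] <- ranked$rank
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run bit-for-bit: the full
#' configuration snapshot, the seed (when synthetic records are involved),
#' the package version, a timestamp and the paths of every emitted output.
#'
#' @param path Output JSON path.
#' @param config An `"obesity_config"` (or any serializable snapshot).
#' @param outputs Character vector of emitted output paths.
#' @param seed Seed used for synthetic records, or `NULL`.
#' @param extra Optional named list of additional entries (e.g. CLI flags).
#' @return The path, invisibly.
#' @export
write_manifest <- function(path, config, outputs, seed = NULL, extra = NULL) {
  snapshot <- list(
    initial_state = as.list(unclass(config$initial_state)),
    params = as.list(unclass(config$params)),
    intervention = config$intervention,
    simulation = unclass(config$simulation)
  )
  manifest <- list(
    tool = "obesitydyn",
    version = as.character(utils::packageVersion("obesitydyn")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = snapshot,
    outputs = as.list(outputs)
  )
  if (!is.null(extra)) manifest <- c(manifest, extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
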