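# Experiment designs: the two-way transmission-rate sensitivity grid and the
# scenario x alternative intervention sweep with ranking by final childhood
# overweight and obesity prevalence.

#' Two-way sensitivity analysis of transmission rates
#'
#' Simulates the model with no interventions for every combination of
#' adult-to-child and child-to-child transmission rates on a regular grid
#' (default: 0.0011 to 0.0019 in 0.0002 increments, 5 x 5 = 25 runs) and
#' records the final childhood overweight and obesity prevalence.
#'
#' @param base_params Baseline [behavior_params()]; `beta_ac` and `beta_cc`
#'   are overridden cell by cell.
#' @param initial Initial [population_state()].
#' @param config A [sim_config()]; the horizon defaults to 520 weeks.
#' @param lo,hi,step Grid bounds and increment for both axes (week^-1).
#' @return Object of class `"sensitivity_grid"`: a list with
#'   `beta_ac_values`, `beta_cc_values` and the matrix
#'   `final_child_prevalence` (rows = beta_ac, columns = beta_cc, percent).
#' @examples
#' \donttest{
#' grid <- run_sensitivity(config = sim_config(horizon = 104))
#' as.data.frame(grid)
#' }
#' @export
run_sensitivity <- function(base_params = behavior_params(),
                            initial = default_initial_state(),
                            config = sim_config(),
                            lo = 0.0011, hi = 0.0019, step = 0.0002) {
  if (!(lo < hi)) stop("lo must be less than hi", call. = FALSE)
  n_steps <- (hi - lo) / step
  if (abs(n_steps - round(n_steps)) > 1e-8) {
    stop("step must divide (hi - lo)", call. = FALSE)
  }
  values <- lo + step * 0:round(n_steps)
  base_params <- validate_behavior_params(base_params)

  prev <- matrix(NA_real_, nrow = length(values), ncol = length(values),
                 dimnames = list(beta_ac = format(values, digits = 4),
                                 beta_cc = format(values, digits = 4)))
  for (i in seq_along(values)) {
    for (j in seq_along(values)) {
      p <- base_params
      p["beta_ac"] <- values[i]
      p["beta_cc"] <- values[j]
      traj <- tryCatch(
        simulate_model(initial, params = p, config = config),
        error = function(e) {
          stop(sprintf("sensitivity cell (beta_ac = %g, beta_cc = %g) failed: %s",
                       values[i], values[j], conditionMessage(e)),
               call. = FALSE)
        })
      prev[i, j] <- traj$child_prevalence_pct[nrow(traj)]
    }
  }
  structure(list(beta_ac_values = values, beta_cc_values = values,
                 final_child_prevalence = prev),
            class = "sensitivity_grid")
}

#' @export
as.data.frame.sensitivity_grid <- function(x, ...) {
  grid <- expand.grid(beta_ac = x$beta_ac_values, beta_cc = x$beta_cc_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$final_prevalence_pct <- as.vector(x$final_child_prevalence)
  grid
}

#' @export
print.sensitivity_grid <- function(x, ...) {
  cat(sprintf("Two-way sensitivity grid: %d x %d runs\n",
              length(x$beta_ac_values), length(x$beta_cc_values)))
  cat(sprintf("  final childhood prevalence %.2f%% to %.2f%%\n",
              min(x$final_child_prevalence), max(x$final_child_prevalence)))
  invisible(x)
}

#' Scenario-by-alternative intervention sweep
#'
#' Runs every intervention alternative under every impact-factor scenario
#' (plus a shared no-intervention baseline, repeated once per scenario for
#' reference) and records the final childhood overweight and obesity
#' prevalence — the model's decision criterion.
#'
#' @param base_params Baseline [behavior_params()].
#' @param initial Initial [population_state()].
#' @param config A [sim_config()]; its horizon is also the intervention ramp
#'   horizon.
#' @param scenarios Data frame from [scenario_catalog()].
#' @param alternatives List from [alternative_catalog()].
#' @param magnitude Direct impact magnitude used when `alternatives` is left
#'   at its default.
#' @param discount Adult-to-child prevention discount factor.
#' @param keep_trajectories Keep each run's full trajectory in the
#'   `"trajectories"` attribute (named `scenario/alternative`).
#' @return Data frame of class `"sweep_result"` with columns `scenario`,
#'   `label`, `alternative`, `final_child_prevalence_pct`; one row per
#'   (scenario, alternative) plus one `baseline` row per scenario.
#' @examples
#' \donttest{
#' sw <- run_sweep(config = sim_config(horizon = 104))
#' rank_alternatives(sw, scenario = 6)
#' }
#' @export
run_sweep <- function(base_params = behavior_params(),
                      initial = default_initial_state(),
                      config = sim_config(),
                      scenarios = scenario_catalog(),
                      alternatives = alternative_catalog(magnitude),
                      magnitude = 0.5,
                      discount = 0.5,
                      keep_trajectories = FALSE) {
  base_params <- validate_behavior_params(base_params)
  if (!nrow(scenarios)) stop("scenario catalog is empty", call. = FALSE)
  if (!length(alternatives)) stop("alternative catalog is empty", call. = FALSE)

  baseline_traj <- simulate_model(initial, params = base_params,
                                  config = config)
  baseline_prev <- baseline_traj$child_prevalence_pct[nrow(baseline_traj)]

  rows <- list()
  trajs <- list()
  for (s in seq_len(nrow(scenarios))) {
    sc <- scenarios[s, ]
    factors <- impact_factors(psi_a = sc$psi_a, psi_c = sc$psi_c,
                              discount = discount)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = sc$scenario, label = sc$label, alternative = "baseline",
      final_child_prevalence_pct = baseline_prev)
    for (alt in alternatives) {
      sched <- intervention_schedule(base_params, alt, factors,
                                     ramp_horizon = config$horizon)
      traj <- tryCatch(
        simulate_model(initial, params = base_params, config = config,
                       schedule = sched),
        error = function(e) {
          stop(sprintf("sweep run (scenario %s, alternative %s) failed: %s",
                       sc$scenario, alt$name, conditionMessage(e)),
               call. = FALSE)
        })
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = sc$scenario, label = sc$label, alternative = alt$name,
        final_child_prevalence_pct = traj$child_prevalence_pct[nrow(traj)])
      if (keep_trajectories) {
        trajs[[paste(sc$scenario, alt$name, sep = "/")]] <- traj
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_trajectories) {
    trajs[["baseline"]] <- baseline_traj
    attr(out, "trajectories") <- trajs
  }
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Rank alternatives within a scenario
#'
#' Orders a scenario's alternatives by ascending final childhood overweight
#' and obesity prevalence (rank 1 = most effective); exact ties are broken
#' alphabetically by alternative name. The baseline row is excluded from the
#' ranking.
#'
#' @param results A `"sweep_result"` from [run_sweep()].
#' @param scenario Scenario number (1-6 with the default catalog).
#' @return Data frame with columns `rank`, `alternative`,
#'   `final_child_prevalence_pct`, best first.
#' @export
rank_alternatives <- function(results, scenario) {
  stopifnot(inherits(results, "sweep_result") || is.data.frame(results))
  sub <- results[results$scenario == scenario &
                   results$alternative != "baseline", , drop = FALSE]
  if (!nrow(sub)) {
    stop(sprintf("no results for scenario %s", scenario), call. = FALSE)
  }
  ord <- order(sub$final_child_prevalence_pct, sub$alternative)
  out <- data.frame(rank = seq_len(nrow(sub)),
                    alternative = sub$alternative[ord],
                    final_child_prevalence_pct =
                      sub$final_child_prevalence_pct[ord])
  rownames(out) <- NULL
  out
}
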