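# Transition dynamics: right-hand side of the six-compartment system,
# fixed-step integration, and prevalence summaries.
#
# Flows (all week^-1):
#   adults:   N_A -> S_A at beta_aa * N_A * (S_A + O_A)
#             S_A -> O_A at gamma_a * S_A
#             S_A -> N_A at rho_awl * S_A / p_sa
#             O_A -> S_A at eps_awl * O_A / p_oa
#   children: N_C -> S_C at [beta_cc * (S_C + O_C) + beta_ac * (S_A + O_A)] * N_C
#             S_C -> O_C at gamma_c * S_C
#             S_C -> N_C at rho_cwl * S_C / p_sc
#             O_C -> S_C at eps_cwl * O_C / p_oc
# Children never appear in the adult equations (no child-to-adult
# transmission); each age group is closed, so each group's derivatives sum
# to zero identically.

# y and p are plain numeric vectors in STATE_NAMES / PARAM_NAMES order;
# integer indexing keeps the per-step cost low.
.deriv_vec <- function(y, p) {
  infect_a <- p[1L] * y[1L] * (y[2L] + y[3L])
  prog_a   <- p[4L] * y[2L]
  rec_sa   <- p[6L] * y[2L] / p[10L]
  rec_oa   <- p[8L] * y[3L] / p[12L]

  infect_c <- (p[2L] * (y[5L] + y[6L]) + p[3L] * (y[2L] + y[3L])) * y[4L]
  prog_c   <- p[5L] * y[5L]
  rec_sc   <- p[7L] * y[5L] / p[11L]
  rec_oc   <- p[9L] * y[6L] / p[13L]

  c(rec_sa - infect_a,
    infect_a + rec_oa - prog_a - rec_sa,
    prog_a - rec_oa,
    rec_sc - infect_c,
    infect_c + rec_oc - prog_c - rec_sc,
    prog_c - rec_oc)
}

#' Time derivatives of the six stocks
#'
#' Evaluates the right-hand side of the transition system at a given state:
#' social-transmission inflows into the overweight stocks, progression from
#' overweight to obese, and weight-loss recovery flows back down. Within each
#' age group the components sum to zero (closed populations).
#'
#' @param state A [population_state()] (or named numeric vector of the six
#'   stocks).
#' @param params A [behavior_params()] vector.
#'
#' @return Named numeric vector of derivatives (week^-1), one per stock.
#' @examples
#' st <- population_state(0.3, 0.35, 0.35, 1, 0, 0)
#' state_derivatives(st, behavior_params())
#' @export
state_derivatives <- function(state, params = behavior_params()) {
  state <- validate_population_state(state)
  params <- validate_behavior_params(params)
  d <- .deriv_vec(as.numeric(state[STATE_NAMES]),
                  as.numeric(params[PARAM_NAMES]))
  names(d) <- STATE_NAMES
  d
}

#' Simulate the transmission model
#'
#' Integrates the six-compartment system with a fixed-step scheme (forward
#' Euler by default, classical Runge-Kutta optionally) over the configured
#' horizon. Parameters may vary in time through `schedule`, which is how
#' intervention ramps enter the dynamics (see [intervention_schedule()]).
#'
#' Each recorded state is checked for conservation (each age group must stay
#' within 1e-8 of summing to 1) and for stock positivity; excursions below
#' -1e-6 abort with an error (the step size is too large for the supplied
#' rates), while float-level noise is clipped back into \[0, 1\].
#'
#' @param initial A [population_state()].
#' @param params Baseline [behavior_params()]; ignored at times where
#'   `schedule` is supplied.
#' @param config A [sim_config()].
#' @param schedule Optional function of time (weeks) returning a
#'   [behavior_params()] vector; when `NULL` the baseline parameters are used
#'   throughout.
#'
#' @return A data frame of class `"obesity_trajectory"` with columns
#'   `time_weeks`, the six stocks, `adult_prevalence_pct` and
#'   `child_prevalence_pct`.
#' @examples
#' traj <- simulate_model(default_initial_state(),
#'                        config = sim_config(horizon = 52))
#' tail(traj, 2)
#' @export
simulate_model <- function(initial,
                           params = behavior_params(),
                           config = sim_config(),
                           schedule = NULL) {
  initial <- validate_population_state(initial)
  base <- as.numeric(validate_behavior_params(params)[PARAM_NAMES])
  stopifnot(inherits(config, "sim_config"))

  if (is.null(schedule)) {
    sched <- function(t) base
  } else {
    if (!is.function(schedule)) stop("schedule must be a function of time",
                                     call. = FALSE)
    probe <- validate_behavior_params(schedule(0))
    sched <- function(t) as.numeric(schedule(t))[seq_len(13L)]
    # schedules built by this package already return vectors in canonical
    # order; user-supplied closures are validated once at t = 0 above
  }

  times <- seq(0, config$horizon, by = config$dt)
  y0 <- as.numeric(initial[STATE_NAMES])
  rhs <- function(t, y, parms) list(.deriv_vec(y, sched(t)))
  out <- deSolve::ode(y = y0, times = times, func = rhs, parms = NULL,
                      method = config$integrator)
  states <- unname(out[, -1L, drop = FALSE])

  if (any(!is.finite(states))) {
    stop("simulation produced non-finite stocks; reduce dt or check parameters",
         call. = FALSE)
  }
  if (min(states) < -1e-6) {
    stop(sprintf(
      "stock went below -1e-6 (min %.3g): dt = %g is too large for these rates",
      min(states), config$dt), call. = FALSE)
  }
  sum_a <- rowSums(states[, 1:3, drop = FALSE])
  sum_c <- rowSums(states[, 4:6, drop = FALSE])
  if (max(abs(sum_a - 1)) > 1e-8 || max(abs(sum_c - 1)) > 1e-8) {
    stop("conservation violated: an age-group sum drifted more than 1e-8 from 1",
         call. = FALSE)
  }
  states[states < 0] <- 0
  states[states > 1] <- 1

  keep <- abs(times / config$record_every -
                round(times / config$record_every)) < 1e-8
  times <- times[keep]
  states <- states[keep, , drop = FALSE]

  traj <- data.frame(time_weeks = times)
  for (i in seq_along(STATE_NAMES)) traj[[STATE_NAMES[i]]] <- states[, i]
  traj$adult_prevalence_pct <-
    100 * (states[, 2] + states[, 3]) / rowSums(states[, 1:3, drop = FALSE])
  traj$child_prevalence_pct <-
    100 * (states[, 5] + states[, 6]) / rowSums(states[, 4:6, drop = FALSE])

  attr(traj, "params") <- params
  attr(traj, "config") <- config
  class(traj) <- c("obesity_trajectory", "data.frame")
  traj
}

#' Combined overweight and obesity prevalence of one age group
#'
#' @param state A [population_state()].
#' @param group `"adult"` or `"child"`.
#' @return Percentage: `100 * (overweight + obese) / (all in group)`.
#' @examples
#' prevalence(population_state(0.5, 0.25, 0.25, 0.34, 0.33, 0.33), "child")
#' @export
prevalence <- function(state, group = c("child", "adult")) {
  group <- match.arg(group)
  state <- validate_population_state(state)
  idx <- if (group == "adult") 1:3 else 4:6
  unname(100 * (state[idx[2]] + state[idx[3]]) / sum(state[idx]))
}

#' Prevalence growth factor over a trajectory
#'
#' Ratio of the final to the initial combined overweight and obesity
#' prevalence of a group. A run over ten years with a growth factor of,
#' say, 1.5 means the prevalence rose by half.
#'
#' @param traj An `"obesity_trajectory"` from [simulate_model()].
#' @param group `"child"` (the model's decision criterion) or `"adult"`.
#' @return Final prevalence divided by initial prevalence.
#' @export
growth_factor <- function(traj, group = c("child", "adult")) {
  group <- match.arg(group)
  stopifnot(inherits(traj, "obesity_trajectory"), nrow(traj) >= 1L)
  col <- paste0(group, "_prevalence_pct")
  p0 <- traj[[col]][1L]
  if (p0 == 0) stop("initial prevalence is zero; growth factor undefined",
                    call. = FALSE)
  traj[[col]][nrow(traj)] / p0
}

#' Extract the state at a given time from a trajectory
#'
#' @param traj An `"obesity_trajectory"`.
#' @param time Recorded time in weeks; defaults to the final time.
#' @return A [population_state()].
#' @export
state_at <- function(traj, time = NULL) {
  stopifnot(inherits(traj, "obesity_trajectory"))
  if (is.null(time)) {
    i <- nrow(traj)
  } else {
    i <- which(abs(traj$time_weeks - time) < 1e-8)
    if (length(i) != 1L) stop(sprintf("time %g weeks was not recorded", time),
                              call. = FALSE)
  }
  st <- as.numeric(traj[i, STATE_NAMES])
  names(st) <- STATE_NAMES
  structure(st, class = "population_state")
}

#' @export
print.obesity_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Obesity transmission trajectory: %d records over %g weeks\n",
              n, x$time_weeks[n]))
  cat(sprintf("  child prevalence: %.2f%% -> %.2f%%\n",
              x$child_prevalence_pct[1L], x$child_prevalence_pct[n]))
  cat(sprintf("  adult prevalence: %.2f%% -> %.2f%%\n",
              x$adult_prevalence_pct[1L], x$adult_prevalence_pct[n]))
  invisible(x)
}

#' Default initial stocks
#'
#' Baseline weight-status proportions for US adults and children circa
#' 2009-2010 (adults: 31.2% normal, 33.1% overweight, 35.7% obese; children:
#' 68.2% normal, 14.9% overweight, 16.9% obese).
#'
#' @return A [population_state()].
#' @export
default_initial_state <- function() {
  population_state(0.312, 0.331, 0.357, 0.682, 0.149, 0.169)
}
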