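# Core domain objects: population state, behavioral parameters, simulation
# controls. All are lightweight classed named-numeric vectors so they can be
# used directly inside the ODE right-hand side without conversion.

STATE_NAMES <- c("n_adult", "ow_adult", "ob_adult",
                 "n_child", "ow_child", "ob_child")

PARAM_NAMES <- c("beta_aa", "beta_cc", "beta_ac",
                 "gamma_a", "gamma_c",
                 "rho_awl", "rho_cwl", "eps_awl", "eps_cwl",
                 "p_sa", "p_sc", "p_oa", "p_oc")

# proportion-valued parameters (must lie in [0, 1])
.PROP_PARAMS <- c("rho_awl", "rho_cwl", "eps_awl", "eps_cwl")
# strictly positive transition times (weeks)
.TIME_PARAMS <- c("p_sa", "p_sc", "p_oa", "p_oc")

#' Population state of the six weight-status stocks
#'
#' The adult and child populations are each split into normal weight,
#' overweight and obese compartments. Stocks are proportions: each age group
#' is closed and sums to 1 (the model has no births, deaths or ageing).
#'
#' @param n_adult,ow_adult,ob_adult Proportions of adults of normal weight
#'   (BMI < 25), overweight (25 <= BMI < 30) and obese (BMI >= 30).
#' @param n_child,ow_child,ob_child Proportions of children below the 85th,
#'   between the 85th and 95th, and at or above the 95th percentile of
#'   BMI-for-age.
#' @param tolerance Allowed deviation of each group sum from 1.
#'
#' @return A named numeric vector of class `"population_state"`.
#' @examples
#' population_state(0.312, 0.331, 0.357, 0.682, 0.149, 0.169)
#' @export
population_state <- function(n_adult, ow_adult, ob_adult,
                             n_child, ow_child, ob_child,
                             tolerance = 1e-9) {
  state <- c(n_adult = n_adult, ow_adult = ow_adult, ob_adult = ob_adult,
             n_child = n_child, ow_child = ow_child, ob_child = ob_child)
  validate_population_state(state, tolerance = tolerance)
  structure(state, class = "population_state")
}

#' Validate a population state vector
#'
#' @param state Named numeric vector with the six stock proportions.
#' @param tolerance Allowed deviation of each group sum from 1, and allowed
#'   excursion of individual stocks outside \[0, 1\].
#' @return The state, invisibly, if valid; otherwise an error naming the
#'   violated constraint.
#' @export
validate_population_state <- function(state, tolerance = 1e-9) {
  if (!is.numeric(state) || length(state) != 6L) {
    stop("population state must be a numeric vector of length 6", call. = FALSE)
  }
  if (!is.null(names(state)) && !identical(names(state), STATE_NAMES) &&
      all(STATE_NAMES %in% names(state))) {
    state <- state[STATE_NAMES]
  }
  if (any(!is.finite(state))) {
    stop("population state contains non-finite values", call. = FALSE)
  }
  bad <- which(state < -tolerance | state > 1 + tolerance)
  if (length(bad)) {
    nm <- if (is.null(names(state))) as.character(bad) else names(state)[bad]
    stop(sprintf("stock '%s' must lie in [0, 1] (got %.6g)",
                 nm[1L], state[bad[1L]]), call. = FALSE)
  }
  if (abs(sum(state[1:3]) - 1) > tolerance) {
    stop(sprintf("adult stocks must sum to 1 (got %.12g)", sum(state[1:3])),
         call. = FALSE)
  }
  if (abs(sum(state[4:6]) - 1) > tolerance) {
    stop(sprintf("child stocks must sum to 1 (got %.12g)", sum(state[4:6])),
         call. = FALSE)
  }
  invisible(state)
}

#' Behavioral parameters of the transmission model
#'
#' Rates are per week; transition times are in weeks; engagement values are
#' proportions. Defaults are the package's calibrated baseline (see the
#' methods vignette): the transmission rates sit at the midpoint of the
#' sensitivity range with the adult-to-child rate 50% above child-to-child,
#' progression rates come from published cohort incidences, transition times
#' from expected weight-loss arithmetic, and engagement proportions are
#' calibrated so the no-intervention run reproduces the observed relative
#' growth of childhood overweight and obesity prevalence.
#'
#' @param beta_aa Adult-to-adult social transmission rate (week^-1).
#' @param beta_cc Child-to-child social transmission rate (week^-1).
#' @param beta_ac Adult-to-child social transmission rate (week^-1).
#' @param gamma_a,gamma_c Rates at which overweight adults/children become
#'   obese (week^-1).
#' @param rho_awl,rho_cwl Proportions of overweight adults/children engaging
#'   in weight-loss behaviors.
#' @param eps_awl,eps_cwl Proportions of obese adults/children engaging in
#'   weight-loss behaviors.
#' @param p_sa,p_sc Average weeks an engaged overweight adult/child needs to
#'   return to normal weight.
#' @param p_oa,p_oc Average weeks an engaged obese adult/child needs to
#'   return to overweight.
#'
#' @return A named numeric vector of class `"behavior_params"`.
#' @examples
#' behavior_params(beta_cc = 0.0019, beta_ac = 1.5 * 0.0019)
#' @export
behavior_params <- function(beta_aa = 0.0015,
                            beta_cc = 0.0015,
                            beta_ac = 0.00225,
                            gamma_a = 0.000769,
                            gamma_c = 0.000354,
                            rho_awl = 0.05,
                            rho_cwl = 0.12,
                            eps_awl = 0.05,
                            eps_cwl = 0.12,
                            p_sa = 66.2,
                            p_sc = 45.9,
                            p_oa = 113.5,
                            p_oc = 104) {
  params <- c(beta_aa = beta_aa, beta_cc = beta_cc, beta_ac = beta_ac,
              gamma_a = gamma_a, gamma_c = gamma_c,
              rho_awl = rho_awl, rho_cwl = rho_cwl,
              eps_awl = eps_awl, eps_cwl = eps_cwl,
              p_sa = p_sa, p_sc = p_sc, p_oa = p_oa, p_oc = p_oc)
  validate_behavior_params(params)
  structure(params, class = "behavior_params")
}

#' Validate a behavioral parameter vector
#'
#' All rates and proportions must be non-negative, engagement proportions at
#' most 1, and transition times strictly positive.
#'
#' @param params Named numeric vector with the 13 behavioral parameters.
#' @return The parameters, invisibly, if valid.
#' @export
validate_behavior_params <- function(params) {
  if (!is.numeric(params) || is.null(names(params)) ||
      !all(PARAM_NAMES %in% names(params)) || length(params) != 13L) {
    stop("behavioral parameters must be a named numeric vector with fields: ",
         paste(PARAM_NAMES, collapse = ", "), call. = FALSE)
  }
  params <- params[PARAM_NAMES]
  if (any(!is.finite(params))) {
    nm <- names(params)[which(!is.finite(params))[1L]]
    stop(sprintf("parameter '%s' is not finite", nm), call. = FALSE)
  }
  neg <- which(params < 0)
  if (length(neg)) {
    nm <- names(params)[neg[1L]]
    stop(sprintf("parameter '%s' must be >= 0 (got %.6g)", nm, params[neg[1L]]),
         call. = FALSE)
  }
  over <- which(params[.PROP_PARAMS] > 1)
  if (length(over)) {
    nm <- .PROP_PARAMS[over[1L]]
    stop(sprintf("parameter '%s' is a proportion and must be <= 1 (got %.6g)",
                 nm, params[nm]), call. = FALSE)
  }
  zero_time <- which(params[.TIME_PARAMS] <= 0)
  if (length(zero_time)) {
    nm <- .TIME_PARAMS[zero_time[1L]]
    stop(sprintf("parameter '%s' is a transition time and must be > 0 (got %.6g)",
                 nm, params[nm]), call. = FALSE)
  }
  invisible(params)
}

#' Simulation controls
#'
#' @param dt Integration time step in weeks.
#' @param horizon Simulation horizon in weeks (default 520, i.e. ten years).
#' @param integrator `"euler"` (fixed-step, the system-dynamics convention) or
#'   `"rk4"`.
#' @param record_every Recording interval in weeks; must be a multiple of
#'   `dt`.
#'
#' @return A list of class `"sim_config"`.
#' @examples
#' sim_config(dt = 0.25, horizon = 520)
#' @export
sim_config <- function(dt = 0.25, horizon = 520,
                       integrator = c("euler", "rk4"),
                       record_every = 1) {
  integrator <- match.arg(integrator)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number of weeks", call. = FALSE)
  }
  if (!is.numeric(horizon) || horizon <= 0 ||
      abs(horizon / dt - round(horizon / dt)) > 1e-8) {
    stop("horizon must be a positive multiple of dt", call. = FALSE)
  }
  if (!is.numeric(record_every) || record_every <= 0 ||
      abs(record_every / dt - round(record_every / dt)) > 1e-8) {
    stop("record_every must be a positive multiple of dt", call. = FALSE)
  }
  structure(list(dt = dt, horizon = horizon, integrator = integrator,
                 record_every = record_every),
            class = "sim_config")
}

#' @export
print.population_state <- function(x, ...) {
  cat("Population state (proportions)\n")
  cat(sprintf("  adults:   normal %.4f  overweight %.4f  obese %.4f\n",
              x[["n_adult"]], x[["ow_adult"]], x[["ob_adult"]]))
  cat(sprintf("  children: normal %.4f  overweight %.4f  obese %.4f\n",
              x[["n_child"]], x[["ow_child"]], x[["ob_child"]]))
  invisible(x)
}

#' @export
print.behavior_params <- function(x, ...) {
  cat("Behavioral parameters\n")
  cat(sprintf("  transmission (week^-1): beta_aa %.5g  beta_cc %.5g  beta_ac %.5g\n",
              x[["beta_aa"]], x[["beta_cc"]], x[["beta_ac"]]))
  cat(sprintf("  progression (week^-1):  gamma_a %.5g  gamma_c %.5g\n",
              x[["gamma_a"]], x[["gamma_c"]]))
  cat(sprintf("  engagement: rho_awl %.3g  eps_awl %.3g  rho_cwl %.3g  eps_cwl %.3g\n",
              x[["rho_awl"]], x[["eps_awl"]], x[["rho_cwl"]], x[["eps_cwl"]]))
  cat(sprintf("  transition times (weeks): p_sa %.4g  p_oa %.4g  p_sc %.4g  p_oc %.4g\n",
              x[["p_sa"]], x[["p_oa"]], x[["p_sc"]], x[["p_oc"]]))
  invisible(x)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation: dt = %g wk, horizon = %g wk, %s, record every %g wk\n",
              x$dt, x$horizon, x$integrator, x$record_every))
  invisible(x)
}
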