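# Intervention machinery: direct impacts per targeted subgroup, cross-age
# coupling into total impacts, the linear ramp that applies totals to the
# behavioral parameters, and the catalogs of named alternatives and
# (psi_a, psi_c) scenarios.

IMPACT_NAMES <- c("eta_nc", "eta_sc", "eta_oc", "eta_na", "eta_sa", "eta_oa")
TOTAL_NAMES <- c("h_nc", "h_sc", "h_oc", "h_na", "h_sa", "h_oa")

#' Direct intervention impacts per targeted subgroup
#'
#' Each impact is the relative change (as a fraction) that the intervention
#' would, at full ramp, apply to its targeted behavioral parameter:
#' prevention impacts (`eta_na`, `eta_nc`) reduce social transmission rates,
#' treatment impacts (`eta_sa`, `eta_oa`, `eta_sc`, `eta_oc`) increase
#' weight-loss engagement of the overweight/obese stock they target.
#'
#' @param eta_nc Child prevention impact.
#' @param eta_sc Child overweight treatment impact.
#' @param eta_oc Child obesity treatment impact.
#' @param eta_na Adult prevention impact.
#' @param eta_sa Adult overweight treatment impact.
#' @param eta_oa Adult obesity treatment impact.
#' @return Named numeric vector of class `"intervention_impacts"`.
#' @export
intervention_impacts <- function(eta_nc = 0, eta_sc = 0, eta_oc = 0,
                                 eta_na = 0, eta_sa = 0, eta_oa = 0) {
  x <- c(eta_nc = eta_nc, eta_sc = eta_sc, eta_oc = eta_oc,
         eta_na = eta_na, eta_sa = eta_sa, eta_oa = eta_oa)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    bad <- which(!is.finite(x) | x < 0 | x > 1)[1L]
    stop(sprintf("impact '%s' must lie in [0, 1] (got %.6g)",
                 names(x)[bad], x[bad]), call. = FALSE)
  }
  structure(x, class = "intervention_impacts")
}

#' Cross-age impact factors and the adult-to-child discount
#'
#' `psi_a` is the fraction of an adult intervention's impact that carries
#' over to children; `psi_c` the fraction of a child intervention's impact
#' carrying over to adults. `discount` attenuates how strongly the
#' adult-to-child transmission rate responds to child prevention, reflecting
#' children's limited control over parental behavior.
#'
#' @param psi_a,psi_c,discount Fractions in \[0, 1\].
#' @return Named numeric vector of class `"impact_factors"`.
#' @examples
#' impact_factors(psi_a = 0.5, psi_c = 0.25)
#' @export
impact_factors <- function(psi_a = 0.5, psi_c = 0.25, discount = 0.5) {
  x <- c(psi_a = psi_a, psi_c = psi_c, discount = discount)
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    bad <- which(!is.finite(x) | x < 0 | x > 1)[1L]
    stop(sprintf("impact factor '%s' must lie in [0, 1] (got %.6g)",
                 names(x)[bad], x[bad]), call. = FALSE)
  }
  structure(x, class = "impact_factors")
}

#' Total intervention impacts after cross-age coupling
#'
#' Each total impact is the subgroup's direct impact plus the impact-factor
#' share of the corresponding impact aimed at the other age group:
#' \deqn{h_{NC} = \eta_{NC} + \psi_A \eta_{NA}, \quad
#'       h_{NA} = \eta_{NA} + \psi_C \eta_{NC}}
#' and likewise for the overweight- and obese-treatment pairs.
#'
#' @param impacts An [intervention_impacts()] vector.
#' @param factors An [impact_factors()] vector.
#' @return Named numeric vector of class `"total_impacts"` with fields
#'   `h_nc`, `h_sc`, `h_oc`, `h_na`, `h_sa`, `h_oa`. Each total is at least
#'   as large as its direct component.
#' @examples
#' total_impacts(intervention_impacts(eta_na = 0.5),
#'               impact_factors(psi_a = 0.5, psi_c = 0.25))
#' @export
total_impacts <- function(impacts, factors) {
  stopifnot(inherits(impacts, "intervention_impacts"),
            inherits(factors, "impact_factors"))
  h <- c(
    h_nc = impacts[["eta_nc"]] + factors[["psi_a"]] * impacts[["eta_na"]],
    h_sc = impacts[["eta_sc"]] + factors[["psi_a"]] * impacts[["eta_sa"]],
    h_oc = impacts[["eta_oc"]] + factors[["psi_a"]] * impacts[["eta_oa"]],
    h_na = impacts[["eta_na"]] + factors[["psi_c"]] * impacts[["eta_nc"]],
    h_sa = impacts[["eta_sa"]] + factors[["psi_c"]] * impacts[["eta_sc"]],
    h_oa = impacts[["eta_oa"]] + factors[["psi_c"]] * impacts[["eta_oc"]])
  structure(h, class = "total_impacts")
}

# core ramp arithmetic on a plain parameter vector (canonical order);
# r is the ramp level in [0, 1]
.effective_vec <- function(base, h, discount, r) {
  v <- base
  v[1L] <- base[1L] * (1 - h[["h_na"]] * r)            # beta_aa
  v[2L] <- base[2L] * (1 - h[["h_nc"]] * r)            # beta_cc
  v[3L] <- base[3L] * (1 - discount * h[["h_nc"]] * r) # beta_ac
  v[6L] <- min(1, base[6L] * (1 + h[["h_sa"]] * r))    # rho_awl
  v[8L] <- min(1, base[8L] * (1 + h[["h_oa"]] * r))    # eps_awl
  v[7L] <- min(1, base[7L] * (1 + h[["h_sc"]] * r))    # rho_cwl
  v[9L] <- min(1, base[9L] * (1 + h[["h_oc"]] * r))    # eps_cwl
  v
}

#' Behavioral parameters under an intervention ramp
#'
#' Interventions change their targeted behavioral parameters linearly over
#' the ramp horizon. With ramp level `r(t) = min(t / ramp_horizon, 1)`,
#' prevention totals scale the transmission rates down
#' (`beta_aa`, `beta_cc`, and `beta_ac` at the discounted rate) and treatment
#' totals scale the four engagement proportions up (capped at 1). Exactly
#' seven parameters can change; progression rates and transition times are
#' untouched.
#'
#' @param base Baseline [behavior_params()].
#' @param totals A [total_impacts()] vector.
#' @param factors An [impact_factors()] vector (supplies the discount).
#' @param t Time in weeks (>= 0); values beyond `ramp_horizon` hold at the
#'   full-ramp level.
#' @param ramp_horizon Ramp duration in weeks (default 520 = ten years).
#' @return A [behavior_params()] vector of effective parameters at time `t`.
#' @examples
#' h <- total_impacts(intervention_impacts(eta_na = 0.5), impact_factors(0, 0))
#' effective_params(behavior_params(), h, impact_factors(0, 0), t = 520)
#' @export
effective_params <- function(base, totals, factors, t, ramp_horizon = 520) {
  base <- validate_behavior_params(base)
  stopifnot(inherits(totals, "total_impacts"),
            inherits(factors, "impact_factors"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("t must be a single non-negative time in weeks", call. = FALSE)
  }
  if (ramp_horizon <= 0) stop("ramp_horizon must be positive", call. = FALSE)
  if (totals[["h_na"]] > 1 || totals[["h_nc"]] > 1) {
    stop("total prevention impact exceeds 1: effective transmission rate would go negative",
         call. = FALSE)
  }
  r <- min(t / ramp_horizon, 1)
  v <- .effective_vec(as.numeric(base[PARAM_NAMES]), totals,
                      factors[["discount"]], r)
  names(v) <- PARAM_NAMES
  structure(v, class = "behavior_params")
}

#' Build a time-varying parameter schedule for an intervention
#'
#' Convenience wrapper producing the `schedule` argument of
#' [simulate_model()] from direct impacts and impact factors.
#'
#' @inheritParams effective_params
#' @param impacts An [intervention_impacts()] vector (or an alternative from
#'   [alternative_catalog()], whose `impacts` element is used).
#' @return A function of time returning effective [behavior_params()].
#' @export
intervention_schedule <- function(base, impacts, factors, ramp_horizon = 520) {
  if (inherits(impacts, "alternative")) impacts <- impacts$impacts
  base <- validate_behavior_params(base)
  h <- total_impacts(impacts, factors)
  if (h[["h_na"]] > 1 || h[["h_nc"]] > 1) {
    stop("total prevention impact exceeds 1: effective transmission rate would go negative",
         call. = FALSE)
  }
  bvec <- base[PARAM_NAMES]  # subsetting drops the class, keeps names
  disc <- factors[["discount"]]
  cls <- "behavior_params"
  function(t) {
    v <- .effective_vec(bvec, h, disc, min(t / ramp_horizon, 1))
    class(v) <- cls
    v
  }
}

# component -> direct impact fields, at a given magnitude
.component_impacts <- function(components, magnitude) {
  eta <- c(eta_nc = 0, eta_sc = 0, eta_oc = 0,
           eta_na = 0, eta_sa = 0, eta_oa = 0)
  if ("adult_prevention" %in% components) eta["eta_na"] <- magnitude
  if ("child_prevention" %in% components) eta["eta_nc"] <- magnitude
  if ("adult_treatment" %in% components) {
    eta["eta_sa"] <- magnitude
    eta["eta_oa"] <- magnitude
  }
  if ("child_treatment" %in% components) {
    eta["eta_sc"] <- magnitude
    eta["eta_oc"] <- magnitude
  }
  do.call(intervention_impacts, as.list(eta))
}

.ALTERNATIVE_COMPONENTS <- list(
  AP     = c("adult_prevention"),
  CP     = c("child_prevention"),
  AT     = c("adult_treatment"),
  CT     = c("child_treatment"),
  APCP   = c("adult_prevention", "child_prevention"),
  ATCT   = c("adult_treatment", "child_treatment"),
  ATCP   = c("adult_treatment", "child_prevention"),
  APCT   = c("adult_prevention", "child_treatment"),
  CPCT   = c("child_prevention", "child_treatment"),
  APAT   = c("adult_prevention", "adult_treatment"),
  APCPCT = c("adult_prevention", "child_prevention", "child_treatment"),
  ATCPCT = c("adult_treatment", "child_prevention", "child_treatment"),
  APATCP = c("adult_prevention", "adult_treatment", "child_prevention"),
  APATCT = c("adult_prevention", "adult_treatment", "child_treatment"),
  ALL    = c("adult_prevention", "adult_treatment",
             "child_prevention", "child_treatment")
)

#' Catalog of the 15 intervention alternatives
#'
#' Every non-empty combination of the four intervention components — adult
#' prevention (AP), adult overweight and obesity treatment (AT), child
#' prevention (CP), child overweight and obesity treatment (CT). Names
#' concatenate the active components; the full combination is `"ALL"`
#' (written APATCPCT when ranked).
#'
#' @param magnitude Direct impact assigned to each active component's
#'   targeted subgroups (default 0.5: a 50% change at full ramp).
#' @return Named list of 15 objects of class `"alternative"`, each with
#'   `name`, `components` and `impacts`.
#' @examples
#' names(alternative_catalog())
#' alternative_catalog()[["ATCP"]]$components
#' @export
alternative_catalog <- function(magnitude = 0.5) {
  if (!is.numeric(magnitude) || magnitude < 0 || magnitude > 1) {
    stop("magnitude must lie in [0, 1]", call. = FALSE)
  }
  out <- lapply(names(.ALTERNATIVE_COMPONENTS), function(nm) {
    comps <- .ALTERNATIVE_COMPONENTS[[nm]]
    structure(list(name = nm, components = comps,
                   impacts = .component_impacts(comps, magnitude)),
              class = "alternative")
  })
  names(out) <- names(.ALTERNATIVE_COMPONENTS)
  out
}

#' @export
print.alternative <- function(x, ...) {
  cat(sprintf("Alternative %s: %s\n", x$name,
              paste(x$components, collapse = " + ")))
  invisible(x)
}

#' Catalog of the six impact-factor scenarios
#'
#' The 3 x 2 grid of adult-on-child impact factors (25%, 50%, 75%) by
#' child-on-adult impact factors (10%, 25%). Scenarios 1-3 hold `psi_c` at
#' 0.10 while `psi_a` rises; scenarios 4-6 repeat with `psi_c` = 0.25.
#'
#' @return Data frame with columns `scenario`, `label`, `psi_a`, `psi_c`.
#' @examples
#' scenario_catalog()
#' @export
scenario_catalog <- function() {
  data.frame(
    scenario = 1:6,
    label = paste("Scenario", 1:6),
    psi_a = rep(c(0.25, 0.50, 0.75), times = 2),
    psi_c = rep(c(0.10, 0.25), each = 3)
  )
}
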