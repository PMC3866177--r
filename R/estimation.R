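# Parameter estimation: converts published summary statistics and
# individual-level survey-style records into model parameters, plus a seeded
# synthetic-record generator so the estimation path is testable without any
# survey download.

RECORD_GROUPS <- c("ow_adult", "ob_adult", "ow_child", "ob_child")

RECORD_COLUMNS <- c("group", "on_weight_loss_diet",
                    "moderate_days_per_week", "moderate_minutes_per_day",
                    "vigorous_days_per_week", "vigorous_minutes_per_day")

# weekly minutes of moderate + vigorous recreational activity
.weekly_activity_minutes <- function(records) {
  records$moderate_days_per_week * records$moderate_minutes_per_day +
    records$vigorous_days_per_week * records$vigorous_minutes_per_day
}

#' Progression rate from a cohort incidence
#'
#' Converts a cumulative incidence of obesity among the overweight observed
#' over some follow-up into a constant per-week progression rate:
#' `incidence / horizon`. With the published inputs this gives the adult rate
#' 0.16 / (4 x 52) = 0.000769 week^-1 and the child rate
#' 0.043 / (28 x 4.333) = 0.000354 week^-1.
#'
#' @param incidence_fraction Cumulative incidence over the follow-up, in
#'   \[0, 1).
#' @param horizon_weeks Follow-up length in weeks (> 0).
#' @return Progression rate in week^-1.
#' @examples
#' progression_rate(0.16, 4 * 52)
#' progression_rate(0.043, 28 * 4.333)
#' @export
progression_rate <- function(incidence_fraction, horizon_weeks) {
  if (!is.numeric(incidence_fraction) || any(!is.finite(incidence_fraction)) ||
      any(incidence_fraction < 0) || any(incidence_fraction >= 1)) {
    stop("incidence_fraction must lie in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(horizon_weeks) || any(!is.finite(horizon_weeks)) ||
      any(horizon_weeks <= 0)) {
    stop("horizon_weeks must be > 0", call. = FALSE)
  }
  incidence_fraction / horizon_weeks
}

#' Average time for an engaged adult to move down one weight category
#'
#' Adults engaged in behavioral weight-loss programs lose about 5.5 kg per
#' year, so an adult needing to shed `mean_excess_weight_kg` takes
#' proportionally many weeks: `(excess / expected_per_year) * 52`.
#'
#' @param mean_excess_weight_kg Average weight (kg) the stock must lose to
#'   reach the next-lower category.
#' @param expected_loss_kg_per_year Expected loss while engaged (kg/year),
#'   default 5.5.
#' @return Transition time in weeks.
#' @examples
#' adult_transition_time(5.5)          # 52 weeks
#' adult_transition_time(11.0, 5.5)    # 104 weeks
#' @export
adult_transition_time <- function(mean_excess_weight_kg,
                                  expected_loss_kg_per_year = 5.5) {
  if (!is.numeric(mean_excess_weight_kg) || any(mean_excess_weight_kg <= 0)) {
    stop("mean_excess_weight_kg must be > 0", call. = FALSE)
  }
  if (!is.numeric(expected_loss_kg_per_year) ||
      any(expected_loss_kg_per_year <= 0)) {
    stop("expected_loss_kg_per_year must be > 0", call. = FALSE)
  }
  mean_excess_weight_kg / expected_loss_kg_per_year * 52
}

#' Average time for an engaged child to move down one weight category
#'
#' Effective child treatment decreases BMI by about 1.7 units per year; a
#' child needing a BMI decrease of `mean_bmi_decrease_needed` (already
#' adjusted for growth over the transition window) takes
#' `(needed / expected_per_year) * 52` weeks.
#'
#' @param mean_bmi_decrease_needed Average BMI-unit decrease required.
#' @param expected_bmi_decrease_per_year Expected decrease while engaged
#'   (BMI units/year), default 1.7.
#' @return Transition time in weeks.
#' @examples
#' child_transition_time(1.7)        # 52 weeks
#' child_transition_time(0.85, 1.7)  # 26 weeks
#' @export
child_transition_time <- function(mean_bmi_decrease_needed,
                                  expected_bmi_decrease_per_year = 1.7) {
  if (!is.numeric(mean_bmi_decrease_needed) ||
      any(mean_bmi_decrease_needed <= 0)) {
    stop("mean_bmi_decrease_needed must be > 0", call. = FALSE)
  }
  if (!is.numeric(expected_bmi_decrease_per_year) ||
      any(expected_bmi_decrease_per_year <= 0)) {
    stop("expected_bmi_decrease_per_year must be > 0", call. = FALSE)
  }
  mean_bmi_decrease_needed / expected_bmi_decrease_per_year * 52
}

.validate_records <- function(records) {
  if (!is.data.frame(records)) stop("records must be a data frame",
                                    call. = FALSE)
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(records$group %in% RECORD_GROUPS)) {
    stop("record group must be one of: ", paste(RECORD_GROUPS, collapse = ", "),
         call. = FALSE)
  }
  days <- c(records$moderate_days_per_week, records$vigorous_days_per_week)
  if (any(days < 0) || any(days > 7)) {
    stop("days per week must lie in [0, 7]", call. = FALSE)
  }
  mins <- c(records$moderate_minutes_per_day, records$vigorous_minutes_per_day)
  if (any(mins < 0)) stop("minutes per day must be >= 0", call. = FALSE)
  invisible(records)
}

#' Proportion of a stock engaging in weight-loss behaviors
#'
#' A record counts as engaging when it reports following a weight-loss or
#' low-calorie diet AND accumulates at least 250 minutes per week of moderate
#' plus vigorous recreational activity (typical days per week times typical
#' minutes per day, summed over the two intensities).
#'
#' @param records Data frame of individual records (see [synthesize_records()]
#'   or [read_records()] for the schema).
#' @param group One of `"ow_adult"`, `"ob_adult"`, `"ow_child"`, `"ob_child"`.
#' @return Proportion of the group's records meeting both criteria.
#' @examples
#' recs <- synthesize_records(n_per_group = 50, engagement_target = 0.4,
#'                            seed = 7)
#' weight_loss_engagement(recs, "ow_child")
#' @export
weight_loss_engagement <- function(records, group) {
  .validate_records(records)
  group <- match.arg(group, RECORD_GROUPS)
  sub <- records[records$group == group, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("no records in group '%s'; engagement proportion undefined",
                 group), call. = FALSE)
  }
  engaged <- sub$on_weight_loss_diet & .weekly_activity_minutes(sub) >= 250
  mean(engaged)
}

#' Generate synthetic survey-style records
#'
#' Builds, for each of the four overweight/obese stocks, `n_per_group`
#' records whose realized weight-loss engagement equals
#' `round(engagement_target * n_per_group) / n_per_group` by construction.
#' Engaging records report a diet plus at least 250 weekly activity minutes;
#' the rest fail the diet criterion, the activity criterion, or both.
#' The generator is deterministic for a given seed and restores the caller's
#' RNG state.
#'
#' @param n_per_group Records per group (>= 1).
#' @param engagement_target Target engagement proportion in \[0, 1\].
#' @param seed Integer seed.
#' @return Data frame with columns `group`, `on_weight_loss_diet`,
#'   `moderate_days_per_week`, `moderate_minutes_per_day`,
#'   `vigorous_days_per_week`, `vigorous_minutes_per_day`.
#' @examples
#' recs <- synthesize_records(100, 0.2, seed = 1)
#' weight_loss_engagement(recs, "ob_adult")
#' @export
synthesize_records <- function(n_per_group, engagement_target, seed) {
  if (!is.numeric(n_per_group) || n_per_group < 1) {
    stop("n_per_group must be >= 1", call. = FALSE)
  }
  if (!is.numeric(engagement_target) || engagement_target < 0 ||
      engagement_target > 1) {
    stop("engagement_target must lie in [0, 1]", call. = FALSE)
  }
  if (missing(seed) || !is.numeric(seed)) stop("seed is required",
                                               call. = FALSE)
  n <- as.integer(n_per_group)
  k <- as.integer(round(engagement_target * n))

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))

  one_group <- function(group) {
    engaged <- c(rep(TRUE, k), rep(FALSE, n - k))
    mod_days <- integer(n); mod_min <- numeric(n)
    vig_days <- integer(n); vig_min <- numeric(n)
    diet <- logical(n)
    for (i in seq_len(n)) {
      if (engaged[i]) {
        diet[i] <- TRUE
        mod_days[i] <- sample(3:6, 1L)
        mod_min[i] <- sample(seq(30, 90, by = 5), 1L)
        vig_days[i] <- sample(0:3, 1L)
        vig_min[i] <- if (vig_days[i] > 0) sample(seq(10, 60, by = 5), 1L) else 0
        total <- mod_days[i] * mod_min[i] + vig_days[i] * vig_min[i]
        if (total < 250) {
          mod_min[i] <- ceiling((250 - vig_days[i] * vig_min[i]) / mod_days[i])
        }
      } else {
        # fail the diet criterion, the activity criterion, or both
        mode <- sample(c("no_diet", "low_activity", "neither"), 1L)
        diet[i] <- mode == "low_activity"
        mod_days[i] <- sample(0:3, 1L)
        mod_min[i] <- if (mod_days[i] > 0) sample(seq(5, 40, by = 5), 1L) else 0
        vig_days[i] <- sample(0:2, 1L)
        vig_min[i] <- if (vig_days[i] > 0) sample(seq(5, 20, by = 5), 1L) else 0
        if (mode == "no_diet") {
          # any activity level is allowed when the diet criterion fails
          if (runif(1) < 0.3) {
            mod_days[i] <- sample(4:7, 1L)
            mod_min[i] <- sample(seq(40, 90, by = 5), 1L)
          }
        } else {
          # must stay under 250 weekly minutes
          while (mod_days[i] * mod_min[i] + vig_days[i] * vig_min[i] >= 250) {
            mod_min[i] <- floor(mod_min[i] / 2)
          }
        }
      }
    }
    data.frame(group = group,
               on_weight_loss_diet = diet,
               moderate_days_per_week = mod_days,
               moderate_minutes_per_day = mod_min,
               vigorous_days_per_week = vig_days,
               vigorous_minutes_per_day = vig_min,
               stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, lapply(RECORD_GROUPS, one_group))
  rownames(out) <- NULL
  out
}

#' Read individual records from CSV
#'
#' @param path CSV file with the [synthesize_records()] column schema.
#' @return Validated records data frame.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path, call. = FALSE)
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  records$on_weight_loss_diet <- as.logical(records$on_weight_loss_diet)
  .validate_records(records)
  records
}

#' Write individual records to CSV
#'
#' @param records Records data frame.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_records <- function(records, path) {
  .validate_records(records)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Estimate model parameters from records and summary statistics
#'
#' Combines the four engagement proportions computed from individual records
#' with progression rates and transition times computed from published
#' summary inputs into a configuration fragment mergeable into the model
#' configuration (see [load_config()]).
#'
#' @param records Individual records (all four groups present).
#' @param adult_incidence,adult_incidence_weeks Cumulative obesity incidence
#'   among overweight adults and its follow-up (defaults 0.16 over 4 years).
#' @param child_incidence,child_incidence_weeks Same for children (defaults
#'   0.043 over 28 months at 4.333 weeks/month).
#' @param ow_adult_excess_kg,ob_adult_excess_kg Mean weight to lose for
#'   overweight/obese adults (kg).
#' @param expected_loss_kg_per_year Expected adult loss while engaged.
#' @param ow_child_bmi_decrease,ob_child_bmi_decrease Mean BMI decrease
#'   needed for overweight/obese children.
#' @param expected_bmi_decrease_per_year Expected child BMI decrease while
#'   engaged.
#' @return Named list (a `params` config fragment) with `rho_awl`, `eps_awl`,
#'   `rho_cwl`, `eps_cwl`, `gamma_a`, `gamma_c`, `p_sa`, `p_oa`, `p_sc`,
#'   `p_oc`.
#' @examples
#' recs <- synthesize_records(200, 0.1, seed = 42)
#' estimate_params(recs)
#' @export
estimate_params <- function(records,
                            adult_incidence = 0.16,
                            adult_incidence_weeks = 4 * 52,
                            child_incidence = 0.043,
                            child_incidence_weeks = 28 * 4.333,
                            ow_adult_excess_kg = 7.0,
                            ob_adult_excess_kg = 12.0,
                            expected_loss_kg_per_year = 5.5,
                            ow_child_bmi_decrease = 1.5,
                            ob_child_bmi_decrease = 3.4,
                            expected_bmi_decrease_per_year = 1.7) {
  list(
    rho_awl = weight_loss_engagement(records, "ow_adult"),
    eps_awl = weight_loss_engagement(records, "ob_adult"),
    rho_cwl = weight_loss_engagement(records, "ow_child"),
    eps_cwl = weight_loss_engagement(records, "ob_child"),
    gamma_a = progression_rate(adult_incidence, adult_incidence_weeks),
    gamma_c = progression_rate(child_incidence, child_incidence_weeks),
    p_sa = adult_transition_time(ow_adult_excess_kg, expected_loss_kg_per_year),
    p_oa = adult_transition_time(ob_adult_excess_kg, expected_loss_kg_per_year),
    p_sc = child_transition_time(ow_child_bmi_decrease,
                                 expected_bmi_decrease_per_year),
    p_oc = child_transition_time(ob_child_bmi_decrease,
                                 expected_bmi_decrease_per_year)
  )
}
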