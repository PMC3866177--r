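test_that("total impacts couple the age groups additively", {
  # no direct impact anywhere -> no totals
  h0 <- total_impacts(intervention_impacts(), impact_factors(0.5, 0.25))
  expect_equal(unname(unclass(h0)), rep(0, 6))

  # child prevention spills over to adults through psi_c only
  h <- total_impacts(intervention_impacts(eta_nc = 0.5),
                     impact_factors(psi_a = 0.5, psi_c = 0.25))
  expect_equal(h[["h_nc"]], 0.5)
  expect_equal(h[["h_na"]], 0.125)
  expect_equal(unname(h[c("h_sc", "h_oc", "h_sa", "h_oa")]), rep(0, 4))

  # both preventions: child total picks up psi_a share of the adult impact
  h2 <- total_impacts(intervention_impacts(eta_na = 0.5, eta_nc = 0.5),
                      impact_factors(psi_a = 0.75, psi_c = 0.25))
  expect_equal(h2[["h_nc"]], 0.875)

  expect_error(intervention_impacts(eta_na = -0.1), "'eta_na'")
  expect_error(impact_factors(psi_a = 1.5), "'psi_a'")
})

test_that("totals dominate their direct component and grow monotonically", {
  set.seed(7)
  for (i in 1:20) {
    eta <- stats::runif(6)
    imp <- do.call(intervention_impacts, as.list(
      stats::setNames(eta, IMPACT_NAMES)))
    fac <- impact_factors(stats::runif(1), stats::runif(1))
    h <- total_impacts(imp, fac)
    expect_true(all(unclass(h) >= unclass(imp)[IMPACT_NAMES]))

    # raising any single eta never lowers any total
    j <- sample(6, 1)
    eta2 <- eta
    eta2[j] <- min(1, eta[j] + 0.1)
    imp2 <- do.call(intervention_impacts, as.list(
      stats::setNames(eta2, IMPACT_NAMES)))
    expect_true(all(total_impacts(imp2, fac) >= h))
  }
})

test_that("the ramp is linear in time and caps at the horizon", {
  base <- behavior_params()
  fac <- impact_factors(psi_a = 0, psi_c = 0)

  # no time elapsed: identity
  h_na_only <- total_impacts(intervention_impacts(eta_na = 0.5), fac)
  eff0 <- effective_params(base, h_na_only, fac, t = 0, ramp_horizon = 520)
  expect_equal(unclass(eff0), unclass(base))

  # full ramp: the directly targeted rate is exactly halved
  eff_end <- effective_params(base, h_na_only, fac, t = 520,
                              ramp_horizon = 520)
  expect_equal(eff_end[["beta_aa"]], base[["beta_aa"]] / 2)
  expect_equal(unclass(eff_end)[-1], unclass(base)[-1])

  # beyond the horizon the level holds
  eff_past <- effective_params(base, h_na_only, fac, t = 1040,
                               ramp_horizon = 520)
  expect_equal(unclass(eff_past), unclass(eff_end))

  # midpoint of a child-treatment ramp scales engagement by 1.25
  h_sc <- total_impacts(intervention_impacts(eta_sc = 0.5), fac)
  eff_mid <- effective_params(base, h_sc, fac, t = 260, ramp_horizon = 520)
  expect_equal(eff_mid[["rho_cwl"]], base[["rho_cwl"]] * 1.25)
})

test_that("exactly seven behavioral parameters can respond to interventions", {
  base <- behavior_params()
  fac <- impact_factors(psi_a = 0.75, psi_c = 0.25, discount = 0.5)
  h <- total_impacts(
    intervention_impacts(eta_nc = 0.3, eta_sc = 0.3, eta_oc = 0.3,
                         eta_na = 0.3, eta_sa = 0.3, eta_oa = 0.3), fac)
  eff <- effective_params(base, h, fac, t = 260, ramp_horizon = 520)
  changed <- names(base)[unclass(eff) != unclass(base)]
  expect_setequal(changed, c("beta_aa", "beta_cc", "beta_ac",
                             "rho_awl", "eps_awl", "rho_cwl", "eps_cwl"))
  # transmission falls, engagement rises, the adult-to-child cut is discounted
  expect_lt(eff[["beta_aa"]], base[["beta_aa"]])
  expect_gt(eff[["rho_cwl"]], base[["rho_cwl"]])
  expect_equal(1 - eff[["beta_ac"]] / base[["beta_ac"]],
               0.5 * (1 - eff[["beta_cc"]] / base[["beta_cc"]]))
})

test_that("engagement proportions cap at 1 and excessive prevention errors", {
  base <- behavior_params(rho_cwl = 0.9)
  fac <- impact_factors(psi_a = 0, psi_c = 0)
  h <- total_impacts(intervention_impacts(eta_sc = 0.5), fac)
  eff <- effective_params(base, h, fac, t = 520, ramp_horizon = 520)
  expect_equal(eff[["rho_cwl"]], 1)

  h_big <- structure(c(h_nc = 1.2, h_sc = 0, h_oc = 0,
                       h_na = 0, h_sa = 0, h_oa = 0),
                     class = "total_impacts")
  expect_error(effective_params(base, h_big, fac, t = 260),
               "would go negative")
})

test_that("the alternative catalog matches its published composition", {
  catalog <- alternative_catalog()
  expect_length(catalog, 15)
  expect_setequal(
    names(catalog),
    c("AP", "CP", "AT", "CT", "APCP", "ATCT", "ATCP", "APCT", "CPCT",
      "APAT", "APCPCT", "ATCPCT", "APATCP", "APATCT", "ALL"))

  expect_setequal(catalog[["ATCP"]]$components,
                  c("adult_treatment", "child_prevention"))
  expect_setequal(catalog[["ALL"]]$components,
                  c("adult_prevention", "adult_treatment",
                    "child_prevention", "child_treatment"))

  # AP targets only adult prevention at the default magnitude
  ap <- catalog[["AP"]]$impacts
  expect_equal(ap[["eta_na"]], 0.5)
  expect_equal(unname(ap[setdiff(IMPACT_NAMES, "eta_na")]), rep(0, 5))

  # treatment components set both the overweight and obese impacts
  at <- catalog[["AT"]]$impacts
  expect_equal(at[["eta_sa"]], 0.5)
  expect_equal(at[["eta_oa"]], 0.5)
  expect_equal(at[["eta_sc"]], 0)
})

test_that("the scenario catalog is the published 3x2 grid", {
  sc <- scenario_catalog()
  expect_equal(nrow(sc), 6)
  expect_equal(sc$psi_a[sc$scenario == 1], 0.25)
  expect_equal(sc$psi_c[sc$scenario == 1], 0.10)
  expect_equal(sc$psi_a[sc$scenario == 6], 0.75)
  expect_equal(sc$psi_c[sc$scenario == 6], 0.25)
  expect_setequal(unique(sc$psi_a), c(0.25, 0.50, 0.75))
  expect_setequal(unique(sc$psi_c), c(0.10, 0.25))
})
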