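test_that("derivatives reproduce the transmission flow algebra", {
  # all normal weight: nothing to transmit, progress, or recover
  all_normal <- population_state(1, 0, 0, 1, 0, 0)
  expect_equal(unname(state_derivatives(all_normal, behavior_params())),
               rep(0, 6))

  # adult-only transmission, hand arithmetic: 0.0015 * 0.3 * 0.7 = 0.000315
  p <- behavior_params(beta_aa = 0.0015, beta_cc = 0, beta_ac = 0,
                       gamma_a = 0, gamma_c = 0,
                       rho_awl = 0, rho_cwl = 0, eps_awl = 0, eps_cwl = 0)
  d <- state_derivatives(population_state(0.3, 0.35, 0.35, 1, 0, 0), p)
  expect_equal(d[["n_adult"]], -0.000315)
  expect_equal(d[["ow_adult"]], 0.000315)
  expect_equal(unname(d[c("ob_adult", "n_child", "ow_child", "ob_child")]),
               rep(0, 4))
})

test_that("derivative components conserve each age group", {
  set.seed(101)
  for (i in 1:25) {
    d <- state_derivatives(random_state(), random_params())
    expect_lt(abs(sum(d[1:3])), 1e-15)
    expect_lt(abs(sum(d[4:6])), 1e-15)
  }
})

test_that("adult equations never reference child stocks", {
  # two runs differing only in child initial stocks, with nonzero beta_ac:
  # the adult trajectory must be bit-identical
  p <- behavior_params()
  cfg <- sim_config(horizon = 52)
  t1 <- simulate_model(population_state(0.4, 0.3, 0.3, 0.9, 0.05, 0.05),
                       p, cfg)
  t2 <- simulate_model(population_state(0.4, 0.3, 0.3, 0.2, 0.5, 0.3),
                       p, cfg)
  adult_cols <- c("n_adult", "ow_adult", "ob_adult")
  expect_identical(t1[adult_cols], t2[adult_cols])
  expect_false(identical(t1$ow_child, t2$ow_child))
})

test_that("zero dynamics leave the trajectory constant", {
  p <- behavior_params(beta_aa = 0, beta_cc = 0, beta_ac = 0,
                       gamma_a = 0, gamma_c = 0,
                       rho_awl = 0, rho_cwl = 0, eps_awl = 0, eps_cwl = 0)
  init <- default_initial_state()
  traj <- simulate_model(init, p, sim_config(horizon = 52))
  for (nm in STATE_NAMES) {
    expect_equal(traj[[nm]], rep(init[[nm]], nrow(traj)))
  }
})

test_that("a disease-free state is a fixed point of the full dynamics", {
  init <- population_state(1, 0, 0, 1, 0, 0)
  traj <- simulate_model(init, behavior_params(), sim_config(horizon = 52))
  expect_equal(traj$child_prevalence_pct, rep(0, nrow(traj)))
  expect_equal(traj$adult_prevalence_pct, rep(0, nrow(traj)))
})

test_that("integrator matches the closed-form linear subsystem", {
  skip_if_not_installed("Matrix")
  p <- behavior_params(beta_aa = 0, beta_cc = 0, beta_ac = 0,
                       gamma_a = 0, gamma_c = 0)
  init <- default_initial_state()
  horizon <- 104
  exact <- linear_solution(init, p, horizon)

  rk4 <- simulate_model(init, p, sim_config(horizon = horizon,
                                            integrator = "rk4"))
  expect_lt(max(abs(as.numeric(state_at(rk4)) - exact)), 1e-6)

  # forward Euler is first order: halving dt roughly halves the error
  e1 <- max(abs(as.numeric(state_at(simulate_model(
    init, p, sim_config(dt = 0.5, horizon = horizon)))) - exact))
  e2 <- max(abs(as.numeric(state_at(simulate_model(
    init, p, sim_config(dt = 0.25, horizon = horizon)))) - exact))
  expect_lt(e2, e1)
  expect_equal(e1 / e2, 2, tolerance = 0.1)
})

test_that("step refinement and scheme choice agree on the final stocks", {
  init <- default_initial_state()
  f_euler <- as.numeric(state_at(simulate_model(init,
    config = sim_config(dt = 0.25))))
  f_half <- as.numeric(state_at(simulate_model(init,
    config = sim_config(dt = 0.125))))
  f_rk4 <- as.numeric(state_at(simulate_model(init,
    config = sim_config(dt = 0.25, integrator = "rk4"))))
  expect_lt(max(abs(f_euler - f_half)), 1e-4)
  expect_lt(max(abs(f_euler - f_rk4)), 1e-4)
})

test_that("increasing any transmission rate weakly increases child prevalence", {
  init <- default_initial_state()
  cfg <- sim_config(horizon = 260)
  grid_vals <- c(0.0005, 0.0015, 0.0025)
  for (beta in c("beta_aa", "beta_cc", "beta_ac")) {
    prev <- vapply(grid_vals, function(v) {
      p <- behavior_params()
      p[beta] <- v
      final_child_prev(simulate_model(init, p, cfg))
    }, numeric(1))
    expect_true(all(diff(prev) >= 0), info = beta)
  }
})

test_that("simulation rejects an oversized step that drives stocks negative", {
  # recovery much faster than the step allows: rho/p = 0.9/2 per week, dt = 4
  p <- behavior_params(beta_aa = 0, beta_cc = 0, beta_ac = 0,
                       gamma_a = 0, gamma_c = 0,
                       rho_awl = 0.9, rho_cwl = 0.9,
                       eps_awl = 0.9, eps_cwl = 0.9,
                       p_sa = 2, p_sc = 2, p_oa = 2, p_oc = 2)
  expect_error(
    simulate_model(population_state(0, 0.9, 0.1, 0, 0.9, 0.1),
                   p, sim_config(dt = 4, horizon = 52)),
    "dt")
})

test_that("prevalence and growth factor follow their definitions", {
  expect_equal(prevalence(population_state(1, 0, 0, 1, 0, 0), "child"), 0)
  expect_equal(prevalence(population_state(0.5, 0.25, 0.25,
                                           0.5, 0.25, 0.25), "child"), 50)
  expect_equal(prevalence(population_state(1, 0, 0, 0.34, 0.33, 0.33),
                          "child"), 66)
  expect_equal(prevalence(population_state(0.5, 0.25, 0.25, 1, 0, 0),
                          "adult"), 50)

  p0 <- behavior_params(beta_aa = 0, beta_cc = 0, beta_ac = 0,
                        gamma_a = 0, gamma_c = 0,
                        rho_awl = 0, rho_cwl = 0, eps_awl = 0, eps_cwl = 0)
  const <- simulate_model(default_initial_state(), p0, sim_config(horizon = 52))
  expect_equal(growth_factor(const, "child"), 1.0)

  zero <- simulate_model(population_state(1, 0, 0, 1, 0, 0), p0,
                         sim_config(horizon = 52))
  expect_error(growth_factor(zero, "child"), "initial prevalence is zero")
})

test_that("trajectories record the requested times", {
  traj <- simulate_model(default_initial_state(),
                         config = sim_config(dt = 0.25, horizon = 52,
                                             record_every = 4))
  expect_equal(traj$time_weeks, seq(0, 52, by = 4))
  expect_true(all(diff(traj$time_weeks) > 0))
})
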