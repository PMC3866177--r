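# Shared fixtures: random valid states/parameters and the independent
# closed-form oracle for the linear (beta = gamma = 0) subsystem.

random_state <- function() {
  a <- stats::runif(3); a <- a / sum(a)
  c <- stats::runif(3); c <- c / sum(c)
  population_state(a[1], a[2], a[3], c[1], c[2], c[3], tolerance = 1e-6)
}

random_params <- function() {
  behavior_params(
    beta_aa = stats::runif(1, 0, 0.003),
    beta_cc = stats::runif(1, 0, 0.003),
    beta_ac = stats::runif(1, 0, 0.004),
    gamma_a = stats::runif(1, 0, 0.002),
    gamma_c = stats::runif(1, 0, 0.002),
    rho_awl = stats::runif(1, 0, 0.5),
    rho_cwl = stats::runif(1, 0, 0.5),
    eps_awl = stats::runif(1, 0, 0.5),
    eps_cwl = stats::runif(1, 0, 0.5),
    p_sa = stats::runif(1, 20, 200),
    p_sc = stats::runif(1, 20, 200),
    p_oa = stats::runif(1, 20, 200),
    p_oc = stats::runif(1, 20, 200)
  )
}

# generator matrix of the linear recovery-only system (columns act on the
# state vector in canonical stock order); independent of the package's RHS
linear_system_matrix <- function(p) {
  A <- matrix(0, 6, 6)
  A[1, 2] <- p[["rho_awl"]] / p[["p_sa"]]
  A[2, 2] <- -p[["rho_awl"]] / p[["p_sa"]]
  A[2, 3] <- p[["eps_awl"]] / p[["p_oa"]]
  A[3, 3] <- -p[["eps_awl"]] / p[["p_oa"]]
  A[4, 5] <- p[["rho_cwl"]] / p[["p_sc"]]
  A[5, 5] <- -p[["rho_cwl"]] / p[["p_sc"]]
  A[5, 6] <- p[["eps_cwl"]] / p[["p_oc"]]
  A[6, 6] <- -p[["eps_cwl"]] / p[["p_oc"]]
  A
}

# closed-form solution at time t via matrix exponential
linear_solution <- function(initial, p, t) {
  as.numeric(Matrix::expm(linear_system_matrix(p) * t) %*% as.numeric(initial))
}

final_child_prev <- function(traj) {
  traj$child_prevalence_pct[nrow(traj)]
}
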