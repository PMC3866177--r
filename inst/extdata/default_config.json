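{
  "initial_state": {
    "n_adult": 0.312,
    "ow_adult": 0.331,
    "ob_adult": 0.357,
    "n_child": 0.682,
    "ow_child": 0.149,
    "ob_child": 0.169
  },
  "params": {
    "beta_aa": 0.0015,
    "beta_cc": 0.0015,
    "beta_ac": 0.00225,
    "gamma_a": 0.000769,
    "gamma_c": 0.000354,
    "rho_awl": 0.05,
    "rho_cwl": 0.12,
    "eps_awl": 0.05,
    "eps_cwl": 0.12,
    "p_sa": 66.2,
    "p_sc": 45.9,
    "p_oa": 113.5,
    "p_oc": 104
  },
  "intervention": {
    "magnitude": 0.5,
    "discount": 0.5,
    "psi_a": 0.5,
    "psi_c": 0.25,
    "ramp_horizon": 520
  },
  "simulation": {
    "dt": 0.25,
    "horizon": 520,
    "integrator": "euler",
    "record_every": 1
  }
}
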