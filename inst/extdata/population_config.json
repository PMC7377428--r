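{
  "v0_mean": 2,
  "v0_sd": 0.4,
  "beta_ev_mean": 0.3,
  "beta_ev_sd": 0.35,
  "beta_risk_base": 0.5,
  "risk_utility_gain": 3.5,
  "beta_risk_sd": 0.4,
  "drift_stim_noise_sd": 0.25,
  "A_mean": 0.7,
  "A_sd": 0.2,
  "A_min": 0.1,
  "bmA_mean": 0.35,
  "bmA_sd": 0.1,
  "bmA_min": 0.05,
  "t0_mean": 0.12,
  "t0_sd": 0.05,
  "t0_min": 0.02,
  "drift_sd": 1,
  "rho_mean": 0.7,
  "rho_sd": 0.2,
  "rho_min": 0.2,
  "rho_max": 1.5,
  "kappa_mean": 0.2,
  "kappa_sd": 0.1,
  "rating_noise_sd": 8,
  "stai_mean": 40,
  "stai_sd": 10
}
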