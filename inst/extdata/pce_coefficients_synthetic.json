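{
  "description": "SYNTHETIC example coefficient table for PCE-style scoring. These numbers are illustrative placeholders exercising the schema (sex-only strata, log-transformed terms, one interaction, mean linear predictor, baseline survival); they are NOT the published pooled-cohort-equation coefficients. Supply a published table in the same schema for real scoring.",
  "synthetic": true,
  "strata": {
    "female": {
      "coefficients": {
        "log_age": 17.0,
        "log_total_chol": 1.0,
        "log_hdl": -1.7,
        "log_sbp_treated": 2.0,
        "log_sbp_untreated": 1.8,
        "smoking": 0.65,
        "diabetes": 0.85,
        "log_age:log_total_chol": -0.2
      },
      "mean_lp": 74.0,
      "s0": 0.966
    },
    "male": {
      "coefficients": {
        "log_age": 12.0,
        "log_total_chol": 1.1,
        "log_hdl": -0.9,
        "log_sbp_treated": 1.9,
        "log_sbp_untreated": 1.7,
        "smoking": 0.7,
        "diabetes": 0.7,
        "log_age:log_total_chol": -0.15
      },
      "mean_lp": 58.0,
      "s0": 0.914
    }
  }
}
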