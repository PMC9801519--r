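{
  "junior_paper": {
    "stage": "junior",
    "n": 8191,
    "intercept": 4.6,
    "noise_sd": 0.61,
    "seed": 1,
    "covariates": [
      {"name": "exercise", "mean": 2.72, "sd": 1.01, "support": "days07", "beta": 0.0177},
      {"name": "bullying", "mean": 10.66, "sd": 1.35, "support": "positive", "beta": 0},
      {"name": "m_stress", "mean": 30.11, "sd": 8.68, "support": "positive", "beta": 0},
      {"name": "network", "mean": 17.43, "sd": 1.10, "support": "positive", "beta": 0},
      {"name": "diet", "mean": 9.43, "sd": 1.43, "support": "positive", "beta": 0}
    ]
  },
  "senior_paper": {
    "stage": "senior",
    "n": 5901,
    "intercept": 4.41,
    "noise_sd": 0.615,
    "seed": 1,
    "covariates": [
      {"name": "exercise", "mean": 2.31, "sd": 1.039, "support": "days07", "beta": 0.0196},
      {"name": "bullying", "mean": 10.46, "sd": 1.08, "support": "positive", "beta": 0},
      {"name": "m_stress", "mean": 31.34, "sd": 8.95, "support": "positive", "beta": 0},
      {"name": "network", "mean": 17.2, "sd": 1.39, "support": "positive", "beta": 0},
      {"name": "diet", "mean": 9.67, "sd": 1.37, "support": "positive", "beta": 0}
    ]
  },
  "primary_null": {
    "stage": "primary",
    "n": 8457,
    "intercept": 4.79,
    "noise_sd": 0.565,
    "seed": 1,
    "covariates": [
      {"name": "exercise", "mean": 2.88, "sd": 1.02, "support": "days07", "beta": 0},
      {"name": "diet", "mean": 9.13, "sd": 1.41, "support": "positive", "beta": 0},
      {"name": "bullying", "mean": 10.78, "sd": 1.44, "support": "positive", "beta": 0},
      {"name": "sleep", "mean": 8.86, "sd": 1.10, "support": "positive", "beta": 0},
      {"name": "network", "mean": 9.00, "sd": 1.82, "support": "positive", "beta": 0}
    ]
  },
  "strong_single": {
    "stage": "junior",
    "n": 8191,
    "intercept": 4.6,
    "noise_sd": 0.61,
    "seed": 1,
    "covariates": [
      {"name": "exercise", "mean": 2.72, "sd": 1.01, "support": "days07", "beta": 0},
      {"name": "bullying", "mean": 10.66, "sd": 1.35, "support": "positive", "beta": 0.03},
      {"name": "m_stress", "mean": 30.11, "sd": 8.68, "support": "positive", "beta": 0},
      {"name": "network", "mean": 17.43, "sd": 1.10, "support": "positive", "beta": 0},
      {"name": "diet", "mean": 9.43, "sd": 1.43, "support": "positive", "beta": 0}
    ]
  },
  "pure_null": {
    "stage": "junior",
    "n": 2000,
    "intercept": 4.6,
    "noise_sd": 0.61,
    "seed": 1,
    "covariates": [
      {"name": "exercise", "mean": 2.72, "sd": 1.01, "support": "days07", "beta": 0},
      {"name": "bullying", "mean": 10.66, "sd": 1.35, "support": "positive", "beta": 0},
      {"name": "m_stress", "mean": 30.11, "sd": 8.68, "support": "positive", "beta": 0},
      {"name": "network", "mean": 17.43, "sd": 1.10, "support": "positive", "beta": 0},
      {"name": "diet", "mean": 9.43, "sd": 1.43, "support": "positive", "beta": 0}
    ]
  }
}
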