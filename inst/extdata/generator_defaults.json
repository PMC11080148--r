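{
  "note": "Default distribution fixtures for the synthetic cohort generator. The source registries publish no distributions for these variables; the values below are plausible for a colorectal-surgery population and exist to make the pipeline testable, not to model real cohorts.",
  "rectum_fraction": 0.35,
  "referred_fraction": 0.1,
  "neoadjuvant_fraction": 0.25,
  "complication_prob": 0.3,
  "waiting_time_days": {"name": "normal", "mean": 28, "sd": 14, "min": 0, "max": 120, "integer": true},
  "age": {"name": "normal", "mean": 68, "sd": 10, "min": 18, "max": 95, "integer": true},
  "bmi": {"name": "lognormal", "meanlog": 3.258, "sdlog": 0.15, "min": 14, "max": 55, "digits": 1},
  "charlson": {"name": "poisson", "lambda": 1.5, "max": 12},
  "asa": {"name": "categorical", "values": [1, 2, 3, 4], "probs": [0.15, 0.55, 0.27, 0.03]},
  "preop_complication": {"name": "bernoulli", "prob": 0.2}
}
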