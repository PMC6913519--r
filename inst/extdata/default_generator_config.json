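{
  "n_subjects": 100000,
  "n_cohorts": 8,
  "seed": 190801,
  "age_range": [25, 80],
  "age_normal": {
    "mean": 50.5,
    "sd": 14
  },
  "sex_fraction_female": 0.487,
  "exam_year_range": [1970, 2013],
  "nonhdl_lognormal": {
    "meanlog": 1.459,
    "sdlog": 0.294
  },
  "hdl_lognormal": {
    "meanlog": 0.262,
    "sdlog": 0.278
  },
  "lipid_copula_rho": -0.2,
  "bmi_normal": {
    "mean": 26,
    "sd": 4.2
  },
  "sbp_normal": {
    "mean": 128,
    "sd": 16
  },
  "sbp_hypertension_shift": 15,
  "prevalences": {
    "smoking": 0.333,
    "diabetes": 0.048,
    "hypertension": 0.401,
    "antihypertensive": 0.15,
    "lipid_lowering": 0.049
  },
  "cvd_hazard": {
    "shape": 6.2,
    "scale": 103,
    "loghr": {
      "male": 0.5,
      "smoking": 0.5,
      "diabetes": 0.5,
      "bmi": 0.015,
      "sbp": 0.008,
      "antihypertensive": 0.1,
      "nonhdl": 0.22
    },
    "exposure_type": "linear",
    "category_loghr": null,
    "centers": {
      "bmi": 26,
      "sbp": 130,
      "nonhdl": 4.3
    }
  },
  "death_hazard": {
    "shape": 8.5,
    "scale": 97,
    "loghr": {
      "male": 0.4,
      "smoking": 0.7,
      "diabetes": 0.5,
      "bmi": 0.01,
      "sbp": 0.004,
      "antihypertensive": 0.05,
      "nonhdl": 0
    },
    "exposure_type": "linear",
    "category_loghr": null,
    "centers": {
      "bmi": 26,
      "sbp": 130,
      "nonhdl": 4.3
    }
  },
  "admin_censoring_years": [5, 30],
  "cohort_frailty_sd": 0.1,
  "treatment_deflation": 1.3
}
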