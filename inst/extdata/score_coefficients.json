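{
  "version": "1.0",
  "ishii": {
    "citation": "Ishii S, Tanaka T, Shibasaki K, et al. Development of a simple screening test for sarcopenia in older adults. Geriatr Gerontol Int 2014;14(Suppl 1):93-101.",
    "notes": "Chart points: score = sum of coef * (value - center) per sex. Score-to-probability uses a logistic interpolation of the published chart: p = plogis((score - midpoint) / scale), with the high-risk threshold taken as the 50% midpoint and 10 chart points per logit; flagged in outputs as probability_method.",
    "probability_method": "logistic_interpolation",
    "male": {
      "high_risk_threshold": 105,
      "logistic_midpoint": 105,
      "logistic_scale": 10,
      "terms": {
        "age":  {"coef": 0.62,  "center": 64, "unit": "years"},
        "grip": {"coef": -3.09, "center": 50, "unit": "kg"},
        "calf": {"coef": -4.64, "center": 42, "unit": "cm"}
      }
    },
    "female": {
      "high_risk_threshold": 120,
      "logistic_midpoint": 120,
      "logistic_scale": 10,
      "terms": {
        "age":  {"coef": 0.80,  "center": 64, "unit": "years"},
        "grip": {"coef": -5.09, "center": 34, "unit": "kg"},
        "calf": {"coef": -3.28, "center": 42, "unit": "cm"}
      }
    }
  },
  "phenoage": {
    "citation": "Levine ME, Lu AT, Quach A, et al. An epigenetic biomarker of aging for lifespan and healthspan. Aging (Albany NY) 2018;10:573-591.",
    "notes": "Linear predictor xb on the Gompertz mortality scale; 10-year mortality risk M = 1 - exp(-exp(xb) * (exp(gamma * t) - 1) / gamma) with t = 120 months; PhenoAge = a + ln(-b * ln(1 - M)) / c.",
    "intercept": -19.9067,
    "gamma": 0.0076927,
    "time_months": 120,
    "transform": {"a": 141.50225, "b": 0.00553, "c": 0.090165},
    "terms": {
      "albumin":              {"coef": -0.0336,  "unit": "g/L",             "transform": "identity"},
      "creatinine":           {"coef": 0.0095,   "unit": "umol/L",          "transform": "identity"},
      "glucose":              {"coef": 0.1953,   "unit": "mmol/L",          "transform": "identity"},
      "crp":                  {"coef": 0.0954,   "unit": "mg/dL",           "transform": "log"},
      "lymphocyte_pct":       {"coef": -0.0120,  "unit": "%",               "transform": "identity"},
      "mcv":                  {"coef": 0.0268,   "unit": "fL",              "transform": "identity"},
      "rdw_pct":              {"coef": 0.3306,   "unit": "%",               "transform": "identity"},
      "alkaline_phosphatase": {"coef": 0.00188,  "unit": "U/L",             "transform": "identity"},
      "wbc":                  {"coef": 0.0554,   "unit": "1000 cells/uL",   "transform": "identity"},
      "age":                  {"coef": 0.0804,   "unit": "years",           "transform": "identity"}
    },
    "cohort_unit_conversions": {
      "albumin": {"from": "g/dL", "factor": 10},
      "creatinine": {"from": "mg/dL", "factor": 88.4017},
      "glucose": {"from": "mg/dL", "factor": 0.0555}
    }
  }
}
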