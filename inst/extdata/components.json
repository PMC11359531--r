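[
  {
    "name": "protopin",
    "content_per_tablet": 0.1742,
    "oral_dose": 1896,
    "iv_dose": 168.062,
    "m0_over_v0": 0.00418,
    "solubilities": {
      "phosphate_pH6.8": 0.535,
      "acetate_pH4.5": 5.403,
      "HCl_0.1M": 4.700,
      "water": 0.07212
    },
    "peff": 7.49e-06
  },
  {
    "name": "alpha-allocryptopine",
    "content_per_tablet": 1.1042,
    "oral_dose": 917,
    "iv_dose": 297.16,
    "m0_over_v0": 0.0265,
    "solubilities": {
      "phosphate_pH6.8": 0.0447,
      "acetate_pH4.5": 0.0458,
      "HCl_0.1M": 0.0487,
      "water": 2.37609
    },
    "peff": 1.34e-05
  },
  {
    "name": "byakangelicin",
    "content_per_tablet": 0.0975,
    "oral_dose": 2783,
    "iv_dose": 78.68,
    "m0_over_v0": 0.00234,
    "solubilities": {
      "phosphate_pH6.8": 0.00763,
      "acetate_pH4.5": 1.291,
      "HCl_0.1M": 2.662,
      "water": 0.0359
    },
    "peff": 8.95e-06
  },
  {
    "name": "tetrahydropalmatine",
    "content_per_tablet": 0.3017,
    "oral_dose": 2500,
    "iv_dose": 19.75,
    "m0_over_v0": 0.00724,
    "solubilities": {
      "phosphate_pH6.8": 0.0197,
      "acetate_pH4.5": 2.666,
      "HCl_0.1M": 0.655,
      "water": 0.01887
    },
    "peff": 3.76e-06
  },
  {
    "name": "corydaline",
    "content_per_tablet": 0.2871,
    "oral_dose": 963,
    "iv_dose": 4.54,
    "m0_over_v0": 0.00689,
    "solubilities": {
      "phosphate_pH6.8": 2.385,
      "acetate_pH4.5": 2.385,
      "HCl_0.1M": 2.385,
      "water": 0.00503
    },
    "peff": 3.94e-06,
    "censored": ["acetate_pH4.5", "HCl_0.1M"]
  }
]
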