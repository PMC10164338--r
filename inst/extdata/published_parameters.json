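{
  "kg": 0.44,
  "kk": 0.3,
  "alpha": 0.06,
  "alpha_beta_ratio": "Inf",
  "inhibition": "linear",
  "gamma": {"study1": 0.027, "study2": 0.044, "study3": 0.02},
  "v0": {"study1": 26, "study2": 44, "study3": 22},
  "potency": {
    "Rs1": {"a": 0.65, "b": 0.26},
    "Rs2": {"a": 0.2, "b": 0.4},
    "Rs3": {"a": 0.14, "b": 0.16}
  },
  "bsv": {"gamma": 64, "alpha": 50, "v0": 40, "convention": "sd_times_100"},
  "sigma": {"prop": 0.35, "add": 4.4},
  "gamma_dose_scale": 10
}
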