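{
  "os_family": "weibull",
  "os_params": {
    "shape": 1.3,
    "scale": 45
  },
  "prog_family": "weibull",
  "prog_params": {
    "shape": 1.1,
    "scale": 10
  },
  "hr_os": 0.55,
  "hr_pfs": 0.28,
  "n_per_arm": 120,
  "censor_months": 24,
  "seed": 60912,
  "hr_mode": "truth"
}
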