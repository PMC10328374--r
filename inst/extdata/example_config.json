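{
  "seed": 1,
  "n_per_group": {
    "C57Bl/6J": 5,
    "TallyHO": 8
  },
  "n_slices": 4,
  "voxel_size": 0.006,
  "points_per_region": 3,
  "bending": {
    "span_mm": 7,
    "preload_N": 2,
    "yield_secant_fraction": 0.1,
    "failure_drop_fraction": 0.1
  },
  "indenter": {
    "epsilon": 0.75,
    "beta": 1,
    "E_indenter": 1141,
    "nu_indenter": 0.07,
    "nu_sample": 0.3,
    "max_load_uN": 1000,
    "load_rate_uN_s": 100,
    "hold_s": 30
  },
  "raman": {
    "rcf_radius": 450,
    "rcf_iterations": 3,
    "step": 1
  },
  "stats": {
    "diabetic_glucose_threshold": 250
  },
  "log_level": "info"
}
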