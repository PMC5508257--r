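{
  "version": "1.3",
  "populations": [
    "SS",
    "SP",
    "II",
    "DP"
  ],
  "kappa_hz": [
    160,
    160,
    12,
    16
  ],
  "g_base": {
    "ss_self": 1400,
    "sp_to_ss": 200,
    "ii_to_ss": 700,
    "ss_to_sp": 200,
    "sp_self": 6000,
    "ss_to_ii": 150,
    "dp_to_ii": 50,
    "ii_self": 3500,
    "sp_to_dp": 150,
    "ii_to_dp": 100,
    "dp_self": 300
  },
  "a_base": {
    "asc_ss": 1600,
    "asc_dp": 800,
    "desc_sp": 300,
    "desc_ii": 150
  },
  "sigmoid_rho": 2,
  "sigmoid_rmax": 2,
  "input_amp_base": 70,
  "input_exponent_base": 1.5,
  "input_white_floor": 0.05,
  "noise_white_base": 1e-08,
  "noise_pink_base": 2e-07,
  "input_amp_ratio": [
    1,
    0.1
  ]
}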