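{
  "cell": {
    "Li_out": 15,
    "delta_out": 15,
    "pH_in0": 6.0,
    "Na_out": 0,
    "temp_K": 310
  },
  "membrane": {
    "P7": 5e-11,
    "rho_ch": 1.004354
  },
  "exchanger": {
    "K_Li": 4.7244,
    "gamma_on": 1.03062,
    "gamma_off": 0.99653,
    "alpha_kie": 0.95,
    "n_scale": 7.2927e-19
  }
}
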