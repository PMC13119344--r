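{
  "feature_names": ["alpha_n", "tau_n", "alpha_c", "tau_c", "contact_density", "fr2_rsa_key"],
  "mu": [-62.09, 126.22, -13.31, 109.68, 0.29, 0.14],
  "sigma": [133.53, 11.47, 101.63, 13.78, 0.31, 0.09],
  "w": [0.11, 0.60, 0.48, -0.42, 1.86, -1.16],
  "b": -0.352
}
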