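{
  "species": {
    "radius": 0.5,
    "molar_mass": 65500,
    "v_bar": 1.0
  },
  "interaction": {
    "L": 1.25,
    "eps_star": -1.0
  },
  "grids": {
    "phi_min": 0.01,
    "phi_max": 0.4,
    "phi_step": 0.01,
    "eps_grid": [-1.9, -1.8, -1.7, -1.6, -1.5, -1.4]
  }
}
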