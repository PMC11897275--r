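{
  "name": "synthetic-victim-low-fm",
  "note": "Synthetic exemplar victim (not a published drug): CYP3A4-minor substrate, fm = 0.25.",
  "compound": {
    "molecular_weight": 400,
    "log_d": 2.0,
    "pka_values": [],
    "aqueous_solubility": 10,
    "solubility_ph": 7.0,
    "particle_radius": 25,
    "precipitation_time": 900,
    "peff": 3.0,
    "rbp": 1.0,
    "fup": 0.1
  },
  "disposition": {
    "vc": 1.0,
    "k12": 0,
    "k21": 0
  },
  "clearance": {
    "cl_cyp3a4_hepatic": 0.025,
    "vmax_mode": "linear",
    "cl_other_hepatic": 0.075,
    "cl_renal": 0,
    "fm_cyp3a4": 0.25,
    "fg": 1.0
  }
}
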