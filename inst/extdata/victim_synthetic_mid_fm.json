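{
  "name": "synthetic-victim-mid-fm",
  "note": "Synthetic exemplar victim (not a published drug): mixed-clearance CYP3A4 substrate, fm = 0.60, moderate gut extraction.",
  "compound": {
    "molecular_weight": 400,
    "log_d": 2.5,
    "pka_values": [],
    "aqueous_solubility": 5,
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
    "cl_cyp3a4_hepatic": 0.06,
    "vmax_mode": "linear",
    "cl_other_hepatic": 0.04,
    "cl_renal": 0,
    "fm_cyp3a4": 0.6,
    "fg": 0.8
  }
}
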