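{
  "_meta": {
    "description": "Tissue-level fracture thresholds. quantity = 'strain' compares maximum principal strain (dimensionless); quantity = 'stress' compares maximum principal stress (MPa)."
  },
  "skull_tables_fracture":    {"quantity": "strain", "threshold": 0.0088, "units": ""},
  "skull_diploe_fracture":    {"quantity": "stress", "threshold": 20,     "units": "MPa"},
  "facial_cortical_fracture": {"quantity": "strain", "threshold": 0.0078, "units": ""},
  "facial_spongy_fracture":   {"quantity": "stress", "threshold": 20,     "units": "MPa"},
  "nose_septal_fracture":     {"quantity": "strain", "threshold": 0.0078, "units": ""}
}
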