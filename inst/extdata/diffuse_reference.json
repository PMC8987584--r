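{
  "_meta": {
    "description": "Reference response levels for diffuse brain injury in white matter (averaged over subcortical white matter, corpus callosum, brainstem). No fitted risk curve exists; these are qualitative reference levels.",
    "units": {"mps": "", "mpsr": "1/s", "product": "1/s"}
  },
  "low_risk":  {"mps": 0.65, "mpsr": 61.52, "product": 22.43, "label": "AIS 2 concussion reference (low risk)"},
  "ais4plus":  {"mps": 0.74, "mpsr": 213,   "product": 107,   "label": "AIS 4+ diffuse brain injury reference (high risk)"}
}
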