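{
  "_meta": {
    "description": "Fixed crash-induced injury index (CII) risk functions. Logistic: P(t) = 1/(1 + exp(-(kappa*t + delta))). Weibull: P(t) = 1 - exp(-(t/scale)^shape).",
    "provenance": "paper-fixed"
  },
  "contusion_logistic_v6": {
    "family": "logistic", "kappa": 0.02394, "delta": -3.8606,
    "predictor": "coup intracranial pressure", "units": "kPa"
  },
  "contusion_weibull_v6": {
    "family": "weibull", "scale": 244.92, "shape": 5.29,
    "predictor": "coup intracranial pressure", "units": "kPa"
  },
  "asdh_logistic_v6": {
    "family": "logistic", "kappa": 9.184, "delta": -4.195,
    "predictor": "bridging-vein stretch ratio", "units": ""
  },
  "asdh_weibull_v6": {
    "family": "weibull", "scale": 0.6181, "shape": 5.3232,
    "predictor": "bridging-vein stretch ratio", "units": ""
  }
}
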