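{
  "_meta": {
    "description": "Brain material parameter registry for the anisotropic visco-hyperelastic model, plus extracranial linear/viscoelastic constants (stored, not simulated).",
    "units": {
      "rho": "g/cm^3",
      "c1": "kPa", "c2": "kPa", "c3": "kPa", "c5": "kPa", "c6": "kPa",
      "c4": "dimensionless", "lambda_star": "dimensionless",
      "k_bulk": "GPa", "beta_s": "1/ms", "beta_p": "1/ms"
    },
    "notes": "c6 is derived at load time from stress continuity at lambda_star. beta_s interpreted as 1/ms (millisecond time base). c5 treated as kPa."
  },
  "brain": {
    "subcortical_white_matter": {
      "rho": 1.06, "c1": -2.19, "c2": 3.29, "c3": 1.06, "c4": 35.6,
      "c5": 1.06, "lambda_star": 1.06, "k_bulk": 0.154, "beta_s": 0.005,
      "fiber_dir": [1, 0, 0]
    },
    "corpus_callosum": {
      "rho": 1.06, "c1": -2.74, "c2": 4.11, "c3": 1.60, "c4": 35.6,
      "c5": 1.06, "lambda_star": 1.06, "k_bulk": 0.1764, "beta_s": 0.005,
      "fiber_dir": [1, 0, 0]
    },
    "brainstem": {
      "rho": 1.06, "c1": -4.57, "c2": 6.86, "c3": 1.80, "c4": 50,
      "c5": 2.0, "lambda_star": 1.06, "k_bulk": 0.168, "beta_s": 0.005,
      "fiber_dir": [0, 0, 1]
    },
    "gray_matter": {
      "rho": 1.06, "c1": -2.19, "c2": 3.29, "c3": 0, "c4": 0,
      "c5": 0, "lambda_star": 0, "k_bulk": 0.154, "beta_s": 0.005
    },
    "csf": {
      "rho": 1.04, "c1": 0.212, "c2": 0, "c3": 0, "c4": 0,
      "c5": 0, "lambda_star": 0, "k_bulk": 0.034, "beta_s": 0.005
    }
  },
  "extracranial": {
    "_units": {
      "density": "g/cm^3", "youngs": "GPa", "poisson": "dimensionless",
      "yield_stress": "GPa", "tangent": "dimensionless",
      "failure_mps": "dimensionless", "bulk": "GPa",
      "g_short": "MPa", "g_long": "MPa", "decay": "1/s"
    },
    "skull_tables":   {"density": 2.1, "youngs": 15,   "poisson": 0.25, "yield_stress": 0.09,   "tangent": 0.5,   "failure_mps": 0.0088},
    "skull_diploe":   {"density": 1.0, "youngs": 0.6,  "poisson": 0.30, "yield_stress": 0.004,  "tangent": 0.02},
    "facial_cortical":{"density": 2.1, "youngs": 6,    "poisson": 0.25, "yield_stress": 0.05,   "tangent": 0.3,   "failure_mps": 0.0078},
    "facial_spongy":  {"density": 2.1, "youngs": 0.3,  "poisson": 0.25, "yield_stress": 0.006,  "tangent": 0.03},
    "nose_septal":    {"density": 2.1, "youngs": 0.02, "poisson": 0.45, "yield_stress": 0.0002, "tangent": 0.005, "failure_mps": 0.0078},
    "facial_flesh":   {"density": 1.1, "bulk": 0.005, "g_short": 0.68, "g_long": 0.28, "decay": 0.03},
    "scalp":          {"density": 1.1, "bulk": 0.02,  "g_short": 8.5,  "g_long": 3.4,  "decay": 0.03}
  }
}
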