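# Synthetic-data presets, version-pinned so tests and examples agree on
# the generating conditions. Units: time ms, length mm, stress kPa.
version: 1
marker_field:
  pmhs:
    # Homogeneous in-plane stretch pulse tuned to the PMHS NDT-cluster
    # amplitude: peak GMPS 0.076 => peak stretch sqrt(1 + 2*0.076).
    # Marker jitter 0.02 mm, within x-ray NDT tracking precision, keeps
    # the strain-domain noise well below the experimental scatter.
    mode: scale
    n_time: 101
    t_end_ms: 40
    peak_gmps: 0.076
    noise_sd_mm: 0.02
    rigid_rotation_deg: 5
    rigid_translation_mm: 2
  quiet:
    mode: scale
    n_time: 51
    t_end_ms: 40
    peak_gmps: 0
    noise_sd_mm: 0
    rigid_rotation_deg: 0
    rigid_translation_mm: 0
case_table:
  asdh:
    # Bridging-vein stretch-ratio groups; means from the ASDH case set,
    # common sd chosen to give overlapping groups.
    kind: two_group
    mean_injury: 0.533
    mean_no_injury: 0.268
    sd_injury: 0.12
    sd_no_injury: 0.12
    n_injury: 6
    n_no_injury: 9
  contusion:
    # Coup-ICP groups bracketing the 161 kPa 50%-risk threshold.
    kind: two_group
    mean_injury: 210
    mean_no_injury: 110
    sd_injury: 50
    sd_no_injury: 40
    n_injury: 8
    n_no_injury: 5
  asdh_logistic_generative:
    kind: logistic
    kappa: 9.184
    delta: -4.195
    n_cases: 500
    predictor_min: 0.05
    predictor_max: 0.9
  asdh_weibull_generative:
    kind: weibull
    scale: 0.6181
    shape: 5.3232
    n_cases: 1000
signal_pair:
  pulse:
    # Damped-sinusoid reference resembling an impact response trace.
    n_time: 201
    t_end_ms: 40
    amplitude: 1.0
    freq_khz: 0.05      # 50 Hz
    tau_ms: 12
    scale: 1.0
    shift_ms: 0.0
    noise_sd: 0.0
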