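{
  "knots": {
    "hip": {
      "pct": [0, 50, 100],
      "deg": [30, -10, 30]
    },
    "knee": {
      "pct": [0, 15, 42, 73, 100],
      "deg": [5, 18, 5, 60, 5]
    },
    "ankle": {
      "pct": [0, 45, 60, 100],
      "deg": [0, 10, -15, 0]
    }
  },
  "pelvis_tilt_deg": 0,
  "pelvis_osc_amp": 0.02,
  "pelvis_fore_aft_amp": 0.014,
  "cadence_slope": 43,
  "cadence_intercept": 65,
  "stance_fraction": 0.6,
  "smooth_sd": 2,
  "interp": ["spline", "smooth", "smooth"],
  "pelvis_vert_phase": 0.045,
  "trunk_lean_deg": 5,
  "cop_rollover": {
    "s": [0, 0.15, 0.5, 0.75, 0.88, 1],
    "u": [0, 0.15, 0.28, 0.5, 1, 1]
  }
}
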