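{
  "geometry": {
    "centerline_radius_mm": 2.343,
    "duct_diameter_mm": 0.45,
    "duct_angle_rad": 4.6,
    "ampulla_angle_rad": 0.2,
    "utricle_lumen_radius_mm": 0.413,
    "ampulla_lumen_radius_mm": 0.45,
    "osseous_canal_diameter_mm": 1.53,
    "dilation_factor": 2.8889,
    "utricular_dilation_factor": 3
  },
  "density": 1000,
  "kinematic_viscosity": 1e-06,
  "filter_cutoff_hz": 30,
  "window_threshold_dps": 20,
  "conversion": 0.056,
  "vor_gain": 1,
  "reference_label": "IV"
}
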