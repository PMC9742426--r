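{
  "grid_step": 0.5,
  "grid_padding": 12,
  "bulk_shell": [8.0, 10.0],
  "min_density": 2.0,
  "site_radius": 1.4,
  "cylinder_diameter": 4.0,
  "angle_step": 20,
  "capture_radius": 1.4,
  "survival_mode": "continuous",
  "superstructured_threshold": 1000,
  "contact_cutoff": 3.5,
  "hbond_dist": 3.5,
  "hbond_angle": 150,
  "seed": 1
}
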