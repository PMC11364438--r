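[
  {"label": "male_sham",            "mean_speed": 20.0, "speed_shape": 6, "heading_sd": 15.0, "pause_prob": 0.020, "startle_latency_mean": 0.3, "hazard_scale": 1.2e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "male_D3Inj",           "mean_speed": 19.0, "speed_shape": 6, "heading_sd": 17.0, "pause_prob": 0.030, "startle_latency_mean": 0.3, "hazard_scale": 1.2e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "male_D17Inj",          "mean_speed": 15.0, "speed_shape": 6, "heading_sd": 25.0, "pause_prob": 0.080, "startle_latency_mean": 0.3, "hazard_scale": 1.2e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "male_D31Inj",          "mean_speed": 10.0, "speed_shape": 6, "heading_sd": 40.0, "pause_prob": 0.150, "startle_latency_mean": 0.3, "hazard_scale": 1.2e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "female_mated_sham",    "mean_speed": 13.0, "speed_shape": 6, "heading_sd": 18.0, "pause_prob": 0.020, "startle_latency_mean": 0.3, "hazard_scale": 1.0e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "female_mated_D3Inj",   "mean_speed": 11.5, "speed_shape": 6, "heading_sd": 24.0, "pause_prob": 0.050, "startle_latency_mean": 0.3, "hazard_scale": 1.0e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "female_mated_D17Inj",  "mean_speed": 9.5,  "speed_shape": 6, "heading_sd": 32.0, "pause_prob": 0.100, "startle_latency_mean": 0.3, "hazard_scale": 1.0e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "female_mated_D31Inj",  "mean_speed": 6.5,  "speed_shape": 6, "heading_sd": 50.0, "pause_prob": 0.180, "startle_latency_mean": 0.3, "hazard_scale": 1.0e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "female_virgin_sham",   "mean_speed": 13.0, "speed_shape": 6, "heading_sd": 18.0, "pause_prob": 0.020, "startle_latency_mean": 0.3, "hazard_scale": 0.8e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "female_virgin_D3Inj",  "mean_speed": 12.8, "speed_shape": 6, "heading_sd": 18.5, "pause_prob": 0.025, "startle_latency_mean": 0.3, "hazard_scale": 0.8e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "female_virgin_D17Inj", "mean_speed": 12.6, "speed_shape": 6, "heading_sd": 19.0, "pause_prob": 0.030, "startle_latency_mean": 0.3, "hazard_scale": 0.8e-4, "hazard_shape": 0.10, "n_flies_default": 15},
  {"label": "female_virgin_D31Inj", "mean_speed": 12.4, "speed_shape": 6, "heading_sd": 19.5, "pause_prob": 0.035, "startle_latency_mean": 0.3, "hazard_scale": 0.8e-4, "hazard_shape": 0.10, "n_flies_default": 15}
]
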