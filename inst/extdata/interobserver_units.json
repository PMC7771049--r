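[
  {"label": "user1", "per_trial_mm": [0.65, 0.77, 0.71]},
  {"label": "user2", "per_trial_mm": [1.20, 1.44, 1.32]},
  {"label": "user3", "per_trial_mm": [0.55, 0.67, 0.61]},
  {"label": "user4", "per_trial_mm": [0.51, 0.63, 0.57]},
  {"label": "user5", "per_trial_mm": [0.81, 0.93, 0.87]}
]
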