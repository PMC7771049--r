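[
  {"label": "patient1", "per_trial_mm": [0.82, 0.98, 0.86, 0.94, 0.90]},
  {"label": "patient2", "per_trial_mm": [1.10, 1.30, 1.15, 1.25, 1.20]},
  {"label": "patient3", "per_trial_mm": [0.50, 0.66, 0.54, 0.62, 0.58]}
]
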