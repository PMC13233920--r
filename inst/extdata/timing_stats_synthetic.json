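{
  "note": "SYNTHETIC example timing statistics for the timing bonus. Duty-cycle means are the experimentally reported values for lobster preparations; the standard deviations and phase statistics are invented placeholders, NOT experimental data. Supply real statistics for scientific use.",
  "duty_mean": {"LP": 0.264, "PY": 0.348, "PD": 0.385},
  "duty_sd": {"LP": 0.05, "PY": 0.05, "PD": 0.05},
  "phase_mean": {"LP": 0.34, "PY": 0.54},
  "phase_sd": {"LP": 0.05, "PY": 0.05}
}
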