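{
  "version": "1.0",
  "comment": "Calibrated case-like / control-like generator settings; synthetic, illustrative only.",
  "case": {
    "hr_baseline": 79.5,
    "hr_baseline_sd": 10.0,
    "hr_circadian_amp": 5.0,
    "hr_activity_gain": 25.0,
    "hr_noise_sd": 12.0,
    "act_day_level": 0.05,
    "act_level_sd": 0.25,
    "act_burst_rate": 3.0,
    "act_burst_scale": 0.14,
    "act_night_level": 0.01,
    "mse_roughness": 0.88,
    "sleep_onset_jitter_sd": 1.0
  },
  "control": {
    "hr_baseline": 74.5,
    "hr_baseline_sd": 6.0,
    "hr_circadian_amp": 5.0,
    "hr_activity_gain": 25.0,
    "hr_noise_sd": 12.0,
    "act_day_level": 0.1,
    "act_level_sd": 0.25,
    "act_burst_rate": 4.0,
    "act_burst_scale": 0.18,
    "act_night_level": 0.01,
    "mse_roughness": 0.55,
    "sleep_onset_jitter_sd": 0.5
  }
}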