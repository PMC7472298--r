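sample_rate_hz: 200.0
bs_mean: 1.163
bs_sd: 0.221
ds_mean: 0.317
ds_sd: 0.046
ft_mean: 0.67
ft_sd: 0.112
dur_bounds:
  bs:
  - 0.1
  - 2.1
  ds:
  - 0.1
  - 0.55
  ft:
  - 0.1
  - 0.93
bf_pad_s: 2.3
af_pad_s: 0.8
lag_s:
  waist: 0.0
  head: 0.015
  wrist: 0.03
acc_scale:
  wrist: 1.0
  head: 1.0
  waist: 1.0
gyro_scale:
  wrist: 1.0
  head: 1.0
  waist: 1.0
impact_amp_g:
  wrist: 12.0
  head: 0.3
  waist: 7.0
impact_decay_s:
  wrist: 0.05
  head: 0.02
  waist: 0.015
impact_freq_hz:
  wrist: 8.0
  head: 0.0
  waist: 0.0
speed_peak_mps:
  driver: 42.0
  iron7: 36.0
bs_speed_peak_mps: 5.0
noise_acc_g: 0.05
noise_gyro_dps: 8.0
subject_amp_sdlog: 0.15
subject_lag_sd: 0.015
subject_dur_sdlog: 0.06
jump_amp_g:
  wrist: 2.0
  head: 0.5
  waist: 0.9
jump_time_s: 0.45
jump_width_s: 0.03
seed: 1
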