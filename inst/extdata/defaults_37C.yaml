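kinetics:
  tau1: 12.0
  slope_m: 0.015550964625
  alpha_max: 0.676180909153
  delta_a: 0.13025725869
  tau_pers: 23.282231109236
  pers_shape: 5.878984670765
  tau_reacid: 1.6
  n_vesicles: 1200.0
  p_release: 0.05
  reprime_s: 2.0
  surface_frac: 0.02
  noise_sd: 16.45
  quench_ratio: 20.0
population:
  tau1_cv: 0.3
  slope_cv: 0.5
fit:
  offset_t0: 2.5
  window_len: 60.0
temperature: 37C
calibration:
  level: population
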