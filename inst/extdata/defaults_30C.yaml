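kinetics:
  tau1: 8.318699311544
  slope_m: 0.065218912467
  alpha_max: 0.1
  delta_a: 0.13025725869
  tau_pers: 23.282231109236
  pers_shape: 5.878984670765
  tau_reacid: 3.2
  n_vesicles: 1200.0
  p_release: 0.05
  reprime_s: 2.0
  surface_frac: 0.02
  noise_sd: 20.07
  quench_ratio: 20.0
population:
  tau1_cv: 0.52
  slope_cv: 1.0
fit:
  offset_t0: 5.0
  window_len: 60.0
temperature: 30C
calibration:
  level: population
condition:
  ca_slope_factor: 6.905250477651
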