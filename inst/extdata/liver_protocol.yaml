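# Eight contrast-enhanced sweeps of the C-arm protocol (248 views over
# 200 degrees, 3.9 s rotation, 1.4 s pause), moderate photon fluence,
# four prior-knowledge basis functions, desk-scale 64x64 phantom grid.
seed: 1
phantom:
  nx: 64
  pixel_size: 3.0
  time_start: 0
  time_end: 42
  time_step: 1
protocol:
  n_sweeps: 8
  n_mask_sweeps: 0
  views_per_sweep: 248
  angular_range_deg: 200
  angular_step_deg: 0.8
  rotation_time_s: 3.9
  pause_time_s: 1.4
  accel_fraction: 0.15
noise:
  fluence_per_mm2: moderate
basis:
  kind: prior_knowledge
  n_funcs: 4
recon:
  max_iterations: 50
  relative_residual_tol: 1.0e-6
perfusion:
  lambda_rel: 0.3
  n_points: 100
  dt_scaling: true
  smoothing_sigma: 3.0
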