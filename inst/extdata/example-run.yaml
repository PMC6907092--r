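# Example pipeline configuration for run_pipeline() /
# read_pipeline_config(). Any omitted key falls back to the package default.
cohort:
  n_per_class: 24
  seed: 7
  noise_sd_kpa: 0.8
  effect:
    amplitude_ratio: 0.75
    timing_shift_frac: 0.10
    plateau_decay: 1.5
    wave_asymmetry: 0.20
    spatial_focus_shift: 1
selection:
  n_keep: 25
  ranking_method: average_rank
  rfe_step: 5
  seed: 7
scheme: combined
fss: bb
fss_scope: outer_fold
subset_dim: 6
top_features: 6
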