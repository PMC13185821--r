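# Desk-scale demonstration run: small sample, reduced resampling.
seed: 1
synth:
  n_items_per_dimension: 6
  structure: big2_hier
  cross_loading: 0.1
  noise_sd: 0.5
  missing_rate: 0.02
  acquiescence_sd: 0.2
  groups:
    - {label: g1, size: 120, perturb_sd: 0.0, noise_mult: 1.0}
    - {label: g2, size: 120, perturb_sd: 0.0, noise_mult: 1.0}
    - {label: g3, size: 120, perturb_sd: 0.0, noise_mult: 1.5}
    - {label: g4, size: 120, perturb_sd: 0.1, noise_mult: 1.0}
rank_scan:
  ranks: [2, 3, 4, 5]
  n_reps: 3
  n_folds: 5
  max_iter: 1000
fit:
  ranks: [2, 5]
subgroup:
  label_field: group
  rank: 2
  n_null: 20
direction_scan:
  theta_true: 147
  n_features: 30
  signal_fraction: 0.5
  noise_sd: 0.5
  family_size: 2
  angles_step: 6
  n_reps: 1
  n_folds: 5
  n_perm: 60
  K_grid: [1, 2, 3]
  eta_grid: [0.2, 0.5, 1.0]
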