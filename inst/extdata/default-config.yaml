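world:
  n_features: 128
  n_contexts: 1
  pattern_density: 0.25
  reservoir_fraction: 0.35
  event_length: 3
  event_overlap: 0.5
  event_novelty: 0.5
  rng_seed: 1
network:
  n_areas: 4
  columns_per_area: 16
  n_l4: 4
  n_l23: 8
  n_deep: 3
  support_size: 12
  l4_syn: 8
  l4_k_classes:
  - 3
  - 4
  - 5
  - 6
  - 7
  deep_w_init: 0.0625
  apical_w_init: 0.0625
  deep_w_max: 0.125
  apical_w_max: 0.5
  apical_threshold: 0.5
  manager_weight: 0.5
  members_per_pcol: 3
  covers: 3
  intermediate_weight: 0.125
  n_p1: 1
  n_p2: 2
  n_p3: 18
  p1_w_init: 0.1875
  p1_w_max: 0.375
  p2_threshold: 0.1
  p3_basal_branches: 2
  p3_basal_syn: 12
  p3_threshold: 0.625
  p3_w_init: 0.0625
  p3_w_max: 0.5
  p3_delays:
  - 1
  - 2
  apical_branches_per_pcol: 1
  apical_syn: 6
  k_winners: 3
  retrieval_k_winners: 2
  retrieval_match_slope: 0.0
  refractory: 6
  candidacy_floor: 0.5
  delta_deep: 0.0625
  delta_p1: 0.1875
  delta_p3: 0.4375
  delta_apical: 0.4375
  ec_gain: 1.0
  decode_gain: 1.0
  group_decay: 0.98
  raise_window: 20
competition:
  n_ca3: 8
  w_rec: 0.5
  w_gc_exc: 1.0
  w_gc_inh: 4.0
  gc_inh_theta: 0.55
  w_mossy: 1.0
  ca3_baseline: 0.2
  tol: 1.0e-06
  max_iter: 500
  activity_cap: 1.0
  relax: 0.4
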