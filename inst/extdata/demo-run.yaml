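# Demo pipeline configuration: a 6 x 6 mini-orchard, three dates, synthetic.
mode: synthetic
seed: 7
orchard:
  n_rows: 6
  n_cols: 6
  origin_xy: [8.0, 8.0]
  treatment_blocks:
    traditional: [1, 2]
    adapted: [3, 4]
    mechanical: [5, 6]
params:
  tile_size_m: 1
  sd_threshold_m: 0.10
  window_radius_m: 1.0
  min_tree_area_m2: 0.5
  buffer_m: 1
synthetic:
  pixel_size: 0.05
  noise_sd: 0.0
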