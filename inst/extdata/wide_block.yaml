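# Wide-block orchard: two large single-cultivar blocks side by side.
# Transects run from the block boundary into the '816' block at rows
# 1, 2, 3 and 11 (8 m row spacing -> 8, 16, 24, 88 m).
orchard:
  type: WIDE
  blocks:
    - {cultivar: "816", n_rows: 42}
    - {cultivar: "Daddow", n_rows: 48}
  trees_per_row: 50
  row_spacing_m: 8
  tree_spacing_m: 4
  offtype_rate: 0.005        # a few storm-damage replacement trees
  offtype_pool: ["741"]
transects:
  rows: [1, 2, 3, 11]
  bees_per_point: 6
  hosts:
    - {block: "816", from: "end", n_transects: 8}
foraging:
  p_row_switch: 0.1
  n_visits: 30
  carryover_retention: 0.7
  pickup_grains: 1
  capture_visit: uniform
  capture_pickup: false
assay:
  theta_detect: 0.05
  fn_rate: 0.02
  fp_rate: 0.002
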