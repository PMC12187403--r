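# Narrow-block orchard: five 5-row single-cultivar blocks.
# Transects at rows 1-4 (10 m row spacing -> 10, 20, 30, 40 m): four into
# the '816' block from its A4-facing edge, three into the 'A4' block from
# its 816-facing edge, so row 4 of each is 2 rows from the opposite
# neighbouring block.
orchard:
  type: NARROW
  blocks:
    - {cultivar: "A203", n_rows: 5}
    - {cultivar: "842", n_rows: 5}
    - {cultivar: "816", n_rows: 5}
    - {cultivar: "A4", n_rows: 5}
    - {cultivar: "741", n_rows: 5}
  trees_per_row: 50
  row_spacing_m: 10
  tree_spacing_m: 2
  offtype_rate: 0.0
  offtype_pool: []
transects:
  rows: [1, 2, 3, 4]
  bees_per_point: 6
  hosts:
    - {block: "816", from: "end", n_transects: 4}
    - {block: "A4", from: "start", n_transects: 3}
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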