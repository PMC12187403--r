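# Wide-block orchard with covert within-row cross-pollen sources: 8% of
# trees are off-type replacements drawn from '741' and '849'.  With
# strongly row-bound foraging (rare row switches) and ~0.7 carryover this
# puts roughly one detectable off-type encounter in a typical bee's recent
# history, producing cross-pollen carriage in the 30-50% range with no
# strong distance gradient -- carriage is driven by in-row sources, not by
# distance to the neighbouring block.  Rows are long (300 trees) so the
# eight transects forage in non-overlapping stretches of each row.
orchard:
  type: WIDE
  blocks:
    - {cultivar: "816", n_rows: 42}
    - {cultivar: "Daddow", n_rows: 48}
  trees_per_row: 300
  row_spacing_m: 8
  tree_spacing_m: 4
  offtype_rate: 0.08
  offtype_pool: ["741", "849"]
transects:
  rows: [1, 2, 3, 11]
  bees_per_point: 6
  hosts:
    - {block: "816", from: "end", n_transects: 8}
foraging:
  p_row_switch: 0.01
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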