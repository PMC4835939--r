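# Operating plans of the best-performing lab-scale multi-feed SSCF and the
# accordingly designed demo-scale run. Feed times and totals are recorded
# values; per-feed masses are NOT recorded and must be reconstructed with
# the model (see reconstruct_schedule()).
lab:
  total_weight_g: 1252
  wis_loading_pct: 22.2
  operating_time_h: 120
  solids_added_at_h: [0, 4, 12, 24, 48, 72, 96]
  cells_added_at_h: [0, 24, 48, 72, 96]
demo:
  total_weight_kg: [5481, 5583]
  wis_loading_pct: [21.9, 21.5]
  pretreatment_liquor_kg: [178, 196]
  operating_time_h: 96
  solids_added_at_h: [0, 4, 12, 24, 48, 72]
  cells_added_at_h: [0, 12, 24, 48, 72]
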