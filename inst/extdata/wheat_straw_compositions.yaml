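# Compositions of the two batches of pre-treated wheat straw.
# Solid-phase entries are mass fractions of WIS; liquid-phase entries are
# g per kg of the retained pre-treatment liquor. Inhibitors are carried
# for bookkeeping only.
lab:
  glucan_frac: 0.479
  xylan_frac: 0.023
  other_polymer_fracs:
    mannan: 0.002
    galactan: 0.0004
    arabinan: 0.001
  wis_of_solid_feed: 0.40
  liquid_sugars:
    glucose: 6.8
    xylose: 12.8
    mannose: 0.4
    galactose: 1.0
    arabinose: 2.0
  liquid_inhibitors:
    acetic_acid: 3.8
    furfural: 4.0
    hmf: 1.4
demo:
  glucan_frac: 0.424
  xylan_frac: 0.026
  other_polymer_fracs:
    mannan: 0.002
    galactan: 0.0
    arabinan: 0.0008
  wis_of_solid_feed: 0.40
  liquid_sugars:
    glucose: 2.4
    xylose: 18.3
    mannose: 0.4
    galactose: 0.8
    arabinose: 2.8
  liquid_inhibitors:
    acetic_acid: 3.2
    furfural: 0.8
    hmf: 0.4
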