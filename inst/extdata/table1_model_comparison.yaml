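# Model Comparison experiment: same moisture sensitivity and saturation
# for both litters, evaporation rate differing (slow WET-LIT, fast
# DRY-LIT); run once with each moisture-sensitivity model.
moyano_wet:
  name: WET-LIT
  model: moyano
  lwc_max: 10
  k_max: 0.01
  e: 0.01
  a: 5
  b: 0.5
moyano_dry:
  name: DRY-LIT
  model: moyano
  lwc_max: 10
  k_max: 0.01
  e: 0.1
  a: 5
  b: 0.5
bunnell_wet:
  name: WET-LIT
  model: bunnell
  lwc_max: 10
  k_max: 0.01
  e: 0.01
  c: 5
  d: 5
bunnell_dry:
  name: DRY-LIT
  model: bunnell
  lwc_max: 10
  k_max: 0.01
  e: 0.1
  c: 5
  d: 5
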