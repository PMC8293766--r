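# Rate Combinations experiment (bunnell model only): litters with
# contrasted saturation water content, maximum decay rate and moisture
# sensitivity.  Simulation 1 ("identical within litter"): the
# fast-decomposing dry litter also evaporates fast.  Simulation 2
# ("different within litter"): the wet slow litter evaporates fast.
sim1_wet:
  name: WET-LIT
  model: bunnell
  lwc_max: 15
  k_max: 0.005
  e: 0.01
  c: 10
  d: 5
sim1_dry:
  name: DRY-LIT
  model: bunnell
  lwc_max: 5
  k_max: 0.015
  e: 0.1
  c: 1
  d: 5
sim2_wet:
  name: WET-LIT
  model: bunnell
  lwc_max: 15
  k_max: 0.005
  e: 0.1
  c: 10
  d: 5
sim2_dry:
  name: DRY-LIT
  model: bunnell
  lwc_max: 5
  k_max: 0.015
  e: 0.01
  c: 1
  d: 5
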