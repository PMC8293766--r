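# Calibrated parameter set for the two peatland litters (bunnell
# model): Sphagnum rubellum, the wet slow-evaporating moss, and
# Molinia caerulea, the dry fast-evaporating graminoid.  lwc_max was
# set from the first measured water content; k_max, c, d, e were
# fitted to the single-litter laboratory series (c and d sit at their
# upper bound, lwc_max).
sphagnum_rubellum:
  name: S. rubellum
  model: bunnell
  lwc_max: 22
  k_max: 0.0055
  e: 0.010
  c: 22
  d: 22
molinia_caerulea:
  name: M. caerulea
  model: bunnell
  lwc_max: 3
  k_max: 0.0060
  e: 0.061
  c: 3
  d: 3
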