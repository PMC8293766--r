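# Shared fixture constructors (all built in code, no files).

bunnell_lit <- function(name = "lit", lwc_max = 10, k_max = 0.01,
                        e = 0.1, c = 5, d = 5) {
  litter_params(name, lwc_max, k_max, e, "bunnell", c = c, d = d)
}

moyano_lit <- function(name = "lit", lwc_max = 10, k_max = 0.01,
                       e = 0.1, a = 5, b = 0.5) {
  litter_params(name, lwc_max, k_max, e, "moyano", a = a, b = b)
}

# The calibrated peatland litters (wet slow moss, dry fast graminoid).
sphagnum <- function() {
  litter_params("S. rubellum", 22, 0.0055, 0.010, "bunnell",
                c = 22, d = 22)
}
molinia <- function() {
  litter_params("M. caerulea", 3, 0.0060, 0.061, "bunnell",
                c = 3, d = 3)
}

noiseless_design <- function(...) {
  sampling_design(noise_sd_lwc = 0, noise_sd_mass = 0, ...)
}
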