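# litmix

Moisture-coupled litter decomposition and nonadditive mixture effects.

When plant litters of different species decompose together, the
mixture often loses mass faster (synergistic effect) or slower
(antagonistic effect) than the average of the same litters decomposing
alone. One candidate mechanism is purely physical: if water can flow
from the wettest litter to the driest, each litter's water content —
and therefore its microbial decay rate — changes, without changing the
total water content of the mixture. `litmix` implements a daily
difference-equation model of this mechanism, for ecosystem ecologists
studying litter-mixture effects (the motivating system is a peatland
mixture of *Sphagnum rubellum* moss and the invasive graminoid
*Molinia caerulea*).

## Model

For each litter, with daily time step *t*:

- Mass decay: `M[t+1] = M[t] − k·M[t]`, with `M` the remaining mass as
  a fraction of the initial dry mass.
- Water loss: `LWC[t] = LWC[t−1] − e·LWC[t−1]`, with `LWC` the litter
  water content (g water g⁻¹ dry matter) and `e` the daily evaporation
  rate. Simulations start at saturation, `LWC[0] = LWC_max`.
- The decay rate `k` responds to moisture through one of two
  double Michaelis–Menten forms:
  - `k = k_max · LWC/(a+LWC) · O_a/(b+O_a)` with oxygen availability
    `O_a = (LWC_max − LWC)/LWC_max` — activity stops at saturation;
  - `k = k_max · LWC/(c+LWC) · d/(d+LWC)` — activity persists at
    saturation (preferred for litter, where air exchange is high).

In a two-litter mixture with interaction, after each litter evaporates
at its own rate, water flows from the currently wettest litter to the
driest: the amount moved is `min(receiver saturation deficit,
half the LWC gap)`, i.e. the donor refills the receiver up to its
saturation while staying the wettest, otherwise the two litters
equalise at their average. The transfer conserves water. The
nonadditive effect is the per-day difference between the combined
remaining mass without and with interaction (percentage points of
initial dry mass; positive = synergistic).

The package also ships the two canonical numerical experiments
(`run_model_comparison()`, `run_rate_combinations()`), a two-phase
least-squares calibration from observed time series
(`fit_litter_model()`: evaporation rate from the water series, then
`k_max`, `c`, `d` from the mass series), validation statistics
(adjusted R², NRMSE, modeled vs observed nonadditive deltas), and a
synthetic-data generator emulating a destructive-sampling laboratory
design.

## Worked example

Simulate the calibrated peatland mixture and measure the nonadditive
effect:

```r
library(litmix)
pars <- read_litter_params(litmix_example("table2_calibrated.yaml"))
wet <- pars$sphagnum_rubellum   # LWC_max 22, e 0.010 — wet, slow
dry <- pars$molinia_caerulea    # LWC_max 3,  e 0.061 — dry, fast

m_no  <- simulate_mixture(wet, dry, 112, interaction = FALSE)
m_int <- simulate_mixture(wet, dry, 112, interaction = TRUE)
m_int
#> Mixture simulation ('interaction'), 112 days
#>   litters: S. rubellum (fraction 0.50) + M. caerulea (fraction 0.50)
#>   combined remaining mass at day 112: 88.74% of initial

d <- nonadditive_delta(m_no, m_int)
d$delta[d$day == 112]
#> [1] 2.461643
```

The interacting mixture has lost 2.46 percentage points more of its
initial dry mass than the additive expectation by day 112 — a
synergistic effect driven purely by water flowing from the moss to the
graminoid.

Calibrate the model from (here synthetic) single-litter observations:

```r
obs <- generate_single_litter_obs(dry, sampling_design(), seed = 42)
fit <- fit_litter_model(obs)
fit
#> Calibrated litter decomposition model: 'M. caerulea'
#>   lwc_max = 3 (set from first measurement)
#>   e = 0.0607497 /d   (phase 1, SSE = 1.014, n = 42)
#>   k_max = 0.00555382 /d   c = 3   d = 3   (phase 2, SSE = 0.01172, n = 42)
#>   at bound: c, d
```

The fitted evaporation rate (0.0607 d⁻¹) recovers the generating
value (0.061 d⁻¹) from noisy data; both moisture-sensitivity
constants rest on their upper bound (the saturation water content), a
weakly identified but correctly flagged outcome. The standard methods
(`coef`, `summary`, `predict`, `plot`, `residuals`, `simulate`) work
on the fit, and `validate_mixture()` compares interaction and
no-interaction predictions against observed mixture data.

A thin command-line wrapper over these functions is installed at
`inst/cli/litmix.R` (`simulate`, `experiment`, `calibrate`,
`validate`, `synth` subcommands).

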