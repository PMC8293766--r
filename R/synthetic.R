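#' Destructive-sampling design
#'
#' Describes the laboratory kinetic design emulated by the synthetic
#' generators: samples destroyed at a fixed set of dates, several
#' replicates per date, whole-sample water content and remaining mass
#' measured on each with additive Gaussian noise.
#'
#' @param sample_days strictly increasing integer sampling days
#'   (first >= 1).  The default, seven dates from day 2 to day 112,
#'   follows an incubation of a few months sampled on a roughly
#'   geometric grid.
#' @param replicates samples retrieved per date (default 6).
#' @param noise_sd_lwc absolute noise s.d. on water content, g water
#'   per g dry matter; \code{NULL} (default) means 5 percent of the
#'   litter's day-0 water content, resolved at generation time.
#' @param noise_sd_mass noise s.d. on the remaining-mass fraction
#'   (default 0.02).
#' @return An object of class \code{"sampling_design"}.
#' @export
sampling_design <- function(sample_days = c(2, 7, 14, 28, 56, 84, 112),
                            replicates = 6,
                            noise_sd_lwc = NULL,
                            noise_sd_mass = 0.02) {
  if (any(sample_days < 1) || any(diff(sample_days) <= 0) ||
      any(sample_days != round(sample_days)))
    stop("`sample_days` must be strictly increasing integers >= 1",
         call. = FALSE)
  if (replicates < 1 || replicates != round(replicates))
    stop("`replicates` must be a whole number >= 1", call. = FALSE)
  if (!is.null(noise_sd_lwc) && noise_sd_lwc < 0)
    stop("`noise_sd_lwc` must be >= 0", call. = FALSE)
  if (noise_sd_mass < 0)
    stop("`noise_sd_mass` must be >= 0", call. = FALSE)
  structure(list(sample_days = as.integer(sample_days),
                 replicates = as.integer(replicates),
                 noise_sd_lwc = noise_sd_lwc,
                 noise_sd_mass = noise_sd_mass),
            class = "sampling_design")
}

#' @export
print.sampling_design <- function(x, ...) {
  cat(sprintf("Sampling design: %d dates (%s), %d replicates/date\n",
              length(x$sample_days),
              paste(x$sample_days, collapse = ", "), x$replicates))
  cat(sprintf("  noise sd: lwc %s, mass %.3g\n",
              if (is.null(x$noise_sd_lwc)) "5% of day-0 LWC"
              else format(x$noise_sd_lwc), x$noise_sd_mass))
  invisible(x)
}

resolve_sd_lwc <- function(design, lwc0) {
  if (is.null(design$noise_sd_lwc)) 0.05 * lwc0 else design$noise_sd_lwc
}

noisy <- function(true_values, n_rep, sd, lower, upper) {
  draws <- rep(true_values, each = n_rep) +
    stats::rnorm(length(true_values) * n_rep, sd = sd)
  pmin(pmax(draws, lower), upper)
}

#' Generate synthetic single-litter observations
#'
#' Simulates the deterministic trajectory of one litter
#' (\code{\link{simulate_litter}}) and emits noisy destructive-sample
#' observations of water content and remaining mass at each sampling
#' day of the design.  Noise is additive Gaussian, independent across
#' replicates and variables; draws are truncated to the physical range
#' (water content at 0, mass fraction to (0, 1]).
#'
#' @param params a \code{\link{litter_params}}.
#' @param design a \code{\link{sampling_design}}.
#' @param seed integer seed for reproducible noise; \code{NULL} uses
#'   the current RNG state.
#' @param treatment treatment label for the emitted rows.
#' @return An \code{\link{observation_series}} with
#'   \code{2 * replicates * length(sample_days)} rows.
#' @examples
#' p <- litter_params("M. caerulea", 3, 0.006, 0.061, "bunnell",
#'                    c = 3, d = 3)
#' obs <- generate_single_litter_obs(p, sampling_design(), seed = 42)
#' nrow(obs)
#' @export
generate_single_litter_obs <- function(params, design, seed = NULL,
                                       treatment = "alone") {
  stopifnot(is_litter_params(params),
            inherits(design, "sampling_design"))
  if (!is.null(seed)) set.seed(seed)
  traj <- simulate_litter(params, max(design$sample_days))
  idx <- match(design$sample_days, traj$day)
  n_rep <- design$replicates
  sd_lwc <- resolve_sd_lwc(design, params$lwc_max)

  lwc_obs <- noisy(traj$lwc[idx], n_rep, sd_lwc, 0, Inf)
  mass_obs <- noisy(traj$mass_fraction[idx], n_rep,
                    design$noise_sd_mass, 1e-6, 1)
  days <- rep(design$sample_days, each = n_rep)
  reps <- rep(seq_len(n_rep), times = length(design$sample_days))
  observation_series(
    day = c(days, days), replicate = c(reps, reps),
    litter = params$name, treatment = treatment,
    variable = rep(c("lwc", "mass_fraction"), each = length(days)),
    value = c(lwc_obs, mass_obs))
}

#' Generate synthetic mixture observations
#'
#' Simulates a two-litter mixture (\code{\link{simulate_mixture}})
#' under the stated scenario and emits noisy observations of the
#' whole-sample quantities actually measurable on a mixed sample: the
#' combined remaining mass and the whole-mixture water content (mean
#' of the two litters' water contents).
#'
#' @param wet,dry \code{\link{litter_params}} of the two litters.
#' @param design a \code{\link{sampling_design}}.
#' @param interaction does the generating process include
#'   inter-litter water flow?
#' @param fraction_wet mixing fraction of \code{wet}.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return An \code{\link{observation_series}} with treatment
#'   \code{"mixture"}.
#' @export
generate_mixture_obs <- function(wet, dry, design, interaction = TRUE,
                                 fraction_wet = 0.5, seed = NULL) {
  stopifnot(inherits(design, "sampling_design"))
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_mixture(wet, dry, max(design$sample_days),
                          interaction = interaction,
                          fraction_wet = fraction_wet)
  comb <- sim$combined
  idx <- match(design$sample_days, comb$day)
  n_rep <- design$replicates
  sd_lwc <- resolve_sd_lwc(design, (wet$lwc_max + dry$lwc_max) / 2)

  lwc_obs <- noisy(comb$mixture_lwc[idx], n_rep, sd_lwc, 0, Inf)
  mass_obs <- noisy(comb$combined_mass[idx], n_rep,
                    design$noise_sd_mass, 1e-6, 1)
  days <- rep(design$sample_days, each = n_rep)
  reps <- rep(seq_len(n_rep), times = length(design$sample_days))
  observation_series(
    day = c(days, days), replicate = c(reps, reps),
    litter = paste(wet$name, dry$name, sep = " + "),
    treatment = "mixture",
    variable = rep(c("lwc", "mass_fraction"), each = length(days)),
    value = c(lwc_obs, mass_obs))
}
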