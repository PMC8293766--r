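#' Oxygen-availability coefficient
#'
#' Linear proxy for oxygen availability in the litter pore space:
#' \code{O_a = (lwc_max - lwc) / lwc_max}.  Equals 1 for fully dry
#' litter and 0 at water saturation, where oxygen diffusion is assumed
#' to be blocked.
#'
#' @param lwc litter water content, g water per g dry matter
#'   (vectorised).
#' @param lwc_max water content at saturation, g water per g dry
#'   matter.
#' @return Dimensionless fraction in \code{[0, 1]}.
#' @export
oxygen_availability <- function(lwc, lwc_max) {
  if (!is.numeric(lwc_max) || length(lwc_max) != 1L || lwc_max <= 0)
    stop("`lwc_max` must be a single number > 0", call. = FALSE)
  if (any(lwc < 0) || any(lwc > lwc_max))
    stop("`lwc` outside [0, lwc_max]: corrupted state", call. = FALSE)
  (lwc_max - lwc) / lwc_max
}

#' Moisture-dependent decomposition rate
#'
#' Daily decomposition rate as a function of litter water content,
#' using the moisture-sensitivity model stored in \code{params}
#' (see \code{\link{litter_params}}).  Both forms are products of two
#' Michaelis-Menten terms: one increasing in water availability, one
#' decreasing (oxygen limitation).  The moyano form is zero at
#' saturation; the bunnell form stays positive there.
#'
#' @param lwc litter water content, g water per g dry matter
#'   (vectorised).
#' @param params a \code{\link{litter_params}} object.
#' @return Decomposition rate k, per day, in \code{[0, k_max)}.
#' @examples
#' p <- litter_params("x", lwc_max = 10, k_max = 0.01, e = 0.1,
#'                    model = "bunnell", c = 5, d = 5)
#' decay_rate(c(0, 5, 10), p)
#' @export
decay_rate <- function(lwc, params) {
  stopifnot(is_litter_params(params))
  switch(params$model,
         moyano  = rate_moyano(lwc, params),
         bunnell = rate_bunnell(lwc, params))
}

#' @rdname decay_rate
#' @export
rate_moyano <- function(lwc, params) {
  stopifnot(is_litter_params(params))
  if (is.null(params$a) || is.null(params$b))
    stop("moyano constants `a`, `b` missing from params", call. = FALSE)
  oa <- oxygen_availability(lwc, params$lwc_max)
  params$k_max * lwc / (params$a + lwc) * oa / (params$b + oa)
}

#' @rdname decay_rate
#' @export
rate_bunnell <- function(lwc, params) {
  stopifnot(is_litter_params(params))
  if (is.null(params$c) || is.null(params$d))
    stop("bunnell constants `c`, `d` missing from params", call. = FALSE)
  if (any(lwc < 0)) stop("`lwc` must be >= 0", call. = FALSE)
  params$k_max * lwc / (params$c + lwc) * params$d / (params$d + lwc)
}

#' One day of evaporation
#'
#' Discrete negative-exponential water loss: a fixed fraction \code{e}
#' of the currently held water leaves the litter each day, so
#' \code{lwc' = lwc * (1 - e)}.
#'
#' @param lwc current litter water content (vectorised).
#' @param e evaporation rate, fraction per day in \code{[0, 1]}.
#' @return Water content after one day.
#' @export
evaporate <- function(lwc, e) {
  if (!is.numeric(e) || length(e) != 1L || e < 0 || e > 1)
    stop("`e` must be a single number in [0, 1]", call. = FALSE)
  if (any(lwc < 0)) stop("`lwc` must be >= 0", call. = FALSE)
  lwc * (1 - e)
}

#' One day of mass loss
#'
#' Discrete negative-exponential decay: the fraction \code{k} of the
#' mass present at time t is lost by t + 1, so
#' \code{m' = m * (1 - k)}.
#'
#' @param mass_fraction remaining mass as a fraction of initial dry
#'   mass (vectorised).
#' @param k decomposition rate for the day, in \code{[0, 1)}.
#' @return Remaining mass fraction after one day.
#' @export
decay_step <- function(mass_fraction, k) {
  if (any(k < 0) || any(k >= 1))
    stop("`k` must lie in [0, 1)", call. = FALSE)
  mass_fraction * (1 - k)
}
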