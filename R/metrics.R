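#' Goodness-of-fit statistics
#'
#' Compares a modeled series with an observed series:
#' \code{r2 = 1 - SSres/SStot} (total sum of squares about the
#' observed mean), the adjusted
#' \code{r2_adj = 1 - (1 - r2)(n - 1)/(n - p - 1)}, and the
#' normalised root mean square error
#' \code{nrmse = sqrt(SSres/n) / mean(observed)} (or divided by the
#' observed range with \code{normalization = "range"}; the normaliser
#' is a convention, not a model property, so both are offered).
#'
#' @param observed,modeled paired numeric series of equal length
#'   (n >= 3).
#' @param p number of parameters charged in the adjustment (default 0:
#'   a pure model-vs-data comparison estimates nothing).
#' @param normalization \code{"mean"} (default) or \code{"range"}.
#' @return An object of class \code{"fit_stats"}: list with
#'   \code{r2}, \code{r2_adj}, \code{nrmse}, \code{n}, \code{p}.
#' @examples
#' fit_stats(c(1, 0.9, 0.8), c(1, 0.9, 0.7))
#' @export
fit_stats <- function(observed, modeled, p = 0,
                      normalization = c("mean", "range")) {
  normalization <- match.arg(normalization)
  if (length(observed) != length(modeled))
    stop("`observed` and `modeled` must have equal length", call. = FALSE)
  n <- length(observed)
  if (n < 3L) stop("need n >= 3 paired values", call. = FALSE)
  ss_res <- sum((observed - modeled)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  r2 <- 1 - ss_res / ss_tot
  if (n > p + 1) {
    r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  } else {
    warning("n <= p + 1: adjusted R-squared undefined", call. = FALSE)
    r2_adj <- NA_real_
  }
  scale <- switch(normalization, mean = mean(observed),
                  range = diff(range(observed)))
  structure(list(r2 = r2, r2_adj = r2_adj,
                 nrmse = sqrt(ss_res / n) / scale,
                 n = n, p = p, normalization = normalization),
            class = "fit_stats")
}

#' @export
print.fit_stats <- function(x, ...) {
  cat(sprintf("  R2 = %.4f   adj. R2 = %.4f   NRMSE = %.4f (%s-normalised, n = %d)\n",
              x$r2, x$r2_adj, x$nrmse, x$normalization, x$n))
  invisible(x)
}

#' Modeled and observed nonadditive effects
#'
#' Computes, day by day, the two deltas used to judge whether
#' inter-litter water flow accounts for an observed mixture effect:
#' the model-predicted nonadditive effect (no-interaction minus
#' interaction remaining mass) and the experimentally observed one
#' (expected additive remaining mass, built from the litters
#' decomposing alone, minus the measured mixture remaining mass).
#' Positive values mean a synergistic effect, in percentage points of
#' initial dry mass.
#'
#' @param day integer days shared by all four series.
#' @param measured_mix observed mixture remaining-mass fractions.
#' @param expected_mix additive expectation from single-litter data.
#' @param modeled_int,modeled_no_int model remaining-mass fractions
#'   under the interaction / no-interaction scenarios.
#' @return Data frame with columns \code{day}, \code{observed_delta},
#'   \code{modeled_delta}.
#' @export
scenario_deltas <- function(day, measured_mix, expected_mix,
                            modeled_int, modeled_no_int) {
  n <- length(day)
  if (any(lengths(list(measured_mix, expected_mix, modeled_int,
                       modeled_no_int)) != n))
    stop("all series must align with `day`", call. = FALSE)
  data.frame(day = day,
             observed_delta = 100 * (expected_mix - measured_mix),
             modeled_delta = 100 * (modeled_no_int - modeled_int))
}

#' Validate the mixture model against observations
#'
#' Full validation pass: from calibrated single-litter parameter sets,
#' simulate the two-litter mixture with and without water flow, then
#' compare against the observed series at the sampled days.  Two
#' comparisons are reported: the no-interaction model against the
#' measured additive expectation (replicate-mean single-litter masses,
#' weighted by mixing fraction), and the interaction model against the
#' measured mixture mass.  Per-day modeled and observed nonadditive
#' deltas come from \code{\link{scenario_deltas}}.
#'
#' @param wet,dry calibrated \code{\link{litter_params}} (or
#'   \code{litter_fit} objects) for the two litters; their
#'   \code{name}s must match the litter labels in \code{obs}.
#' @param obs an \code{\link{observation_series}} holding
#'   single-litter mass series (treatment \code{"alone"}) for both
#'   litters and the mixture mass series (treatment
#'   \code{"mixture"}).
#' @param fraction_wet mass fraction of \code{wet} in the mixture.
#' @param p parameters charged in the adjusted R-squared (default 0).
#' @param normalization NRMSE normalisation, \code{"mean"} or
#'   \code{"range"}.
#' @return An object of class \code{"mixture_validation"}: list with
#'   \code{stats_no_interaction}, \code{stats_interaction} (both
#'   \code{\link{fit_stats}}), \code{deltas}, and the aligned series
#'   in \code{table}.
#' @export
validate_mixture <- function(wet, dry, obs, fraction_wet = 0.5,
                             p = 0, normalization = c("mean", "range")) {
  if (inherits(wet, "litter_fit")) wet <- wet$params
  if (inherits(dry, "litter_fit")) dry <- dry$params
  stopifnot(is_litter_params(wet), is_litter_params(dry),
            inherits(obs, "observation_series"))
  normalization <- match.arg(normalization)

  day_mean <- function(sel) {
    sub <- obs[sel & obs$variable == "mass_fraction", , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    means <- tapply(sub$value, sub$day, mean)
    data.frame(day = as.integer(names(means)),
               value = as.numeric(means))
  }
  m_wet <- day_mean(obs$treatment == "alone" & obs$litter == wet$name)
  m_dry <- day_mean(obs$treatment == "alone" & obs$litter == dry$name)
  m_mix <- day_mean(obs$treatment == "mixture")
  if (is.null(m_wet) || is.null(m_dry))
    stop("single-litter mass series missing for one of the litters",
         call. = FALSE)
  if (is.null(m_mix))
    stop("mixture mass series missing from observations", call. = FALSE)

  days <- sort(Reduce(intersect, list(m_wet$day, m_dry$day, m_mix$day)))
  if (length(days) < 3L)
    stop("need >= 3 shared sampling days across treatments",
         call. = FALSE)
  at <- function(df) df$value[match(days, df$day)]
  expected <- fraction_wet * at(m_wet) + (1 - fraction_wet) * at(m_dry)
  measured <- at(m_mix)

  horizon <- max(days)
  sim_no <- simulate_mixture(wet, dry, horizon, interaction = FALSE,
                             fraction_wet = fraction_wet)
  sim_int <- simulate_mixture(wet, dry, horizon, interaction = TRUE,
                              fraction_wet = fraction_wet)
  model_no <- sim_no$combined$combined_mass[match(days, sim_no$combined$day)]
  model_int <- sim_int$combined$combined_mass[match(days, sim_int$combined$day)]

  structure(
    list(stats_no_interaction =
           fit_stats(expected, model_no, p, normalization),
         stats_interaction =
           fit_stats(measured, model_int, p, normalization),
         deltas = scenario_deltas(days, measured, expected,
                                  model_int, model_no),
         table = data.frame(day = days, measured_mix = measured,
                            expected_mix = expected,
                            model_interaction = model_int,
                            model_no_interaction = model_no),
         litters = c(wet = wet$name, dry = dry$name)),
    class = "mixture_validation")
}

#' @export
print.mixture_validation <- function(x, ...) {
  cat(sprintf("Mixture validation: %s + %s\n",
              x$litters[["wet"]], x$litters[["dry"]]))
  cat("No-interaction model vs measured additive expectation:\n")
  print(x$stats_no_interaction)
  cat("Interaction model vs measured mixture:\n")
  print(x$stats_interaction)
  last <- nrow(x$deltas)
  cat(sprintf("Nonadditive delta at day %d: observed %.2f pp, modeled %.2f pp\n",
              x$deltas$day[last], x$deltas$observed_delta[last],
              x$deltas$modeled_delta[last]))
  invisible(x)
}
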