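#' @export
print.litter_fit <- function(x, ...) {
  cat(sprintf("Calibrated litter decomposition model: '%s'\n",
              x$params$name))
  cat(sprintf("  lwc_max = %g (set from first measurement)\n",
              x$params$lwc_max))
  cat(sprintf("  e = %.6g /d   (phase 1, SSE = %.4g, n = %d)\n",
              x$params$e, x$phase1$sse, x$phase1$n_obs))
  cat(sprintf("  k_max = %.6g /d   c = %.4g   d = %.4g   (phase 2, SSE = %.4g, n = %d)\n",
              x$params$k_max, x$params$c, x$params$d, x$phase2$sse,
              x$phase2$n_obs))
  at_bound <- names(x$bounds_active)[x$bounds_active]
  if (length(at_bound))
    cat(sprintf("  at bound: %s\n", paste(at_bound, collapse = ", ")))
  invisible(x)
}

#' Extract calibrated parameters
#'
#' @param object a \code{litter_fit}.
#' @param ... unused.
#' @return Named numeric vector \code{lwc_max}, \code{k_max},
#'   \code{c}, \code{d}, \code{e}.
#' @export
coef.litter_fit <- function(object, ...) {
  p <- object$params
  c(lwc_max = p$lwc_max, k_max = p$k_max, c = p$c, d = p$d, e = p$e)
}

#' @export
summary.litter_fit <- function(object, ...) {
  structure(list(fit = object, stats = object$stats),
            class = "summary.litter_fit")
}

#' @export
print.summary.litter_fit <- function(x, ...) {
  print(x$fit)
  cat("Goodness of fit (remaining mass at observed days):\n")
  print(x$stats)
  invisible(x)
}

#' Predict from a calibrated litter model
#'
#' Evaluates the fitted deterministic trajectory.
#'
#' @param object a \code{litter_fit}.
#' @param days integer days at which to predict (default: the
#'   observed sampling days).
#' @param variable \code{"mass_fraction"}, \code{"lwc"} or \code{"k"}.
#' @param ... unused.
#' @return Numeric vector of predictions at \code{days}.
#' @export
predict.litter_fit <- function(object,
                               days = sort(unique(object$obs$day)),
                               variable = c("mass_fraction", "lwc", "k"),
                               ...) {
  variable <- match.arg(variable)
  if (any(days < 0 | days != round(days)))
    stop("`days` must be non-negative integers", call. = FALSE)
  traj <- simulate_litter(object$params, max(days, 1L))
  traj[[variable]][match(days, traj$day)]
}

#' @export
fitted.litter_fit <- function(object, ...) mass_fitted_values(object)

#' Residuals of the remaining-mass fit
#'
#' Observed minus fitted remaining-mass fraction at the observed
#' sampling days (pooled replicates).
#'
#' @param object a \code{litter_fit}.
#' @param ... unused.
#' @return Numeric vector, one element per mass observation.
#' @export
residuals.litter_fit <- function(object, ...) {
  mass_obs_values(object) - mass_fitted_values(object)
}

#' Plot a calibrated litter model
#'
#' Two base-graphics panels: observed vs fitted water content, and
#' observed vs fitted remaining mass.
#'
#' @param x a \code{litter_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.litter_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  p <- x$params
  horizon <- max(x$obs$day, 1L)
  traj <- simulate_litter(p, horizon)
  lw <- x$obs[x$obs$variable == "lwc", ]
  ms <- mass_obs(x)
  graphics::plot(lw$day, lw$value, xlab = "day",
                 ylab = "LWC (g water / g dry matter)",
                 main = p$name, ...)
  graphics::lines(traj$day, traj$lwc)
  graphics::plot(ms$day, 100 * ms$value, xlab = "day",
                 ylab = "remaining mass (% of initial)",
                 main = sprintf("e = %.3g, k_max = %.3g", p$e, p$k_max),
                 ...)
  graphics::lines(traj$day, 100 * traj$mass_fraction)
  invisible(x)
}

#' Simulate observation sets from a calibrated model
#'
#' Draws new synthetic observation series from the fitted parameter
#' set under the laboratory sampling design, mirroring
#' \code{\link{generate_single_litter_obs}}.
#'
#' @param object a \code{litter_fit}.
#' @param nsim number of series to draw.
#' @param seed integer seed (optional).
#' @param design a \code{\link{sampling_design}}; defaults to the
#'   fit's observed days and replicate count.
#' @param ... unused.
#' @return A list of \code{nsim} \code{observation_series}.
#' @export
simulate.litter_fit <- function(object, nsim = 1, seed = NULL,
                                design = NULL, ...) {
  if (is.null(design)) {
    ms <- mass_obs(object)
    design <- sampling_design(
      sample_days = sort(unique(object$obs$day[object$obs$day >= 1])),
      replicates = max(1L, as.integer(stats::median(
        table(ms$day)))))
  }
  if (!is.null(seed)) set.seed(seed)
  replicate(nsim,
            generate_single_litter_obs(object$params, design),
            simplify = FALSE)
}
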