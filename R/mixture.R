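#' Daily water transfer between two litters
#'
#' Moves water down the moisture gradient, from the currently wetter
#' litter to the drier one.  The transferred amount is
#' \code{tau = min(lwc_max_dry - lwc_dry, (lwc_wet - lwc_dry)/2)}:
#' the donor refills the receiver up to the receiver's saturation
#' point as long as the donor stays the wettest; when the gradient is
#' too small for a full refill the two water contents are equalised at
#' their average.  The sum of the two water contents is unchanged
#' (equal-dry-mass bookkeeping; see the package vignette).
#'
#' @param lwc_wet water content of the currently wetter litter.
#' @param lwc_dry water content of the currently drier litter; must
#'   not exceed \code{lwc_wet}.
#' @param lwc_max_dry saturation water content of the drier litter.
#' @return Named numeric vector \code{c(wet = , dry = )} with the
#'   post-transfer water contents.
#' @examples
#' transfer_water(10, 2, 5)  # full refill: c(7, 5)
#' transfer_water(4, 2, 5)   # equalisation: c(3, 3)
#' @export
transfer_water <- function(lwc_wet, lwc_dry, lwc_max_dry) {
  if (lwc_dry < 0 || lwc_wet < lwc_dry)
    stop("orientation error: need lwc_wet >= lwc_dry >= 0", call. = FALSE)
  if (lwc_dry > lwc_max_dry)
    stop("receiver above its own saturation", call. = FALSE)
  tau <- min(lwc_max_dry - lwc_dry, (lwc_wet - lwc_dry) / 2)
  tau <- max(tau, 0)
  c(wet = lwc_wet - tau, dry = lwc_dry + tau)
}

#' Simulate a two-litter mixture
#'
#' Runs the daily difference equations for two litters decomposing
#' together.  Under \code{interaction = FALSE} the litters are fully
#' independent (the additive expectation).  Under
#' \code{interaction = TRUE}, each day after both litters evaporate at
#' their own rates, water flows from the currently wettest litter to
#' the driest via \code{\link{transfer_water}}; which litter is
#' "wettest" is re-evaluated every day from the current water
#' contents, so the roles can swap mid-run.  Decomposition rates are
#' computed from the post-transfer water contents.
#'
#' The combined remaining mass is the mass-fraction-weighted mean of
#' the two litters' remaining masses
#' (\code{fraction_wet * m_wet + (1 - fraction_wet) * m_dry}).
#'
#' @param wet,dry \code{\link{litter_params}} for the two litters.
#'   The names refer to the initial roles; the engine re-orients by
#'   current water content at every step.
#' @param horizon days to simulate.
#' @param interaction logical: allow inter-litter water flow?
#' @param fraction_wet mass fraction of the \code{wet} litter in the
#'   mixture (default 0.5, an equal-parts mixture).
#' @return An object of class \code{"mixture_result"}: a list with the
#'   two \code{litter_trajectory} data frames (\code{traj_wet},
#'   \code{traj_dry}), a per-day \code{combined} data frame
#'   (\code{day}, \code{combined_mass}, \code{mixture_lwc}), and the
#'   scenario label.
#' @examples
#' wet <- litter_params("WET-LIT", 10, 0.01, 0.01, "bunnell", c = 5, d = 5)
#' dry <- litter_params("DRY-LIT", 10, 0.01, 0.1,  "bunnell", c = 5, d = 5)
#' m <- simulate_mixture(wet, dry, horizon = 80, interaction = TRUE)
#' m
#' @export
simulate_mixture <- function(wet, dry, horizon, interaction = TRUE,
                             fraction_wet = 0.5) {
  stopifnot(is_litter_params(wet), is_litter_params(dry))
  horizon <- check_horizon(horizon)
  if (!is.numeric(fraction_wet) || fraction_wet <= 0 || fraction_wet >= 1)
    stop("`fraction_wet` must lie strictly between 0 and 1", call. = FALSE)

  n <- horizon + 1L
  lwc_w <- k_w <- m_w <- lwc_d <- k_d <- m_d <- numeric(n)
  lwc_w[1L] <- wet$lwc_max; lwc_d[1L] <- dry$lwc_max
  m_w[1L] <- m_d[1L] <- 1
  k_w[1L] <- decay_rate(lwc_w[1L], wet)
  k_d[1L] <- decay_rate(lwc_d[1L], dry)

  for (t in seq_len(horizon)) {
    a <- evaporate(lwc_w[t], wet$e)
    b <- evaporate(lwc_d[t], dry$e)
    if (interaction) {
      if (a >= b) {
        moved <- transfer_water(a, b, dry$lwc_max)
        a <- moved[["wet"]]; b <- moved[["dry"]]
      } else {
        moved <- transfer_water(b, a, wet$lwc_max)
        b <- moved[["wet"]]; a <- moved[["dry"]]
      }
    }
    lwc_w[t + 1L] <- a
    lwc_d[t + 1L] <- b
    k_w[t + 1L] <- decay_rate(a, wet)
    k_d[t + 1L] <- decay_rate(b, dry)
    m_w[t + 1L] <- decay_step(m_w[t], k_w[t + 1L])
    m_d[t + 1L] <- decay_step(m_d[t], k_d[t + 1L])
  }

  days <- 0:horizon
  structure(
    list(
      traj_wet = new_trajectory(days, wet$name, lwc_w, k_w, m_w),
      traj_dry = new_trajectory(days, dry$name, lwc_d, k_d, m_d),
      combined = data.frame(
        day = days,
        combined_mass = fraction_wet * m_w + (1 - fraction_wet) * m_d,
        mixture_lwc = (lwc_w + lwc_d) / 2),
      scenario = if (interaction) "interaction" else "no_interaction",
      fraction_wet = fraction_wet),
    class = "mixture_result")
}

#' @export
print.mixture_result <- function(x, ...) {
  h <- max(x$combined$day)
  cat(sprintf("Mixture simulation ('%s'), %d days\n", x$scenario, h))
  cat(sprintf("  litters: %s (fraction %.2f) + %s (fraction %.2f)\n",
              x$traj_wet$litter[1L], x$fraction_wet,
              x$traj_dry$litter[1L], 1 - x$fraction_wet))
  cat(sprintf("  combined remaining mass at day %d: %.2f%% of initial\n",
              h, 100 * x$combined$combined_mass[nrow(x$combined)]))
  invisible(x)
}

#' Nonadditive mixture effect
#'
#' Per-day difference between the combined remaining mass of the
#' no-interaction (additive) scenario and the interaction scenario,
#' expressed in percentage points of initial dry mass.  Positive
#' values indicate a synergistic effect (the interacting mixture has
#' lost more mass than the additive expectation), negative values an
#' antagonistic effect, and values near zero additivity.
#'
#' @param no_interaction,interaction \code{mixture_result} objects
#'   from \code{\link{simulate_mixture}} with matching horizons and
#'   mixing fractions.
#' @return Data frame with columns \code{day} and \code{delta}
#'   (percentage points of initial dry mass).
#' @export
nonadditive_delta <- function(no_interaction, interaction) {
  stopifnot(inherits(no_interaction, "mixture_result"),
            inherits(interaction, "mixture_result"))
  a <- no_interaction$combined; b <- interaction$combined
  if (nrow(a) != nrow(b) || any(a$day != b$day))
    stop("mismatched horizons between scenarios", call. = FALSE)
  if (no_interaction$fraction_wet != interaction$fraction_wet)
    stop("mismatched mixing fractions between scenarios", call. = FALSE)
  data.frame(day = a$day,
             delta = 100 * (a$combined_mass - b$combined_mass))
}

#' Write a mixture simulation to CSV
#'
#' Long-format export with one row per day and litter, plus the
#' combined mixture mass repeated on each row.
#'
#' @param result a \code{mixture_result}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_mixture <- function(result, path) {
  long <- rbind(as.data.frame(result$traj_wet),
                as.data.frame(result$traj_dry))
  long$scenario <- result$scenario
  long <- merge(long, result$combined, by = "day", sort = TRUE)
  long <- long[order(long$day, long$litter),
               c("day", "scenario", "litter", "lwc", "k",
                 "mass_fraction", "combined_mass", "mixture_lwc")]
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
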