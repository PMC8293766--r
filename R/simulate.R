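#' Simulate one litter decomposing alone
#'
#' Advances the daily difference equations for a single litter over
#' \code{horizon} days.  Each day, in this order: water evaporates
#' (\code{\link{evaporate}}), the decomposition rate is computed from
#' the new water content (\code{\link{decay_rate}}), and the remaining
#' mass decays by that rate (\code{\link{decay_step}}).  The water
#' content starts at \code{params$lwc_max} (saturation) and the mass at
#' 1 (all of the initial dry mass).
#'
#' The returned trajectory includes the initial state as day 0, so a
#' run of \code{horizon} days has \code{horizon + 1} rows and the water
#' column follows the closed form \code{lwc_max * (1 - e)^day} exactly.
#' The \code{k} column holds the rate computed from that day's water
#' content; the day-0 entry is purely informational (no decay has been
#' applied yet).
#'
#' @param params a \code{\link{litter_params}} object.
#' @param horizon number of days to simulate (>= 1).
#' @return A data frame of class \code{"litter_trajectory"} with
#'   columns \code{day}, \code{litter}, \code{lwc}, \code{k},
#'   \code{mass_fraction}.
#' @examples
#' p <- litter_params("DRY-LIT", lwc_max = 10, k_max = 0.01, e = 0.1,
#'                    model = "bunnell", c = 5, d = 5)
#' tail(simulate_litter(p, horizon = 80))
#' @export
simulate_litter <- function(params, horizon) {
  stopifnot(is_litter_params(params))
  horizon <- check_horizon(horizon)
  lwc <- k <- mass <- numeric(horizon + 1L)
  state <- list(day = 0L, lwc = params$lwc_max, mass_fraction = 1)
  lwc[1L] <- state$lwc
  k[1L] <- decay_rate(state$lwc, params)
  mass[1L] <- 1
  for (t in seq_len(horizon)) {
    state <- step_litter(state, params)
    lwc[t + 1L] <- state$lwc
    k[t + 1L] <- state$k
    mass[t + 1L] <- state$mass_fraction
  }
  new_trajectory(0:horizon, params$name, lwc, k, mass)
}

new_trajectory <- function(day, litter, lwc, k, mass_fraction) {
  structure(
    data.frame(day = day, litter = litter, lwc = lwc, k = k,
               mass_fraction = mass_fraction),
    class = c("litter_trajectory", "data.frame"))
}

check_horizon <- function(horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L ||
      horizon < 1 || horizon != round(horizon))
    stop("`horizon` must be a whole number >= 1", call. = FALSE)
  as.integer(horizon)
}

#' Advance one litter by a single day
#'
#' Low-level single-step update used by the simulators: evaporate,
#' recompute the decay rate from the new water content, decay the
#' mass, increment the day counter.
#'
#' @param state list with elements \code{day}, \code{lwc},
#'   \code{mass_fraction}.
#' @param params a \code{\link{litter_params}} object.
#' @return The updated state, with the applied rate in \code{k}.
#' @export
step_litter <- function(state, params) {
  stopifnot(is_litter_params(params))
  lwc <- evaporate(state$lwc, params$e)
  k <- decay_rate(lwc, params)
  list(day = state$day + 1L, lwc = lwc, k = k,
       mass_fraction = decay_step(state$mass_fraction, k))
}

#' @export
print.litter_trajectory <- function(x, ...) {
  cat(sprintf("Litter trajectory: '%s', %d days\n",
              x$litter[1L], max(x$day)))
  cat(sprintf("  final lwc = %.4g g/g, remaining mass = %.2f%% of initial\n",
              x$lwc[nrow(x)], 100 * x$mass_fraction[nrow(x)]))
  NextMethod()
}

#' Write a trajectory to CSV
#'
#' @param traj a \code{litter_trajectory} data frame.
#' @param path output file; columns are
#'   \code{day,litter,lwc,k,mass_fraction}.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
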