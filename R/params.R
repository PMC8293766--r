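#' Litter parameter set
#'
#' Bundles the physical and biological constants of one litter type:
#' its water holding capacity, maximum decomposition rate, evaporation
#' rate, and the Michaelis-Menten constants of the chosen
#' moisture-sensitivity function.
#'
#' Two moisture-sensitivity models are supported.  The \code{"moyano"}
#' form multiplies a water-limitation term \code{lwc/(a + lwc)} by an
#' oxygen-limitation term \code{O_a/(b + O_a)}, where
#' \code{O_a = (lwc_max - lwc)/lwc_max} is the oxygen-availability
#' coefficient; decomposition stops entirely at saturation.  The
#' \code{"bunnell"} form multiplies \code{lwc/(c + lwc)} by a
#' gas-exchange facilitation term \code{d/(d + lwc)}; activity remains
#' positive at saturation.
#'
#' @param name character label for the litter (e.g. species name).
#' @param lwc_max water content at saturation, g water per g dry
#'   matter; also the initial water content of simulations.
#' @param k_max maximum decomposition rate, per day.
#' @param e evaporation rate: fraction of currently held water lost
#'   per day, in \code{[0, 1]}.
#' @param model moisture-sensitivity model, \code{"bunnell"} or
#'   \code{"moyano"}.
#' @param a,b Michaelis-Menten constants of the moyano form
#'   (\code{a} in g water per g dry matter; \code{b} dimensionless,
#'   acting on the oxygen-availability coefficient).  Required when
#'   \code{model = "moyano"}, ignored otherwise.
#' @param c,d Michaelis-Menten constants of the bunnell form, g water
#'   per g dry matter.  Required when \code{model = "bunnell"}.
#'
#' @return An object of class \code{"litter_params"}.
#'
#' @examples
#' wet <- litter_params("WET-LIT", lwc_max = 10, k_max = 0.01, e = 0.01,
#'                      model = "bunnell", c = 5, d = 5)
#' decay_rate(5, wet)
#' @export
litter_params <- function(name, lwc_max, k_max, e,
                          model = c("bunnell", "moyano"),
                          a = NULL, b = NULL, c = NULL, d = NULL) {
  model <- match.arg(model)
  stopifnot(is.character(name), length(name) == 1L)
  check_number(lwc_max, "lwc_max")
  check_number(k_max, "k_max")
  check_number(e, "e")
  if (lwc_max <= 0) stop("`lwc_max` must be > 0", call. = FALSE)
  if (k_max < 0) stop("`k_max` must be >= 0", call. = FALSE)
  if (e < 0 || e > 1) stop("`e` must lie in [0, 1]", call. = FALSE)
  if (model == "moyano") {
    if (is.null(a) || is.null(b))
      stop("moyano model requires constants `a` and `b`", call. = FALSE)
    check_number(a, "a"); check_number(b, "b")
    if (a <= 0 || b <= 0)
      stop("moyano constants `a`, `b` must be > 0", call. = FALSE)
  } else {
    if (is.null(c) || is.null(d))
      stop("bunnell model requires constants `c` and `d`", call. = FALSE)
    check_number(c, "c"); check_number(d, "d")
    if (c <= 0 || d <= 0)
      stop("bunnell constants `c`, `d` must be > 0", call. = FALSE)
  }
  structure(
    list(name = name, lwc_max = lwc_max, k_max = k_max, e = e,
         model = model, a = a, b = b, c = c, d = d),
    class = "litter_params")
}

check_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", what),
         call. = FALSE)
  invisible(x)
}

#' @export
print.litter_params <- function(x, ...) {
  cat(sprintf("Litter '%s' [%s model]\n", x$name, x$model))
  cat(sprintf("  lwc_max = %g g/g   k_max = %g /d   e = %g /d\n",
              x$lwc_max, x$k_max, x$e))
  if (x$model == "moyano")
    cat(sprintf("  a = %g g/g   b = %g (on O_a)\n", x$a, x$b))
  else
    cat(sprintf("  c = %g g/g   d = %g g/g\n", x$c, x$d))
  invisible(x)
}

#' @export
format.litter_params <- function(x, ...) {
  sprintf("litter_params(%s, %s)", x$name, x$model)
}

is_litter_params <- function(x) inherits(x, "litter_params")

#' Path to a packaged example file
#'
#' Convenience accessor for the parameter fixtures shipped with the
#' package (the two numerical-experiment parameter sets and the
#' calibrated peatland-litter set).
#'
#' @param file file name; with no argument, lists available files.
#' @return Full path to the file.
#' @examples
#' litmix_example()
#' read_litter_params(litmix_example("table2_calibrated.yaml"))
#' @export
litmix_example <- function(file = NULL) {
  dir <- system.file("extdata", package = "litmix")
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path))
    stop(sprintf("no packaged file '%s'", file), call. = FALSE)
  path
}
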