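#' Read and write litter parameter files
#'
#' Parameter files are structured key-value configs (YAML, or JSON by
#' file extension) holding one or more named litter blocks, each with
#' the fields of \code{\link{litter_params}}: \code{name},
#' \code{model}, \code{lwc_max}, \code{k_max}, \code{e} and the
#' constants of the active model (\code{a}, \code{b} for moyano;
#' \code{c}, \code{d} for bunnell).  Constants of the inactive model
#' may be omitted.
#'
#' @param path file to read or write.
#' @return \code{read_litter_params}: a named list of
#'   \code{litter_params} (a single unnamed block is returned as one
#'   \code{litter_params}).  \code{write_litter_params}: \code{path},
#'   invisibly.
#' @examples
#' pars <- read_litter_params(litmix_example("table2_calibrated.yaml"))
#' pars$molinia_caerulea
#' @export
read_litter_params <- function(path) {
  if (!file.exists(path))
    stop(sprintf("parameter file not found: %s", path), call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(raw) || length(raw) == 0L)
    stop("parameter file is empty or malformed", call. = FALSE)
  # a single bare block (has lwc_max at top level) vs a map of blocks
  if (!is.null(raw$lwc_max)) return(as_litter_params(raw))
  out <- lapply(raw, as_litter_params)
  names(out) <- names(raw)
  out
}

as_litter_params <- function(block) {
  if (is_litter_params(block)) return(block)
  required <- c("name", "model", "lwc_max", "k_max", "e")
  missing <- setdiff(required, names(block))
  if (length(missing))
    stop(sprintf("parameter block missing field(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!block$model %in% c("moyano", "bunnell"))
    stop(sprintf("unknown model kind '%s'", block$model), call. = FALSE)
  litter_params(name = block$name, lwc_max = block$lwc_max,
                k_max = block$k_max, e = block$e, model = block$model,
                a = block$a, b = block$b, c = block$c, d = block$d)
}

#' @rdname read_litter_params
#' @param params a \code{litter_params} or a named list of them.
#' @export
write_litter_params <- function(params, path) {
  if (is_litter_params(params)) params <- list(litter = params)
  stopifnot(is.list(params), all(vapply(params, is_litter_params, TRUE)))
  strip <- function(p) Filter(Negate(is.null), unclass(p))
  out <- lapply(params, strip)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(out, path)
  invisible(path)
}

#' Observation series
#'
#' Long-format container for measured (or synthetic) destructive
#' sampling observations: one row per sampling day, replicate and
#' variable.  \code{variable} is \code{"lwc"} (litter water content,
#' g water per g dry matter) or \code{"mass_fraction"} (remaining
#' mass as a fraction of initial dry mass, in \code{(0, 1]}).
#'
#' @param day integer sampling day (>= 0).
#' @param replicate replicate identifier.
#' @param litter litter/treatment label.
#' @param treatment \code{"alone"} or \code{"mixture"}.
#' @param variable \code{"lwc"} or \code{"mass_fraction"}.
#' @param value measured value.
#' @return A data frame of class \code{"observation_series"}.
#' @export
observation_series <- function(day, replicate, litter, treatment,
                               variable, value) {
  df <- data.frame(day = as.integer(day), replicate = replicate,
                   litter = litter, treatment = treatment,
                   variable = variable, value = value)
  validate_observations(df)
}

validate_observations <- function(df) {
  required <- c("day", "replicate", "litter", "treatment", "variable",
                "value")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("observations missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  bad_row <- function(cond, what) {
    if (any(cond))
      stop(sprintf("invalid observation(s), row %s: %s",
                   paste(which(cond), collapse = ", "), what),
           call. = FALSE)
  }
  bad_row(!is.finite(df$value), "non-numeric or missing value")
  bad_row(is.na(df$day) | df$day < 0, "negative or missing day")
  bad_row(!df$variable %in% c("lwc", "mass_fraction"),
          "variable must be 'lwc' or 'mass_fraction'")
  is_mass <- df$variable == "mass_fraction"
  bad_row(is_mass & (df$value <= 0 | df$value > 1),
          "mass_fraction outside (0, 1]")
  bad_row(!is_mass & df$value < 0, "negative water content")
  class(df) <- c("observation_series", "data.frame")
  df
}

#' Load observations from CSV
#'
#' Reads a long-format observation CSV with columns \code{day},
#' \code{replicate}, \code{litter}, \code{treatment}, \code{variable},
#' \code{value}.  External files with different column names (such as
#' a downloaded data deposit) are adapted via \code{column_mapping}, a
#' named character vector mapping the expected names to the file's
#' names, e.g. \code{c(day = "time_d", value = "measurement")}.
#' Remaining-mass values recorded in percent are rescaled to fractions
#' with \code{mass_unit = "percent"}.
#'
#' @param path CSV file.
#' @param column_mapping optional named character vector (see above).
#' @param mass_unit \code{"fraction"} (default) or \code{"percent"}.
#' @return An \code{\link{observation_series}}; rows failing
#'   validation raise an error naming the offending rows.
#' @export
load_observations <- function(path, column_mapping = NULL,
                              mass_unit = c("fraction", "percent")) {
  mass_unit <- match.arg(mass_unit)
  if (!file.exists(path))
    stop(sprintf("observation file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_mapping)) {
    for (want in names(column_mapping)) {
      have <- column_mapping[[want]]
      if (!have %in% names(df))
        stop(sprintf("mapped column '%s' not in file", have),
             call. = FALSE)
      names(df)[names(df) == have] <- want
    }
  }
  if (!"treatment" %in% names(df)) df$treatment <- "alone"
  if (!"replicate" %in% names(df)) df$replicate <- seq_len(nrow(df))
  if (!is.numeric(df$value))
    stop("column 'value' is not numeric; check the file's decimal format",
         call. = FALSE)
  if (mass_unit == "percent") {
    sel <- df$variable == "mass_fraction"
    df$value[sel] <- df$value[sel] / 100
  }
  validate_observations(df[, c("day", "replicate", "litter",
                               "treatment", "variable", "value")])
}

#' @rdname load_observations
#' @param obs an \code{observation_series} to write.
#' @export
write_observations <- function(obs, path) {
  utils::write.csv(as.data.frame(obs), path, row.names = FALSE)
  invisible(path)
}

#' The deposited laboratory data
#'
#' The calibration/validation case study uses laboratory decomposition
#' data for \emph{Sphagnum rubellum} and \emph{Molinia caerulea}
#' deposited on Zenodo (DOI \code{10.5281/zenodo.4789262}).  The
#' deposit is never fetched automatically; download it yourself and
#' point \code{\link{load_observations}} at the extracted table, using
#' \code{column_mapping} to adapt its column names to the package
#' schema.  \code{zenodo_info()} prints the DOI and the expected
#' target schema.
#'
#' @return The DOI string, invisibly.
#' @export
zenodo_info <- function() {
  doi <- "10.5281/zenodo.4789262"
  cat("Laboratory decomposition data deposit\n")
  cat(sprintf("  DOI: https://doi.org/%s\n", doi))
  cat("  Expected long-format schema after column mapping:\n")
  cat("    day,replicate,litter,treatment,variable,value\n")
  cat("  treatment: 'alone' or 'mixture'; variable: 'lwc' or",
      "'mass_fraction'\n")
  invisible(doi)
}
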