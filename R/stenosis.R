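# Stenosis <-> distal resistance mapping. A stenosis of fractional
# diameter reduction s shrinks the radius of the (circular) distal lumen
# by the same fraction, so at fixed viscosity and length the
# Hagen-Poiseuille resistance scales as (1 - s)^-4. The viscosity cancels
# in the ratio R(s)/R0, so the scaling is independent of the rheology.

#' Stenosis severity specification
#'
#' @param branch Outlet branch name.
#' @param severity Fractional diameter reduction, in `[0, 0.95]`.
#' @return An object of class `stenosis_spec`.
#' @export
stenosis_spec <- function(branch, severity) {
  stopifnot(is.character(branch), length(branch) == 1L)
  if (severity < 0 || severity >= 1)
    stop("stenosis_spec: severity must lie in [0, 1)", call. = FALSE)
  structure(list(branch = branch, severity = severity),
            class = "stenosis_spec")
}

#' Distal resistance at a given stenosis severity
#'
#' `R(s) = R0 / (1 - s)^4`: fourth-power radius scaling of the
#' Hagen-Poiseuille resistance under a fractional diameter reduction `s`.
#'
#' @param healthy_resistance Healthy (severity-0) resistance R0, > 0.
#'   Vectorised.
#' @param severity Fractional diameter reduction, in `[0, 1)`. Vectorised.
#' @return Resistance (kg m^-4 s^-1).
#' @export
stenosis_resistance <- function(healthy_resistance, severity) {
  if (any(severity < 0 | severity >= 1))
    stop("stenosis_resistance: severity must lie in [0, 1)", call. = FALSE)
  if (any(healthy_resistance <= 0))
    stop("stenosis_resistance: healthy_resistance must be > 0",
         call. = FALSE)
  healthy_resistance / (1 - severity)^4
}

#' Severity implied by a resistance
#'
#' Closed-form inverse of [stenosis_resistance()]:
#' `s = 1 - (R0/R)^(1/4)`.
#'
#' @param resistance Stenosed resistance, >= `healthy_resistance`.
#' @param healthy_resistance Healthy resistance R0, > 0.
#' @return Severity (fractional diameter reduction).
#' @export
severity_from_resistance <- function(resistance, healthy_resistance) {
  if (any(healthy_resistance <= 0))
    stop("severity_from_resistance: healthy_resistance must be > 0",
         call. = FALSE)
  if (any(resistance < healthy_resistance))
    stop("severity_from_resistance: resistance must be >= healthy_resistance",
         call. = FALSE)
  1 - (healthy_resistance / resistance)^(1 / 4)
}

#' Resistance table over branches and severities
#'
#' Builds the branch-by-severity table of distal resistances,
#' `R(s) = R0 / (1 - s)^4` for every combination.
#'
#' @param healthy Named numeric vector (or list) of healthy resistances
#'   per branch.
#' @param severities Severity grid in `[0, 1)`.
#' @return A data frame with `severity_percent` followed by one column per
#'   branch (resistances in kg m^-4 s^-1). Zero severities given an empty
#'   grid yield a zero-row table.
#' @examples
#' build_resistance_table(c(M1 = 1.04e8, M2 = 2.43e8, ACA = 3.34e8),
#'                        seq(0, 0.6, by = 0.1))
#' @export
build_resistance_table <- function(healthy, severities) {
  healthy <- unlist(healthy)
  if (is.null(names(healthy)) || any(!nzchar(names(healthy))))
    stop("build_resistance_table: healthy resistances must be named",
         call. = FALSE)
  if (length(severities) && any(severities < 0 | severities >= 1))
    stop("build_resistance_table: severities must lie in [0, 1)",
         call. = FALSE)
  out <- data.frame(severity_percent = round(100 * severities))
  for (b in names(healthy))
    out[[b]] <- stenosis_resistance(healthy[[b]], severities)
  out
}

#' Write a resistance table as CSV
#'
#' Severities as integer percent, resistances in scientific notation with
#' three significant figures, so regenerated files are byte-comparable.
#'
#' @param table Output of [build_resistance_table()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_resistance_table <- function(table, path) {
  fmt <- table
  for (b in setdiff(names(table), "severity_percent"))
    fmt[[b]] <- formatC(table[[b]], format = "e", digits = 2)
  utils::write.csv(fmt, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
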