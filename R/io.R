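# Configuration schema and file I/O. The run configuration is a YAML
# document validated against an in-package schema: unknown keys are
# rejected and every violation is reported with its path, so a typo never
# silently falls back to a default. Units are embedded in column names
# throughout the CSV dialect (comma-separated, period decimal, header
# mandatory).

#' Default run configuration
#'
#' The fully resolved default configuration: Carreau rheology, the default
#' tree geometry with the healthy outlet resistances, the synthetic inlet
#' waveform, a 0-60% severity sweep in 2% steps over M1, M2 and ACA, and
#' the analysis options.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    rheology = list(mu_zero = 0.056, mu_inf = 0.0035, lambda_c = 3.313,
                    n_index = 0.3568, rho = 1060),
    geometry = generate_default_geometry(),
    windkessel = list(tau_s = 1.0, distal_pressure_Pa = 0),
    waveform = list(source = "generate", period_s = 0.876,
                    mean_flow_m3_per_s = 4.17e-6, peak_to_mean = 1.8,
                    systolic_fraction = 0.35, samples_per_cycle = 128L),
    simulation = list(dt_s = 1e-3, n_cycles = 5L),
    sweep = list(branches = c("M1", "M2", "ACA"), severity_max = 0.6,
                 severity_step = 0.02),
    calibration = list(sites = c("ACA", "MCA"), tolerance = 0.01,
                       max_iterations = 100L, damping = 1,
                       tunable = c("M1", "M2", "ACA")),
    analysis = list(sensitivity_statistic = "mean",
                    ffr_pressure_offset_Pa = 0,
                    reference_branch = "M1"),
    seed = 1L), class = "run_config")
}

# schema: allowed keys per config section; NULL marks free-form subtrees
.config_schema <- function() {
  list(rheology = c("mu_zero", "mu_inf", "lambda_c", "n_index", "rho"),
       geometry = c("segments", "inlet", "outlet_resistances",
                    "measurement_sites"),
       windkessel = c("tau_s", "distal_pressure_Pa"),
       waveform = c("source", "period_s", "mean_flow_m3_per_s",
                    "peak_to_mean", "systolic_fraction",
                    "samples_per_cycle", "file"),
       simulation = c("dt_s", "n_cycles"),
       sweep = c("branches", "severity_max", "severity_step"),
       calibration = c("sites", "tolerance", "max_iterations", "damping",
                       "tunable", "targets"),
       analysis = c("sensitivity_statistic", "ffr_pressure_offset_Pa",
                    "reference_branch"),
       seed = NA)
}

#' Validate a run configuration
#'
#' Checks key names against the schema and value ranges; collects every
#' violation (with its dotted path) before failing.
#'
#' @param config A configuration list.
#' @return The config, invisibly, if valid; otherwise an error listing
#'   every offending key.
#' @export
validate_config <- function(config) {
  schema <- .config_schema()
  errs <- character(0)
  bad_top <- setdiff(names(config), names(schema))
  if (length(bad_top))
    errs <- c(errs, paste0("unknown key: ", bad_top))
  for (sec in intersect(names(config), names(schema))) {
    allowed <- schema[[sec]]
    if (length(allowed) == 1L && is.na(allowed[1])) next
    bad <- setdiff(names(config[[sec]]), allowed)
    if (length(bad))
      errs <- c(errs, paste0("unknown key: ", sec, ".", bad))
  }
  chk <- function(cond, path, msg)
    if (!isTRUE(cond)) errs <<- c(errs, paste0(path, ": ", msg))
  rh <- config$rheology
  if (!is.null(rh)) {
    chk(rh$mu_inf > 0 && rh$mu_zero > rh$mu_inf, "rheology",
        "need 0 < mu_inf < mu_zero")
    chk(rh$lambda_c > 0, "rheology.lambda_c", "must be > 0")
    chk(rh$n_index > 0 && rh$n_index <= 1, "rheology.n_index",
        "must lie in (0, 1]")
    chk(rh$rho > 0, "rheology.rho", "must be > 0")
  }
  ge <- config$geometry
  if (!is.null(ge)) {
    for (g in ge$segments) {
      chk(g$radius_m > 0, paste0("geometry.segments.", g$name, ".radius_m"),
          "must be > 0")
      chk(g$length_m > 0, paste0("geometry.segments.", g$name, ".length_m"),
          "must be > 0")
    }
    for (b in names(ge$outlet_resistances))
      chk(ge$outlet_resistances[[b]] > 0,
          paste0("geometry.outlet_resistances.", b), "must be > 0")
  }
  wv <- config$waveform
  if (!is.null(wv)) {
    chk(wv$source %in% c("generate", "file"), "waveform.source",
        "must be 'generate' or 'file'")
    chk(wv$period_s > 0, "waveform.period_s", "must be > 0")
    chk(wv$peak_to_mean >= 1, "waveform.peak_to_mean", "must be >= 1")
    chk(wv$systolic_fraction > 0 && wv$systolic_fraction < 1,
        "waveform.systolic_fraction", "must lie in (0, 1)")
  }
  sw <- config$sweep
  if (!is.null(sw)) {
    chk(sw$severity_max >= 0 && sw$severity_max < 1, "sweep.severity_max",
        "must lie in [0, 1)")
    chk(sw$severity_step > 0, "sweep.severity_step", "must be > 0")
  }
  ca <- config$calibration
  if (!is.null(ca)) {
    chk(ca$tolerance > 0, "calibration.tolerance", "must be > 0")
    chk(ca$damping > 0 && ca$damping <= 1, "calibration.damping",
        "must lie in (0, 1]")
  }
  an <- config$analysis
  if (!is.null(an))
    chk(an$sensitivity_statistic %in% c("mean", "systolic"),
        "analysis.sensitivity_statistic", "must be 'mean' or 'systolic'")
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "),
         call. = FALSE)
  invisible(config)
}

#' Load a run configuration from YAML
#'
#' Reads the file, rejects unknown keys, validates values, and merges the
#' result over [default_config()] so all unspecified fields resolve to
#' their defaults.
#'
#' @param path YAML file path.
#' @return A validated, fully resolved `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("load_config: no such file: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  validate_config(user)
  cfg <- utils::modifyList(default_config(), user)
  # geometry is replaced wholesale, not merged field-by-field
  if (!is.null(user$geometry)) cfg$geometry <- user$geometry
  validate_config(cfg)
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#'
#' @param config A `run_config` list.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Build the model objects described by a configuration
#'
#' @param config A `run_config` list.
#' @return List with `network` ([vessel_network()]), `waveform`
#'   ([inlet_waveform()]) and `params` ([rheology_params()]).
#' @export
build_from_config <- function(config) {
  params <- with(config$rheology,
                 rheology_params(mu_zero, mu_inf, lambda_c, n_index, rho))
  network <- assemble_default_tree(config$geometry,
                                   tau = config$windkessel$tau_s,
                                   distal_pressure =
                                     config$windkessel$distal_pressure_Pa)
  wv <- config$waveform
  waveform <- if (identical(wv$source, "file")) {
    read_waveform_csv(wv$file, period = wv$period_s)
  } else {
    generate_inlet_waveform(waveform_params(
      period = wv$period_s, mean_flow = wv$mean_flow_m3_per_s,
      peak_to_mean = wv$peak_to_mean,
      systolic_fraction = wv$systolic_fraction,
      samples_per_cycle = wv$samples_per_cycle))
  }
  list(network = network, waveform = waveform, params = params)
}

#' Read an inlet waveform from two-column CSV
#'
#' Expects columns `time_s` and either `flow_m3_per_s` or
#' `velocity_m_per_s` (the header declares the units).
#'
#' @param path CSV path.
#' @param period Cardiac period (s); defaults to the time span implied by
#'   the sample grid (last time plus one sample interval).
#' @param inlet_area Inlet area (m^2), required for velocity waveforms.
#' @return An [inlet_waveform()].
#' @export
read_waveform_csv <- function(path, period = NULL, inlet_area = NULL) {
  d <- utils::read.csv(path)
  if (!"time_s" %in% names(d))
    stop("read_waveform_csv: column 'time_s' missing", call. = FALSE)
  vcol <- intersect(c("flow_m3_per_s", "velocity_m_per_s"), names(d))
  if (length(vcol) != 1L)
    stop("read_waveform_csv: need exactly one of 'flow_m3_per_s' or ",
         "'velocity_m_per_s'", call. = FALSE)
  if (is.null(period)) {
    dt <- diff(d$time_s)
    period <- d$time_s[nrow(d)] + dt[length(dt)]
  }
  inlet_waveform(d$time_s, d[[vcol]], period,
                 units = if (vcol == "flow_m3_per_s") "flow" else "velocity",
                 inlet_area = inlet_area)
}

#' Write an inlet waveform as two-column CSV
#'
#' @param waveform An [inlet_waveform()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  col <- if (waveform$units == "flow") "flow_m3_per_s" else "velocity_m_per_s"
  d <- data.frame(time_s = waveform$times, v = waveform$values)
  names(d)[2] <- col
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a simulation result as long-format CSV
#'
#' One row per (time, site): pressure, flow and plane-averaged velocity
#' over the final cycle.
#'
#' @param result A [simulate_pulsatile()] result.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_simulation_csv <- function(result, path) {
  sites <- result$sites
  rows <- lapply(sites, function(s) data.frame(
    time_s = result$time, site = s,
    pressure_Pa = result$site_pressure[, s],
    flow_m3_per_s = result$branch_flow[, s],
    velocity_m_per_s = result$site_velocity[, s]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Run-metadata JSON
#'
#' Writes the reproducibility envelope of an artifact: a hash of the
#' resolved configuration, the seed, and the package version.
#'
#' @param config The `run_config` that produced the artifact.
#' @param path Destination path.
#' @param extra Optional named list merged into the metadata.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(config, path, extra = list()) {
  cfg_txt <- yaml::as.yaml(unclass(config))
  meta <- c(list(
    config_sha = .simple_hash(cfg_txt),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("icaflow"))),
    extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# dependency-free polynomial rolling hash, hex-encoded
.simple_hash <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
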