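# Synthetic inputs: pulsatile inlet waveform, default geometry, and noisy
# calibration targets. These stand in for subject-specific PCMRI data,
# which is not publicly available; every generator is a pure function of
# its parameters (seed included).

#' Inlet waveform shape parameters
#'
#' Parameters of the synthetic carotid inlet waveform. Defaults: cardiac
#' period 0.876 s; cycle-mean flow 4.17e-6 m^3 s^-1 (the sum of the
#' healthy ACA and MCA branch flows, 0.964 + 3.206 ml s^-1); systolic
#' peak at 1.8 times the mean; systole occupying 35% of the cycle; 128
#' samples per cycle.
#'
#' @param period Cardiac period (s), > 0.
#' @param mean_flow Cycle-mean flow (m^3 s^-1).
#' @param peak_to_mean Peak/mean flow ratio, >= 1 (1 gives constant flow).
#' @param systolic_fraction Fraction of the cycle occupied by systole,
#'   in (0, 1).
#' @param samples_per_cycle Number of samples per cycle (>= 16).
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(period = 0.876, mean_flow = 4.17e-6,
                            peak_to_mean = 1.8, systolic_fraction = 0.35,
                            samples_per_cycle = 128L) {
  if (period <= 0) stop("waveform_params: period must be > 0", call. = FALSE)
  if (peak_to_mean < 1)
    stop("waveform_params: peak_to_mean must be >= 1", call. = FALSE)
  if (systolic_fraction <= 0 || systolic_fraction >= 1)
    stop("waveform_params: systolic_fraction must lie in (0, 1)",
         call. = FALSE)
  if (samples_per_cycle < 16L)
    stop("waveform_params: at least 16 samples per cycle", call. = FALSE)
  structure(list(period = period, mean_flow = mean_flow,
                 peak_to_mean = peak_to_mean,
                 systolic_fraction = systolic_fraction,
                 samples_per_cycle = as.integer(samples_per_cycle)),
            class = "waveform_params")
}

#' Generate a synthetic pulsatile inlet waveform
#'
#' Deterministic smooth periodic flow waveform: a Gaussian systolic pulse
#' superposed on an exponential diastolic decay, renormalised so that the
#' cycle mean equals `mean_flow` exactly (to floating-point precision) and
#' the single systolic maximum sits at `peak_to_mean` times the mean.
#' `peak_to_mean = 1` degenerates to constant flow.
#'
#' @param params A [waveform_params()].
#' @return An [inlet_waveform()] in flow units, strictly positive.
#' @examples
#' wf <- generate_inlet_waveform()
#' waveform_cycle_mean(wf)
#' @export
generate_inlet_waveform <- function(params = waveform_params()) {
  m <- params$samples_per_cycle
  tt <- (0:(m - 1)) / m                   # phase in [0, 1)
  tp <- params$systolic_fraction / 2      # systolic peak phase
  sg <- params$systolic_fraction / 4      # pulse width
  # systolic pulse over a diastolic decay; zero-mean feature scaled to the
  # requested peak-to-mean ratio
  f <- exp(-0.5 * ((tt - tp) / sg)^2) + 0.3 * exp(-4 * tt)
  g <- f - mean(f)
  amp <- (params$peak_to_mean - 1) / max(g)
  u <- 1 + amp * g
  if (any(u <= 0))
    stop("generate_inlet_waveform: parameters yield non-positive flow ",
         "(reduce peak_to_mean or widen systolic_fraction)", call. = FALSE)
  u <- u / mean(u)                        # cycle mean exactly 1 on the grid
  q <- params$mean_flow * u
  inlet_waveform(times = tt * params$period, values = q,
                 period = params$period, units = "flow")
}

#' Default tree geometry
#'
#' Geometry configuration of the truncated internal-carotid tree. Trunk
#' radii are chosen so that the plane-averaged velocities implied by the
#' healthy branch flows match measured values: the MCA radius 1.568 mm
#' inverts 3.206 ml s^-1 at 0.415 m s^-1, the ACA radius 1.166 mm inverts
#' 0.964 ml s^-1 at 0.226 m s^-1. The ICA trunk is 2.0 mm by 30 mm; the
#' M1/M2/OA stubs are 5 mm long with radii 1.4/1.1/0.6 mm (segment
#' resistances are second-order next to the outlet resistances). Healthy
#' outlet resistances are 1.04e8 (M1), 2.43e8 (M2), 3.34e8 (ACA) and
#' 1.33e12 (OA) kg m^-4 s^-1.
#'
#' @return A geometry configuration list consumed by
#'   [assemble_default_tree()]: `segments`, `inlet`,
#'   `outlet_resistances`, `measurement_sites`.
#' @export
generate_default_geometry <- function() {
  list(
    segments = list(
      list(name = "ICA", parent = NA, radius_m = 2.0e-3, length_m = 30e-3),
      list(name = "OA",  parent = "ICA", radius_m = 0.6e-3, length_m = 5e-3),
      list(name = "ACA", parent = "ICA", radius_m = 1.166e-3, length_m = 10e-3),
      list(name = "MCA", parent = "ICA", radius_m = 1.568e-3, length_m = 10e-3),
      list(name = "M1",  parent = "MCA", radius_m = 1.4e-3, length_m = 5e-3),
      list(name = "M2",  parent = "MCA", radius_m = 1.1e-3, length_m = 5e-3)),
    inlet = "ICA",
    outlet_resistances = list(M1 = 1.04e8, M2 = 2.43e8, ACA = 3.34e8,
                              OA = 1.33e12),
    measurement_sites = c("ICA", "ACA", "MCA", "M1", "M2"))
}

#' Noise parameters for synthetic measurements
#'
#' @param sd Relative standard deviation of the multiplicative noise,
#'   >= 0.
#' @param seed Integer random seed; recorded alongside the outputs.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sd = 0.05, seed = 1L) {
  if (sd < 0) stop("noise_params: sd must be >= 0", call. = FALSE)
  structure(list(sd = sd, seed = as.integer(seed)), class = "noise_params")
}

#' Generate plane-averaged velocity targets
#'
#' Forward-simulates the network and extracts cycle-mean plane-averaged
#' velocities at the requested measurement sites, then applies seeded
#' multiplicative lognormal noise emulating plane-averaged PCMRI
#' measurement scatter. `sd = 0` returns the exact model velocities.
#'
#' @param network A [vessel_network()].
#' @param waveform An [inlet_waveform()].
#' @param noise A [noise_params()].
#' @param sites Measurement sites to target (default the ACA and MCA
#'   validation planes).
#' @param method `"steady"` (cycle-mean inflow, quasi-steady solve) or
#'   `"pulsatile"`.
#' @param ... Passed to [simulate_pulsatile()] when
#'   `method = "pulsatile"`.
#' @return Named numeric vector of target velocities (m s^-1) with
#'   attributes `seed` and `sd` recording the noise settings.
#' @export
generate_velocity_targets <- function(network, waveform,
                                      noise = noise_params(sd = 0),
                                      sites = c("ACA", "MCA"),
                                      method = c("steady", "pulsatile"),
                                      ...) {
  method <- match.arg(method)
  bad <- setdiff(sites, network$measurement_sites)
  if (length(bad))
    stop("generate_velocity_targets: unknown site '", bad[1], "'",
         call. = FALSE)
  v <- cycle_mean_site_velocities(network, waveform, method = method, ...)
  v <- v[sites]
  if (noise$sd > 0) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(noise$seed)
    # multiplicative lognormal scatter with relative sd ~ noise$sd
    s2 <- log(1 + noise$sd^2)
    v <- v * exp(stats::rnorm(length(v), -s2 / 2, sqrt(s2)))
  }
  attr(v, "seed") <- noise$seed
  attr(v, "sd") <- noise$sd
  v
}

#' Cycle-mean plane-averaged velocities at all measurement sites
#'
#' Convenience wrapper shared by the calibration loop and the target
#' generator: either a quasi-steady solve at the cycle-mean inflow or a
#' full pulsatile simulation.
#'
#' @inheritParams generate_velocity_targets
#' @param ... Passed to [simulate_pulsatile()].
#' @return Named numeric vector over the network's measurement sites.
#' @export
cycle_mean_site_velocities <- function(network, waveform,
                                       method = c("steady", "pulsatile"),
                                       ...) {
  method <- match.arg(method)
  if (method == "steady") {
    q <- waveform_cycle_mean(as_flow_waveform(waveform))
    sol <- solve_steady(network, q, ...)
    i <- match(network$measurement_sites, sol$segments$segment)
    setNames(sol$segments$velocity_m_per_s[i], network$measurement_sites)
  } else {
    sim <- simulate_pulsatile(network, waveform, ...)
    setNames(sim$summary$v_mean_m_per_s, sim$summary$site)
  }
}
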