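#' Periodic inlet waveform
#'
#' One cardiac cycle of the inlet boundary forcing, sampled on a strictly
#' increasing time grid spanning `[0, period)`. Values are either a
#' volumetric flow or a plane-averaged velocity; velocity waveforms carry
#' the inlet cross-sectional area used to convert to flow.
#'
#' @param times Sample times (s), strictly increasing, in `[0, period)`;
#'   at least 16 samples.
#' @param values Flow (m^3 s^-1) or velocity (m s^-1) samples; finite.
#' @param period Cardiac period T (s), > 0.
#' @param units `"flow"` or `"velocity"`.
#' @param inlet_area Inlet cross-sectional area (m^2); required when
#'   `units = "velocity"`.
#' @return An object of class `inlet_waveform`.
#' @export
inlet_waveform <- function(times, values, period,
                           units = c("flow", "velocity"),
                           inlet_area = NULL) {
  units <- match.arg(units)
  if (!is.numeric(period) || period <= 0)
    stop("inlet_waveform: period must be > 0", call. = FALSE)
  if (length(times) < 16L)
    stop("inlet_waveform: at least 16 samples per period required",
         call. = FALSE)
  if (length(times) != length(values))
    stop("inlet_waveform: times and values differ in length", call. = FALSE)
  if (any(diff(times) <= 0))
    stop("inlet_waveform: times must be strictly increasing", call. = FALSE)
  if (times[1] < 0 || times[length(times)] >= period)
    stop("inlet_waveform: times must lie in [0, period)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("inlet_waveform: values must be finite", call. = FALSE)
  if (units == "velocity" &&
      (is.null(inlet_area) || !is.numeric(inlet_area) || inlet_area <= 0))
    stop("inlet_waveform: velocity waveforms need a positive inlet_area",
         call. = FALSE)
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 period = period, units = units, inlet_area = inlet_area),
            class = "inlet_waveform")
}

#' @export
print.inlet_waveform <- function(x, ...) {
  cat(sprintf("inlet_waveform: %d samples, period %.4g s, units %s, mean %.4g\n",
              length(x$times), x$period, x$units, waveform_cycle_mean(x)))
  invisible(x)
}

#' Convert a waveform to volumetric flow
#'
#' Velocity waveforms are multiplied by the inlet area; flow waveforms are
#' returned unchanged.
#'
#' @param waveform An [inlet_waveform()].
#' @return An [inlet_waveform()] in flow units.
#' @export
as_flow_waveform <- function(waveform) {
  if (waveform$units == "flow") return(waveform)
  inlet_waveform(waveform$times, waveform$values * waveform$inlet_area,
                 waveform$period, units = "flow")
}

#' Cycle mean of a periodic waveform
#'
#' Period-exact quadrature for a periodic signal: the mean of the
#' left-endpoint samples weighted by the inter-sample intervals (the
#' wrap-around interval closes the cycle).
#'
#' @param waveform An [inlet_waveform()].
#' @return Cycle-mean value in the waveform's own units.
#' @export
waveform_cycle_mean <- function(waveform) {
  t <- waveform$times
  w <- diff(c(t, t[1] + waveform$period))
  sum(waveform$values * w) / waveform$period
}

#' Evaluate a waveform at arbitrary times
#'
#' Periodic linear interpolation of the flow signal; velocity waveforms
#' are converted through the inlet area first.
#'
#' @param waveform An [inlet_waveform()].
#' @param t Times (s); any real values, folded into the cycle.
#' @return Flow (m^3 s^-1) at `t`.
#' @export
waveform_flow_at <- function(waveform, t) {
  wf <- as_flow_waveform(waveform)
  tt <- t %% wf$period
  xs <- c(wf$times, wf$times[1] + wf$period)
  ys <- c(wf$values, wf$values[1])
  # points before the first sample wrap to the tail of the cycle
  tt[tt < xs[1]] <- tt[tt < xs[1]] + wf$period
  stats::approx(xs, ys, xout = tt, rule = 2)$y
}

#' Rescale a waveform to a target cycle mean
#'
#' Uniform multiplicative scaling so the cycle mean equals `target_mean`;
#' the normalised shape is unchanged. Mirrors the scaling of a measured
#' velocity waveform to match a flow estimate at the inlet plane.
#'
#' @param waveform An [inlet_waveform()].
#' @param target_mean Desired cycle mean, in the waveform's own units.
#' @return The scaled [inlet_waveform()].
#' @export
scale_waveform <- function(waveform, target_mean) {
  m <- waveform_cycle_mean(waveform)
  if (m == 0)
    stop("scale_waveform: waveform has zero cycle mean", call. = FALSE)
  inlet_waveform(waveform$times, waveform$values * (target_mean / m),
                 waveform$period, units = waveform$units,
                 inlet_area = waveform$inlet_area)
}
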