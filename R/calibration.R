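# Outlet-resistance calibration: iteratively retune the Windkessel distal
# resistances until simulated cycle-mean plane-averaged velocities at the
# target sites match measured (or synthetic) values. The update is
# per-outlet multiplicative with the velocity ratio, exploiting the
# monotone resistance-velocity relationship: raising an outlet's
# resistance lowers the velocity at every site upstream of it.

#' Calibration problem
#'
#' @param network A [vessel_network()] carrying the initial outlet
#'   resistances.
#' @param waveform The inlet [inlet_waveform()].
#' @param targets Named numeric vector of target cycle-mean plane-averaged
#'   velocities (m s^-1); names are measurement sites, each upstream of at
#'   least one tunable outlet.
#' @param tolerance Relative velocity error at which a site counts as
#'   matched (default 0.01).
#' @param max_iterations Iteration cap (default 100).
#' @param tunable Outlets allowed to move. Defaults to all outlets except
#'   OA, whose very high distal resistance makes its flow negligible.
#' @param damping Exponent applied to the multiplicative update, in
#'   (0, 1]; 1 is the undamped update.
#' @param method `"steady"` (quasi-steady solve at the cycle-mean inflow,
#'   the default) or `"pulsatile"`.
#' @param ... Passed to the forward model ([solve_steady()] or
#'   [simulate_pulsatile()]).
#' @return An object of class `calibration_problem`.
#' @export
calibration_problem <- function(network, waveform, targets,
                                tolerance = 0.01, max_iterations = 100L,
                                tunable = setdiff(names(network$outlets),
                                                  "OA"),
                                damping = 1,
                                method = c("steady", "pulsatile"), ...) {
  method <- match.arg(method)
  if (is.null(names(targets)) || any(!nzchar(names(targets))))
    stop("calibration_problem: targets must be named by site", call. = FALSE)
  if (any(targets <= 0))
    stop("calibration_problem: target velocities must be > 0", call. = FALSE)
  if (tolerance <= 0)
    stop("calibration_problem: tolerance must be > 0", call. = FALSE)
  if (damping <= 0 || damping > 1)
    stop("calibration_problem: damping must lie in (0, 1]", call. = FALSE)
  bad <- setdiff(names(targets), network$measurement_sites)
  if (length(bad))
    stop("calibration_problem: target site '", bad[1],
         "' is not a measurement site", call. = FALSE)
  bad <- setdiff(tunable, names(network$outlets))
  if (length(bad))
    stop("calibration_problem: tunable outlet '", bad[1], "' not found",
         call. = FALSE)
  # map each target site to the tunable outlets downstream of it
  site_outlets <- lapply(names(targets), function(s)
    intersect(.descendant_leaves(network, s), tunable))
  names(site_outlets) <- names(targets)
  empty <- names(targets)[vapply(site_outlets, length, integer(1)) == 0L]
  if (length(empty))
    stop("calibration_problem: no tunable outlet downstream of site '",
         empty[1], "'", call. = FALSE)
  structure(list(network = network, waveform = waveform, targets = targets,
                 tolerance = tolerance,
                 max_iterations = as.integer(max_iterations),
                 tunable = tunable, damping = damping, method = method,
                 site_outlets = site_outlets, forward_args = list(...)),
            class = "calibration_problem")
}

# leaves of the subtree rooted at segment s (s itself if a leaf)
.descendant_leaves <- function(network, s) {
  acc <- character(0)
  stack <- s
  while (length(stack)) {
    cur <- stack[[1]]; stack <- stack[-1]
    ch <- network$children[[cur]]
    if (length(ch) == 0L) acc <- c(acc, cur) else stack <- c(stack, ch)
  }
  acc
}

#' Calibrate outlet resistances against velocity targets
#'
#' Fixed-point loop: each iteration runs one forward solution, then
#' updates every tunable outlet multiplicatively,
#' `R <- R * (v_computed / v_target)^damping`, using the velocity at the
#' target site upstream of it (sites feeding several tunable outlets apply
#' the same factor to each, preserving their resistance ratio). The loop
#' stops when all relative site residuals fall within the tolerance or at
#' the iteration cap; non-convergence is reported through the `converged`
#' flag, never as an error.
#'
#' @param problem A [calibration_problem()].
#' @return An object of class `calibration_result`: `resistances` (named,
#'   final), `initial_resistances`, `iterations`, `residuals` (relative,
#'   per site), `converged`, and `history` (per-iteration maximum
#'   residual).
#' @examples
#' net <- assemble_default_tree()
#' wf <- generate_inlet_waveform()
#' tg <- generate_velocity_targets(net, wf)
#' res <- calibrate_outlet_resistances(calibration_problem(net, wf, tg))
#' res$converged
#' @export
calibrate_outlet_resistances <- function(problem) {
  net <- problem$network
  tg <- problem$targets
  sites <- names(tg)
  init <- vapply(problem$tunable,
                 function(b) net$outlets[[b]]$distal_resistance, numeric(1))
  history <- numeric(0)
  resid <- setNames(rep(NA_real_, length(tg)), sites)
  iters <- 0L
  converged <- FALSE
  repeat {
    v <- do.call(cycle_mean_site_velocities,
                 c(list(net, problem$waveform, method = problem$method),
                   problem$forward_args))
    resid <- abs(v[sites] - tg) / tg
    history <- c(history, max(resid))
    if (all(resid <= problem$tolerance)) { converged <- TRUE; break }
    if (iters >= problem$max_iterations) break
    iters <- iters + 1L
    for (s in sites) {
      fac <- (v[[s]] / tg[[s]])^problem$damping
      for (b in problem$site_outlets[[s]]) {
        net <- set_outlet_resistance(
          net, b, net$outlets[[b]]$distal_resistance * fac,
          rescale_compliance = TRUE)
      }
    }
  }
  final <- vapply(problem$tunable,
                  function(b) net$outlets[[b]]$distal_resistance, numeric(1))
  structure(list(resistances = final, initial_resistances = init,
                 iterations = iters, residuals = resid,
                 converged = converged, history = history,
                 network = net),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: %s after %d iterations (max residual %.3g)\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, max(x$residuals)))
  print(data.frame(outlet = names(x$resistances),
                   initial = x$initial_resistances,
                   final = x$resistances, row.names = NULL), digits = 4)
  invisible(x)
}

#' Write a calibration result as JSON
#'
#' @param result A `calibration_result`.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(result, path) {
  jsonlite::write_json(
    list(converged = result$converged, iterations = result$iterations,
         resistances = as.list(result$resistances),
         initial_resistances = as.list(result$initial_resistances),
         residuals = as.list(result$residuals),
         residual_history = result$history),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
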