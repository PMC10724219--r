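# Severity sweeps and the three headline analyses: branch-sensitivity
# statistics, reverse-flow onset thresholds, and fractional flow reserve.

#' Stenosis severity sweep over one branch
#'
#' For each severity on the grid, the target outlet's distal resistance is
#' replaced by `stenosis_resistance(R0, s)` (all other outlets stay at
#' their healthy values), the model is run, and final-cycle summaries are
#' recorded. The severity-0 entry is the healthy baseline.
#'
#' @param network A [vessel_network()] (healthy).
#' @param waveform The inlet [inlet_waveform()].
#' @param branch Outlet branch to stenose.
#' @param severities Severity grid, sorted ascending, starting at 0.
#' @param params A [rheology_params()].
#' @param method `"pulsatile"` (default) or `"steady"` (quasi-steady at
#'   the cycle-mean inflow; no compliance dynamics).
#' @param dt,n_cycles Passed to [simulate_pulsatile()].
#' @param ... Further arguments for the forward model.
#' @return An object of class `sweep_result`: `branch`,
#'   `severities`, `healthy_resistance`, a long `summary` data frame
#'   (severity x site cycle statistics), `outlet` (per-severity cycle-mean
#'   node pressure and flow at the stenosed outlet), and
#'   `site_pressure_series` (per-severity final-cycle site pressure
#'   matrices, used by [reverse_flow_threshold()]).
#' @export
stenosis_sweep <- function(network, waveform, branch,
                           severities = seq(0, 0.6, by = 0.02),
                           params = rheology_params(),
                           method = c("pulsatile", "steady"),
                           dt = 1e-3, n_cycles = 5L, ...) {
  method <- match.arg(method)
  if (!branch %in% names(network$outlets))
    stop("stenosis_sweep: '", branch, "' has no Windkessel outlet",
         call. = FALSE)
  if (length(severities) == 0L || is.unsorted(severities, strictly = TRUE))
    stop("stenosis_sweep: severities must be strictly ascending",
         call. = FALSE)
  if (severities[1] != 0)
    stop("stenosis_sweep: the first severity must be 0 (healthy baseline)",
         call. = FALSE)
  R0 <- network$outlets[[branch]]$distal_resistance
  wf_flow <- as_flow_waveform(waveform)
  q_mean <- waveform_cycle_mean(wf_flow)

  rows <- list(); series <- list(); out_rows <- list()
  cons <- 0
  for (i in seq_along(severities)) {
    s <- severities[i]
    net_s <- set_outlet_resistance(network, branch,
                                   stenosis_resistance(R0, s))
    if (method == "pulsatile") {
      sim <- simulate_pulsatile(net_s, wf_flow, dt = dt,
                                n_cycles = n_cycles, params = params, ...)
      summ <- sim$summary
      osum <- sim$outlet_summary
      p_node <- osum$p_node_mean_Pa[osum$outlet == branch]
      q_out <- osum$q_mean_m3_per_s[osum$outlet == branch]
      cons <- max(cons, sim$conservation)
      series[[i]] <- sim$site_pressure
    } else {
      sol <- solve_steady(net_s, q_mean, params = params, ...)
      k <- match(network$measurement_sites, sol$segments$segment)
      summ <- data.frame(site = network$measurement_sites,
                         p_mean_Pa = sol$segments$p_mid_Pa[k],
                         p_max_Pa = sol$segments$p_mid_Pa[k],
                         p_min_Pa = sol$segments$p_mid_Pa[k],
                         q_mean_m3_per_s = sol$segments$flow_m3_per_s[k],
                         v_mean_m_per_s = sol$segments$velocity_m_per_s[k])
      p_node <- unname(sol$outlet_pressures[branch])
      q_out <- unname(sol$outlet_flows[branch])
      m <- matrix(summ$p_mean_Pa, nrow = 1)
      colnames(m) <- network$measurement_sites
      series[[i]] <- m
    }
    summ$severity <- s
    rows[[i]] <- summ
    out_rows[[i]] <- data.frame(severity = s, p_node_mean_Pa = p_node,
                                q_mean_m3_per_s = q_out)
  }
  structure(list(branch = branch, severities = severities,
                 healthy_resistance = R0,
                 summary = do.call(rbind, rows),
                 outlet = do.call(rbind, out_rows),
                 site_pressure_series = series,
                 conservation = cons,
                 method = method),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("sweep_result: %s stenosis, %d severities in [0, %.2g], %s model\n",
              x$branch, length(x$severities), max(x$severities), x$method))
  invisible(x)
}

#' Relative sensitivity of one branch against a reference
#'
#' `100 * (1 - dP_branch / dP_ref)`: the percentage by which the pressure
#' variation caused by stenosis in one branch falls short of the variation
#' caused by stenosis in the reference branch.
#'
#' @param delta_ref Pressure variation of the reference branch (Pa), != 0.
#' @param delta_branch Pressure variation of the compared branch (Pa).
#'   Vectorised.
#' @return Relative sensitivity in percent.
#' @examples
#' relative_sensitivity(514.88, 220.98)  # 57.1
#' @export
relative_sensitivity <- function(delta_ref, delta_branch) {
  if (any(delta_ref == 0))
    stop("relative_sensitivity: reference variation is zero", call. = FALSE)
  100 * (1 - delta_branch / delta_ref)
}

#' Branch-sensitivity report at one measurement site
#'
#' Compares, across per-branch severity sweeps sharing one grid, the
#' maximum pressure variation each branch's stenosis causes at a given
#' site: the magnitude of the change in the site's cycle-mean (or, with
#' `statistic = "systolic"`, systolic-peak) pressure between the healthy
#' baseline and the top severity. Relative sensitivities are expressed
#' against a reference branch via [relative_sensitivity()].
#'
#' @param sweeps Named list of [stenosis_sweep()] results (names are the
#'   stenosed branches), sharing the severity grid.
#' @param site Measurement site at which pressures are compared.
#' @param reference_branch Branch against which sensitivities are
#'   expressed (default `"M1"`).
#' @param statistic `"mean"` (cycle-mean pressures) or `"systolic"`
#'   (cycle-peak pressures).
#' @return An object of class `sensitivity_report`: a data frame with the
#'   stenosed branch, the signed pressure change (stenosed minus baseline,
#'   Pa), its magnitude `delta_p_max_Pa`, and the relative sensitivity in
#'   percent (0 for the reference branch).
#' @export
sensitivity_report <- function(sweeps, site, reference_branch = "M1",
                               statistic = c("mean", "systolic")) {
  statistic <- match.arg(statistic)
  col <- if (statistic == "mean") "p_mean_Pa" else "p_max_Pa"
  if (!reference_branch %in% names(sweeps))
    stop("sensitivity_report: no sweep for reference branch '",
         reference_branch, "'", call. = FALSE)
  grids <- lapply(sweeps, `[[`, "severities")
  if (length(unique(vapply(grids, paste, character(1), collapse = ","))) != 1L)
    stop("sensitivity_report: sweeps do not share a severity grid",
         call. = FALSE)
  top <- max(grids[[1]])
  change <- vapply(sweeps, function(sw) {
    d <- sw$summary
    if (!site %in% d$site)
      stop("sensitivity_report: site '", site, "' not in sweep summaries",
           call. = FALSE)
    d[[col]][d$site == site & d$severity == top] -
      d[[col]][d$site == site & d$severity == 0]
  }, numeric(1))
  dP <- abs(change)
  if (dP[reference_branch] == 0)
    stop("sensitivity_report: reference branch shows zero pressure ",
         "variation; sensitivity undefined", call. = FALSE)
  structure(data.frame(
    branch = names(sweeps),
    signed_change_Pa = unname(change),
    delta_p_max_Pa = unname(dP),
    relative_sensitivity_pct =
      relative_sensitivity(dP[reference_branch], unname(dP)),
    row.names = NULL),
    site = site, reference_branch = reference_branch,
    statistic = statistic,
    class = c("sensitivity_report", "data.frame"))
}

#' Reverse-flow onset threshold from a sweep
#'
#' For each severity, forms the pressure gradient between two measurement
#' sites over the final cycle, `G(s) = min_t [P_up(t) - P_down(t)]`, and
#' locates the smallest severity at which the gradient turns negative
#' (heralding reverse flow from the downstream towards the upstream site)
#' by linear interpolation between adjacent grid points.
#'
#' @param sweep A [stenosis_sweep()] result (pulsatile sweeps resolve the
#'   within-cycle minimum; steady sweeps reduce to the mean gradient).
#' @param upstream_site,downstream_site Measurement sites present in the
#'   sweep.
#' @return An object of class `reverse_flow_threshold`: `onset_severity`
#'   (`NA` when the gradient stays non-negative — "none within sweep"),
#'   `most_negative_gradient_Pa`, and the per-severity `gradient` curve.
#' @export
reverse_flow_threshold <- function(sweep, upstream_site, downstream_site) {
  sites <- colnames(sweep$site_pressure_series[[1]])
  for (s in c(upstream_site, downstream_site))
    if (!s %in% sites)
      stop("reverse_flow_threshold: site '", s, "' not in sweep",
           call. = FALSE)
  sv <- sweep$severities
  if (is.unsorted(sv, strictly = TRUE))
    stop("reverse_flow_threshold: severity grid must be sorted",
         call. = FALSE)
  G <- vapply(sweep$site_pressure_series, function(m)
    min(m[, upstream_site] - m[, downstream_site]), numeric(1))
  onset <- NA_real_
  if (G[1] < 0) {
    onset <- sv[1]
  } else {
    k <- which(G < 0)
    if (length(k)) {
      k <- k[1]
      # linear root between the bracketing grid points
      onset <- sv[k - 1] + (sv[k] - sv[k - 1]) * G[k - 1] / (G[k - 1] - G[k])
    }
  }
  structure(list(stenosed_branch = sweep$branch,
                 upstream_site = upstream_site,
                 downstream_site = downstream_site,
                 onset_severity = onset,
                 most_negative_gradient_Pa = min(G),
                 gradient = data.frame(severity = sv, gradient_Pa = G)),
            class = "reverse_flow_threshold")
}

#' @export
print.reverse_flow_threshold <- function(x, ...) {
  cat(sprintf("reverse flow %s -> %s under %s stenosis: %s\n",
              x$downstream_site, x$upstream_site, x$stenosed_branch,
              if (is.na(x$onset_severity)) "none within sweep"
              else sprintf("onset at severity %.3f", x$onset_severity)))
  invisible(x)
}

#' Fractional flow reserve at one severity of a sweep
#'
#' FFR is the post- over pre-stenotic pressure ratio. The pre-stenotic
#' pressure is the cycle-mean pressure at the node feeding the stenosed
#' outlet (plus an optional absolute-reference offset); the post-stenotic
#' pressure subtracts the pressure drop across the *added* stenotic
#' resistance, `(R(s) - R0) * Q_mean`, so that FFR is exactly 1 at
#' severity 0.
#'
#' @param sweep A [stenosis_sweep()] result.
#' @param severity A severity present in the sweep grid.
#' @param reference_pressure_offset Absolute-pressure offset added to the
#'   gauge pre-stenotic pressure (Pa); default 0.
#' @return An object of class `ffr_result` with `p_pre_Pa`, `p_post_Pa`
#'   and `ffr`.
#' @export
compute_ffr <- function(sweep, severity, reference_pressure_offset = 0) {
  i <- match(severity, sweep$severities)
  if (is.na(i))
    stop("compute_ffr: severity ", severity, " not in the sweep grid",
         call. = FALSE)
  R0 <- sweep$healthy_resistance
  Rs <- stenosis_resistance(R0, severity)
  p_pre <- sweep$outlet$p_node_mean_Pa[i] + reference_pressure_offset
  if (p_pre <= 0)
    stop("compute_ffr: pre-stenotic pressure <= 0; raise ",
         "reference_pressure_offset", call. = FALSE)
  q <- sweep$outlet$q_mean_m3_per_s[i]
  p_post <- p_pre - pressure_drop(Rs - R0, q)
  structure(list(branch = sweep$branch, severity = severity,
                 p_pre_Pa = p_pre, p_post_Pa = p_post,
                 ffr = p_post / p_pre),
            class = "ffr_result")
}

#' @export
print.ffr_result <- function(x, ...) {
  cat(sprintf("FFR(%s, s = %.2f) = %.3f  (P_pre %.1f Pa, P_post %.1f Pa)\n",
              x$branch, x$severity, x$ffr, x$p_pre_Pa, x$p_post_Pa))
  invisible(x)
}

#' FFR over a whole sweep
#'
#' @param sweep A [stenosis_sweep()] result.
#' @param reference_pressure_offset See [compute_ffr()].
#' @return Data frame of severity, pre/post pressures and FFR over the
#'   sweep grid.
#' @export
ffr_curve <- function(sweep, reference_pressure_offset = 0) {
  rows <- lapply(sweep$severities, function(s) {
    f <- compute_ffr(sweep, s, reference_pressure_offset)
    data.frame(branch = f$branch, severity = s, p_pre_Pa = f$p_pre_Pa,
               p_post_Pa = f$p_post_Pa, ffr = f$ffr)
  })
  do.call(rbind, rows)
}
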