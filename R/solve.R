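# Steady and pulsatile solvers for the lumped-parameter tree.
#
# The tree is solved by Thevenin reduction: every subtree collapses, leaf
# to root, into an equivalent (resistance, source-pressure) pair; a forward
# pass then distributes pressures and flows. This is exact for trees and
# O(n) per solve, which matters in the pulsatile stepper where the tree is
# re-solved every time step.

# Precompute integer-indexed topology for the hot path.
.net_prep <- function(network) {
  nm <- network$order                      # topological order, root first
  n <- length(nm)
  idx <- setNames(seq_len(n), nm)
  children <- lapply(nm, function(s) unname(idx[network$children[[s]]]))
  leaf <- nm %in% network$leaves
  r <- vapply(nm, function(s) network$segments[[s]]$radius, numeric(1))
  L <- vapply(nm, function(s) network$segments[[s]]$length, numeric(1))
  out_R <- out_Pd <- out_C <- rep(NA_real_, n)
  for (s in network$leaves) {
    o <- network$outlets[[s]]
    out_R[idx[s]] <- o$distal_resistance
    out_Pd[idx[s]] <- o$distal_pressure
    out_C[idx[s]] <- o$compliance
  }
  list(nm = nm, n = n, idx = idx, children = children, leaf = leaf,
       r = r, L = L, out_R = out_R, out_Pd = out_Pd, out_C = out_C,
       sites = network$measurement_sites)
}

# One linear tree solve for fixed segment resistances and outlet Thevenin
# equivalents (Rth, Pth at each leaf). Returns proximal/distal node
# pressures and the flow through every segment.
.tree_solve <- function(prep, Rseg, Rth, Pth, Q_in) {
  n <- prep$n
  Rsub <- numeric(n); Psub <- numeric(n)
  for (k in n:1) {
    ch <- prep$children[[k]]
    if (length(ch) == 0L) {
      Rsub[k] <- Rseg[k] + Rth[k]
      Psub[k] <- Pth[k]
    } else {
      g <- sum(1 / Rsub[ch])
      Rsub[k] <- Rseg[k] + 1 / g
      Psub[k] <- sum(Psub[ch] / Rsub[ch]) / g
    }
  }
  Q <- numeric(n); Pprox <- numeric(n); Pdist <- numeric(n)
  Q[1] <- Q_in
  Pprox[1] <- Psub[1] + Q_in * Rsub[1]
  for (k in 1:n) {
    Pdist[k] <- Pprox[k] - Q[k] * Rseg[k]
    for (c in prep$children[[k]]) {
      Q[c] <- (Pdist[k] - Psub[c]) / Rsub[c]
      Pprox[c] <- Pdist[k]
    }
  }
  list(Pprox = Pprox, Pdist = Pdist, Q = Q)
}

# Segment resistances from flows under Carreau rheology (vectorised
# closed form: the Poiseuille wall shear rate does not depend on mu).
.carreau_Rseg <- function(prep, Q, params) {
  gamma <- 4 * abs(Q) / (pi * prep$r^3)
  mu <- params$mu_inf + (params$mu_zero - params$mu_inf) *
    (1 + (params$lambda_c * gamma)^2)^((params$n_index - 1) / 2)
  8 * mu * prep$L / (pi * prep$r^4)
}

#' Steady-state solution of the network
#'
#' Solves the resistor-network limit of the Windkessel system (compliances
#' carry no current in steady state) for a prescribed inlet flow. With
#' Carreau rheology the segment resistances depend on the flows; an outer
#' fixed-point iteration is run until the flows change by no more than
#' `tol` (relative).
#'
#' @param network A [vessel_network()].
#' @param inlet_flow Inlet volumetric flow (m^3 s^-1), finite.
#' @param params A [rheology_params()]; ignored when `viscosity` is given.
#' @param viscosity Optional fixed dynamic viscosity (kg m^-1 s^-1);
#'   bypasses the Carreau closure (used e.g. for linear-solver
#'   cross-checks).
#' @param tol Relative fixed-point tolerance on all flows.
#' @param max_iter Fixed-point iteration cap.
#' @return An object of class `steady_solution`: data frame `segments`
#'   with per-segment proximal/distal pressures (Pa), flow (m^3 s^-1),
#'   midpoint pressure, plane-averaged velocity and resistance; `inlet_pressure`
#'   (Pa); `outlet_flows` and `outlet_pressures` (named, at the outlet
#'   nodes); `iterations`.
#' @examples
#' net <- assemble_default_tree()
#' sol <- solve_steady(net, 4.17e-6)
#' sol$segments
#' @export
solve_steady <- function(network, inlet_flow, params = rheology_params(),
                         viscosity = NULL, tol = 1e-9, max_iter = 100L) {
  if (!is.finite(inlet_flow))
    stop("solve_steady: inlet_flow must be finite", call. = FALSE)
  prep <- .net_prep(network)
  Rth <- ifelse(prep$leaf, prep$out_R, 0)
  Pth <- ifelse(prep$leaf, prep$out_Pd, 0)

  if (!is.null(viscosity)) {
    Rseg <- 8 * viscosity * prep$L / (pi * prep$r^4)
    sol <- .tree_solve(prep, Rseg, Rth, Pth, inlet_flow)
    iters <- 0L
  } else {
    # start from the infinite-shear (thinnest) resistances
    Rseg <- 8 * params$mu_inf * prep$L / (pi * prep$r^4)
    sol <- .tree_solve(prep, Rseg, Rth, Pth, inlet_flow)
    iters <- 0L
    repeat {
      iters <- iters + 1L
      Rseg <- .carreau_Rseg(prep, sol$Q, params)
      new <- .tree_solve(prep, Rseg, Rth, Pth, inlet_flow)
      dq <- max(abs(new$Q - sol$Q)) / max(abs(new$Q), .Machine$double.xmin)
      sol <- new
      if (dq <= tol || iters >= max_iter) break
    }
    if (iters >= max_iter)
      warning("solve_steady: viscosity fixed point not converged after ",
              max_iter, " iterations")
  }

  seg_df <- data.frame(
    segment = prep$nm,
    p_proximal_Pa = sol$Pprox, p_distal_Pa = sol$Pdist,
    p_mid_Pa = (sol$Pprox + sol$Pdist) / 2,
    flow_m3_per_s = sol$Q,
    velocity_m_per_s = sol$Q / (pi * prep$r^2),
    resistance = Rseg,
    row.names = NULL)
  out_idx <- which(prep$leaf)
  structure(list(segments = seg_df,
                 inlet_pressure = sol$Pprox[1],
                 outlet_flows = setNames(sol$Q[out_idx], prep$nm[out_idx]),
                 outlet_pressures = setNames(sol$Pdist[out_idx],
                                             prep$nm[out_idx]),
                 iterations = iters),
            class = "steady_solution")
}

#' @export
print.steady_solution <- function(x, ...) {
  cat(sprintf("steady_solution: inlet pressure %.2f Pa (%d viscosity iterations)\n",
              x$inlet_pressure, x$iterations))
  print(x$segments, digits = 4)
  invisible(x)
}

# Backward-Euler integration of the Windkessel states coupled to the
# quasi-static tree, with the tree passes inlined for speed. `qv` holds
# the inlet flow at the step times (qv[1] belongs to the initial state).
# Returns the final states and, when `record`, the full histories.
.integrate_wk <- function(prep, Rout, Pd, Cc, dt, qv, Pc, Qprev,
                          params, viscosity, record) {
  n <- prep$n
  ch <- prep$children
  li <- which(prep$leaf)
  maskC <- as.numeric(Cc > 0)
  gcomp <- 1 / Rout + maskC * Cc / dt     # companion conductance, constant
  Rth <- numeric(n); Rth[li] <- 1 / gcomp
  PdR <- Pd / Rout
  gC <- maskC * Cc / dt

  fixed <- !is.null(viscosity)
  coefL <- 8 * prep$L / (pi * prep$r^4)   # Rseg = coefL * mu
  cgam <- 4 / (pi * prep$r^3)
  mu_inf <- params$mu_inf; dmu <- params$mu_zero - params$mu_inf
  lam <- params$lambda_c; ex <- (params$n_index - 1) / 2
  Rseg <- if (fixed) coefL * viscosity else
    coefL * (mu_inf + dmu * (1 + (lam * cgam * abs(Qprev))^2)^ex)

  N <- length(qv) - 1L
  if (record) {
    Pprox_h <- matrix(NA_real_, N + 1L, n)
    Pdist_h <- matrix(NA_real_, N + 1L, n)
    Q_h <- matrix(NA_real_, N + 1L, n)
  }
  Rsub <- numeric(n); Psub <- numeric(n)
  Qs <- numeric(n); Pprox <- numeric(n); Pdist <- numeric(n)
  Pth <- numeric(n)
  cons_max <- 0

  if (record) {
    # initial record: compliant outlet nodes pinned at their state pressure
    Rth0 <- numeric(n); Rth0[li] <- (1 - maskC) * Rout
    Pth0 <- numeric(n); Pth0[li] <- maskC * Pc + (1 - maskC) * Pd
    s0 <- .tree_solve(prep, Rseg, Rth0, Pth0, qv[1])
    Pprox_h[1, ] <- s0$Pprox; Pdist_h[1, ] <- s0$Pdist; Q_h[1, ] <- s0$Q
  }

  for (j in seq_len(N)) {
    Pth[li] <- (PdR + gC * Pc) / gcomp
    qin <- qv[j + 1L]
    npass <- if (fixed) 1L else 2L
    for (pass in seq_len(npass)) {
      if (!fixed)
        Rseg <- coefL * (mu_inf + dmu *
                           (1 + (lam * cgam * abs(Qprev))^2)^ex)
      for (k in n:1) {
        cc <- ch[[k]]
        if (length(cc)) {
          gg <- sum(1 / Rsub[cc])
          Rsub[k] <- Rseg[k] + 1 / gg
          Psub[k] <- sum(Psub[cc] / Rsub[cc]) / gg
        } else {
          Rsub[k] <- Rseg[k] + Rth[k]
          Psub[k] <- Pth[k]
        }
      }
      Qs[1] <- qin
      Pprox[1] <- Psub[1] + qin * Rsub[1]
      for (k in 1:n) {
        Pdist[k] <- Pprox[k] - Qs[k] * Rseg[k]
        for (c2 in ch[[k]]) {
          Qs[c2] <- (Pdist[k] - Psub[c2]) / Rsub[c2]
          Pprox[c2] <- Pdist[k]
        }
      }
      Qprev <- Qs
    }
    Pc_new <- Pdist[li]
    res <- qin - sum((Pc_new - Pd) / Rout + gC * (Pc_new - Pc))
    acc <- abs(res)
    if (acc > cons_max) cons_max <- acc
    Pc <- maskC * Pc_new + (1 - maskC) * Pc
    if (record) {
      Pprox_h[j + 1L, ] <- Pprox
      Pdist_h[j + 1L, ] <- Pdist
      Q_h[j + 1L, ] <- Qs
    }
  }
  out <- list(Pc = Pc, Qprev = Qprev, cons_max = cons_max)
  if (record) {
    out$Pprox <- Pprox_h; out$Pdist <- Pdist_h; out$Q <- Q_h
  }
  out
}

#' Pulsatile simulation with Windkessel outlet dynamics
#'
#' Integrates the outlet compliance states
#' \deqn{C\,dP_c/dt = Q_{outlet} - (P_c - P_d)/R}
#' coupled to the quasi-static resistive tree with prescribed periodic
#' inlet flow. Time integration is implicit (backward) Euler: each
#' compliance is replaced by its companion Thevenin branch
#' (resistance `dt/C`, source `P_c` at the previous step), so every step is
#' one linear tree solve and the scheme is unconditionally stable across
#' the four-decade spread of outlet resistances. Outlets with `C = 0` are
#' handled algebraically. Carreau segment resistances are refreshed within
#' each step from the current flows (lagged solve plus one refresh; the
#' Poiseuille shear rate closes the viscosity fixed point in one
#' evaluation).
#'
#' The Windkessel states are initialised from the steady solution at the
#' cycle-mean inflow and settled onto the periodic orbit by a short
#' coarse-step run (`warmup_cycles` cycles at `warmup_steps` steps per
#' cycle) before the `n_cycles` reported cycles are integrated; only the
#' final cycle is reported, together with a periodicity measure comparing
#' the last two cycles.
#'
#' @param network A [vessel_network()].
#' @param waveform An [inlet_waveform()] (velocity waveforms are converted
#'   through their inlet area).
#' @param dt Requested time step (s); must satisfy `dt <= period/64`. The
#'   effective step is `period / ceiling(period/dt)` so cycles contain a
#'   whole number of steps.
#' @param n_cycles Number of cardiac cycles to integrate (>= 2).
#' @param params A [rheology_params()]; ignored when `viscosity` is given.
#' @param viscosity Optional fixed viscosity (kg m^-1 s^-1).
#' @param warmup_cycles Settling cycles integrated at the coarse step
#'   before the reported run (0 disables the warm start).
#' @param warmup_steps Steps per cycle of the settling run.
#' @return An object of class `simulation_result` with the final-cycle
#'   `time` grid (s), matrices `site_pressure` (Pa, segment midpoints),
#'   `site_velocity` (m s^-1), `branch_flow` (m^3 s^-1, per segment),
#'   `outlet_pressure`/`outlet_flow` (at the Windkessel nodes),
#'   `inlet_flow`, `inlet_pressure`, a `summary` data frame of final-cycle
#'   mean/max/min per site, an `outlet_summary`, the maximum relative
#'   conservation residual `conservation`, and the cycle-to-cycle
#'   `periodicity` residual.
#' @examples
#' net <- assemble_default_tree()
#' wf <- generate_inlet_waveform()
#' sim <- simulate_pulsatile(net, wf, dt = 2e-3, n_cycles = 3)
#' sim$summary
#' @export
simulate_pulsatile <- function(network, waveform, dt = 1e-3, n_cycles = 5L,
                               params = rheology_params(), viscosity = NULL,
                               warmup_cycles = 6L, warmup_steps = 128L) {
  wf <- as_flow_waveform(waveform)
  Tc <- wf$period
  if (dt > Tc / 64)
    stop("simulate_pulsatile: dt must be <= period/64 (got dt = ", dt, ")",
         call. = FALSE)
  if (n_cycles < 2L)
    stop("simulate_pulsatile: n_cycles must be >= 2", call. = FALSE)
  prep <- .net_prep(network)
  n <- prep$n
  n_per <- as.integer(ceiling(Tc / dt))
  dt_eff <- Tc / n_per
  N <- n_per * n_cycles

  li <- which(prep$leaf)
  Rout <- prep$out_R[li]
  Pd <- prep$out_Pd[li]
  Cc <- prep$out_C[li]

  # initial compliance states: steady solution at the cycle-mean inflow
  q_mean <- waveform_cycle_mean(wf)
  init <- solve_steady(network, q_mean, params = params,
                       viscosity = viscosity)
  Pc <- unname(init$outlet_pressures[prep$nm[li]])
  Qprev <- init$segments$flow_m3_per_s[match(prep$nm, init$segments$segment)]

  if (warmup_cycles > 0L && any(Cc > 0)) {
    dt_w <- Tc / warmup_steps
    t_w <- (0:(warmup_steps * warmup_cycles)) * dt_w
    w <- .integrate_wk(prep, Rout, Pd, Cc, dt_w, waveform_flow_at(wf, t_w),
                       Pc, Qprev, params, viscosity, record = FALSE)
    Pc <- w$Pc; Qprev <- w$Qprev
  }

  t_all <- (0:N) * dt_eff
  q_in <- waveform_flow_at(wf, t_all)
  run <- .integrate_wk(prep, Rout, Pd, Cc, dt_eff, q_in, Pc, Qprev,
                       params, viscosity, record = TRUE)

  Pmid <- (run$Pprox + run$Pdist) / 2
  colnames(Pmid) <- colnames(run$Q) <- prep$nm

  last <- (N - n_per + 1L):(N + 1L)       # final cycle incl. both ends
  prev <- last - n_per                    # same phases, previous cycle
  site_idx <- match(prep$sites, prep$nm)
  periodicity <- max(abs(Pmid[last, site_idx] - Pmid[prev, site_idx])) /
    max(abs(Pmid[last, site_idx]))

  mean_idx <- (N - n_per + 1L):N          # left endpoints of final cycle
  vel <- sweep(run$Q, 2, pi * prep$r^2, "/")
  summ <- data.frame(
    site = prep$sites,
    p_mean_Pa = colMeans(Pmid[mean_idx, site_idx, drop = FALSE]),
    p_max_Pa = apply(Pmid[last, site_idx, drop = FALSE], 2, max),
    p_min_Pa = apply(Pmid[last, site_idx, drop = FALSE], 2, min),
    q_mean_m3_per_s = colMeans(run$Q[mean_idx, site_idx, drop = FALSE]),
    v_mean_m_per_s = colMeans(vel[mean_idx, site_idx, drop = FALSE]),
    v_max_m_per_s = apply(vel[last, site_idx, drop = FALSE], 2, max),
    v_min_m_per_s = apply(vel[last, site_idx, drop = FALSE], 2, min),
    row.names = NULL)
  out_summ <- data.frame(
    outlet = prep$nm[li],
    p_node_mean_Pa = colMeans(run$Pdist[mean_idx, li, drop = FALSE]),
    q_mean_m3_per_s = colMeans(run$Q[mean_idx, li, drop = FALSE]),
    row.names = NULL)

  op <- run$Pdist[last, li, drop = FALSE]
  colnames(op) <- prep$nm[li]
  of <- run$Q[last, li, drop = FALSE]
  colnames(of) <- prep$nm[li]

  structure(list(
    time = t_all[last],
    site_pressure = Pmid[last, site_idx, drop = FALSE],
    site_velocity = vel[last, site_idx, drop = FALSE],
    branch_flow = run$Q[last, , drop = FALSE],
    outlet_pressure = op,
    outlet_flow = of,
    inlet_flow = q_in[last],
    inlet_pressure = run$Pprox[last, 1],
    summary = summ,
    outlet_summary = out_summ,
    conservation = run$cons_max / max(abs(q_in)),
    periodicity = periodicity,
    dt = dt_eff, n_cycles = n_cycles, period = Tc,
    sites = prep$sites),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf(
    "simulation_result: %d cycles of %.4g s at dt = %.3g s (final cycle reported)\n",
    x$n_cycles, x$period, x$dt))
  cat(sprintf("  conservation residual %.2e, cycle periodicity %.2e\n",
              x$conservation, x$periodicity))
  print(x$summary, digits = 4)
  invisible(x)
}
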