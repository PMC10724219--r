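# Independent oracles used across the suite.
#
# oracle_steady() solves the same steady network by dense nodal analysis
# (conductance-matrix stamping + solve()), a different algorithm from the
# package's Thevenin tree reduction.

oracle_steady <- function(network, inlet_flow, viscosity) {
  seg_names <- network$order
  n <- length(seg_names)
  # node 1 = inlet; node k+1 = distal node of segment k
  node_of <- setNames(seq_len(n) + 1L, seg_names)
  prox_node <- function(s) {
    p <- network$parent[[s]]
    if (is.na(p)) 1L else node_of[[p]]
  }
  G <- matrix(0, n + 1L, n + 1L)
  b <- numeric(n + 1L)
  Rseg <- numeric(n)
  for (k in seq_len(n)) {
    s <- seg_names[k]
    seg <- network$segments[[s]]
    Rseg[k] <- 8 * viscosity * seg$length / (pi * seg$radius^4)
    i <- prox_node(s); j <- node_of[[s]]
    g <- 1 / Rseg[k]
    G[i, i] <- G[i, i] + g; G[j, j] <- G[j, j] + g
    G[i, j] <- G[i, j] - g; G[j, i] <- G[j, i] - g
  }
  for (s in network$leaves) {
    o <- network$outlets[[s]]
    j <- node_of[[s]]
    g <- 1 / o$distal_resistance
    G[j, j] <- G[j, j] + g
    b[j] <- b[j] + o$distal_pressure * g
  }
  b[1] <- b[1] + inlet_flow
  p <- solve(G, b)
  flows <- vapply(seg_names, function(s)
    (p[prox_node(s)] - p[node_of[[s]]]) / Rseg[match(s, seg_names)],
    numeric(1))
  list(inlet_pressure = p[1],
       node_pressure = setNames(p[node_of], seg_names),
       flows = flows)
}

# Random rooted tree of n_seg conduits with Windkessel leaves; radii,
# lengths, resistances and distal pressures drawn over physiological-ish
# decades.
random_tree <- function(n_seg = 6L, tau = 0) {
  nm <- paste0("S", seq_len(n_seg))
  segs <- lapply(seq_len(n_seg), function(k)
    conduit(nm[k], length = runif(1, 2e-3, 40e-3),
            radius = runif(1, 0.5e-3, 2.5e-3)))
  parent <- c(NA, vapply(2:n_seg, function(k)
    nm[sample.int(k - 1L, 1L)], character(1)))
  topo <- setNames(parent[-1], nm[-1])
  leaves <- setdiff(nm, parent[-1])
  outlets <- lapply(leaves, function(s) {
    R <- 10^runif(1, 7.5, 10)
    windkessel_outlet(s, R, compliance = if (tau > 0) tau / R else 0,
                      distal_pressure = runif(1, 0, 500))
  })
  names(outlets) <- leaves
  vessel_network(segs, topo, nm[1], outlets, measurement_sites = nm)
}

# conduit whose Poiseuille resistance equals R_target at the given
# viscosity (radius fixed, length solved)
conduit_with_resistance <- function(name, R_target, viscosity,
                                    radius = 1e-3) {
  conduit(name, length = R_target * pi * radius^4 / (8 * viscosity),
          radius = radius)
}
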