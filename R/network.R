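#' Two-element Windkessel outlet
#'
#' Lumped representation of the vasculature distal to a truncated outlet:
#' a distal resistance `R` to the reference pressure `P_d`, with a
#' compliance `C` in parallel at the outlet node. `C = 0` degrades to a
#' pure-resistance outlet (no pressure state).
#'
#' @param branch Outlet branch name (e.g. `"M1"`).
#' @param distal_resistance Distal resistance (kg m^-4 s^-1), > 0.
#' @param compliance Compliance (m^3 Pa^-1), >= 0.
#' @param distal_pressure Distal reference pressure (Pa, gauge); default 0.
#' @return An object of class `windkessel_outlet`.
#' @export
windkessel_outlet <- function(branch, distal_resistance, compliance = 0,
                              distal_pressure = 0) {
  stopifnot(is.character(branch), length(branch) == 1L)
  if (!is.numeric(distal_resistance) || distal_resistance <= 0)
    stop("windkessel_outlet '", branch, "': distal_resistance must be > 0",
         call. = FALSE)
  if (!is.numeric(compliance) || compliance < 0)
    stop("windkessel_outlet '", branch, "': compliance must be >= 0",
         call. = FALSE)
  structure(list(branch = branch, distal_resistance = distal_resistance,
                 compliance = compliance, distal_pressure = distal_pressure),
            class = "windkessel_outlet")
}

#' Vessel network
#'
#' Assembles conduit segments into a rooted tree with Windkessel-terminated
#' leaves. Node convention: node 0 is the inlet (proximal end of the root
#' segment); every segment owns its distal node; a leaf's distal node is
#' the outlet node where the Windkessel attaches.
#'
#' @param segments Named list of [conduit()] objects.
#' @param topology Named character vector mapping each non-root segment to
#'   its parent segment; the root is the one segment absent from the names.
#' @param inlet Name of the root segment.
#' @param outlets Named list of [windkessel_outlet()] objects, one per leaf
#'   segment (names are leaf segment names).
#' @param measurement_sites Character vector of segment names whose
#'   midpoints are reported as measurement sites.
#' @return An object of class `vessel_network` with precomputed topology
#'   (topological order, children lists) used by the solvers.
#' @export
vessel_network <- function(segments, topology, inlet, outlets,
                           measurement_sites) {
  seg_names <- vapply(segments, function(s) s$name, character(1))
  names(segments) <- seg_names
  n <- length(segments)
  if (n < 1L) stop("vessel_network: no segments", call. = FALSE)
  if (!inlet %in% seg_names)
    stop("vessel_network: inlet segment '", inlet, "' not found", call. = FALSE)
  bad <- setdiff(names(topology), seg_names)
  if (length(bad))
    stop("vessel_network: topology names unknown segment '", bad[1], "'",
         call. = FALSE)
  bad <- setdiff(topology, seg_names)
  if (length(bad))
    stop("vessel_network: topology parent '", bad[1],
         "' is not a segment", call. = FALSE)
  parent <- setNames(rep(NA_character_, n), seg_names)
  parent[names(topology)] <- topology
  roots <- seg_names[is.na(parent)]
  if (length(roots) != 1L)
    stop("vessel_network: exactly one root required, found [",
         paste(roots, collapse = ", "), "]", call. = FALSE)
  if (roots != inlet)
    stop("vessel_network: declared inlet '", inlet,
         "' is not the tree root '", roots, "'", call. = FALSE)

  # topological order by walking up to the root; a cycle never reaches it
  depth <- setNames(integer(n), seg_names)
  for (s in seg_names) {
    cur <- s; d <- 0L
    while (!is.na(parent[cur])) {
      cur <- parent[cur]; d <- d + 1L
      if (d > n)
        stop("vessel_network: cycle detected at segment '", s, "'",
             call. = FALSE)
    }
    if (cur != inlet)
      stop("vessel_network: segment '", s, "' is disconnected from the inlet",
           call. = FALSE)
    depth[s] <- d
  }
  ord <- seg_names[order(depth)]

  children <- lapply(setNames(seg_names, seg_names),
                     function(s) seg_names[!is.na(parent) & parent == s])
  leaves <- seg_names[vapply(children, length, integer(1)) == 0L]

  miss <- setdiff(leaves, names(outlets))
  if (length(miss))
    stop("vessel_network: leaf segment '", miss[1],
         "' has no Windkessel outlet", call. = FALSE)
  extra <- setdiff(names(outlets), leaves)
  if (length(extra))
    stop("vessel_network: outlet '", extra[1],
         "' does not terminate a leaf segment", call. = FALSE)
  bad <- setdiff(measurement_sites, seg_names)
  if (length(bad))
    stop("vessel_network: measurement site '", bad[1],
         "' names no segment", call. = FALSE)

  structure(list(segments = segments, parent = parent, children = children,
                 order = ord, inlet = inlet, leaves = leaves,
                 outlets = outlets, measurement_sites = measurement_sites),
            class = "vessel_network")
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("vessel_network:", length(x$segments), "segments,",
      length(x$outlets), "Windkessel outlets, inlet =", x$inlet, "\n")
  for (s in x$order) {
    seg <- x$segments[[s]]
    tail <- if (s %in% x$leaves)
      sprintf("-> Windkessel R = %.3g", x$outlets[[s]]$distal_resistance)
    else ""
    cat(sprintf("  %-4s r = %.4g mm, L = %.3g mm %s\n",
                s, seg$radius * 1e3, seg$length * 1e3, tail))
  }
  invisible(x)
}

#' Default intracranial tree
#'
#' Builds the truncated internal-carotid tree ICA -> {OA, ACA, MCA},
#' MCA -> {M1, M2}, with the four leaves (OA, ACA, M1, M2) terminated by
#' two-element Windkessel outlets. Geometry and outlet resistances come
#' from the supplied configuration (defaults:
#' [generate_default_geometry()]); per-outlet compliance is `tau / R` with
#' a shared time constant `tau`.
#'
#' @param geometry Geometry configuration as returned by
#'   [generate_default_geometry()]: a list with `segments` (each a list
#'   with `name`, `parent` (`NA` for the root), `radius_m`, `length_m`),
#'   `inlet`, `outlet_resistances` (named, kg m^-4 s^-1),
#'   `measurement_sites`.
#' @param tau Windkessel time constant (s) shared across outlets; each
#'   outlet gets compliance `tau / R`. `tau = 0` gives pure-resistance
#'   outlets.
#' @param distal_pressure Distal reference pressure (Pa, gauge) for all
#'   outlets.
#' @return A [vessel_network()].
#' @examples
#' net <- assemble_default_tree()
#' net
#' @export
assemble_default_tree <- function(geometry = generate_default_geometry(),
                                  tau = 1.0, distal_pressure = 0) {
  segs <- lapply(geometry$segments, function(g)
    conduit(g$name, g$length_m, g$radius_m))
  names(segs) <- vapply(segs, function(s) s$name, character(1))
  par <- vapply(geometry$segments, function(g)
    if (is.null(g$parent) || is.na(g$parent)) NA_character_ else g$parent,
    character(1))
  names(par) <- names(segs)
  topo <- par[!is.na(par)]

  # leaves of the declared topology must all carry a resistance
  leaves <- setdiff(names(segs), unname(topo))
  for (b in leaves) {
    if (is.null(geometry$outlet_resistances[[b]]))
      stop("assemble_default_tree: no outlet resistance for branch '", b,
           "'", call. = FALSE)
  }
  outlets <- lapply(leaves, function(b) {
    R <- geometry$outlet_resistances[[b]]
    windkessel_outlet(b, R, compliance = if (tau > 0) tau / R else 0,
                      distal_pressure = distal_pressure)
  })
  names(outlets) <- leaves
  vessel_network(segs, topo, geometry$inlet, outlets,
                 geometry$measurement_sites)
}

#' Replace one outlet's distal resistance
#'
#' Returns a copy of the network with the named outlet's distal resistance
#' set to `resistance`. If the network was built with a shared Windkessel
#' time constant, set `rescale_compliance = TRUE` to keep `tau = R C`
#' fixed; the default keeps the healthy compliance, so that stenosis
#' changes only the resistive load.
#'
#' @param network A [vessel_network()].
#' @param branch Outlet name.
#' @param resistance New distal resistance (kg m^-4 s^-1).
#' @param rescale_compliance Keep `R * C` constant if `TRUE`.
#' @return The modified network.
#' @export
set_outlet_resistance <- function(network, branch, resistance,
                                  rescale_compliance = FALSE) {
  if (!branch %in% names(network$outlets))
    stop("set_outlet_resistance: unknown outlet '", branch, "'",
         call. = FALSE)
  o <- network$outlets[[branch]]
  if (rescale_compliance && o$compliance > 0)
    o$compliance <- o$compliance * o$distal_resistance / resistance
  o$distal_resistance <- resistance
  network$outlets[[branch]] <- o
  network
}

#' Plane-averaged velocity from flow
#'
#' The zero-dimensional equivalent of an area-weighted average velocity at
#' a measurement plane: `v = Q / (pi r^2)`.
#'
#' @param flow Volumetric flow (m^3 s^-1). Vectorised.
#' @param radius Luminal radius (m), > 0.
#' @return Velocity (m s^-1).
#' @export
plane_average_velocity <- function(flow, radius) {
  if (any(radius <= 0))
    stop("plane_average_velocity: radius must be > 0", call. = FALSE)
  flow / (pi * radius^2)
}
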