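test_that("default tree has the expected structure", {
  net <- assemble_default_tree()
  expect_length(net$segments, 6L)
  expect_length(net$outlets, 4L)
  expect_length(net$measurement_sites, 5L)
  expect_setequal(names(net$outlets), c("OA", "ACA", "M1", "M2"))
  expect_identical(net$inlet, "ICA")
  # MCA plane area inverts the healthy flow/velocity pair
  expect_equal(pi * net$segments$MCA$radius^2, 3.206e-6 / 0.415,
               tolerance = 5e-4)
  expect_equal(pi * net$segments$ACA$radius^2, 0.964e-6 / 0.226,
               tolerance = 5e-4)
})

test_that("malformed topologies are rejected with the offending segment named", {
  geo <- generate_default_geometry()
  geo$outlet_resistances$M2 <- NULL
  expect_error(assemble_default_tree(geo), "M2")

  segs <- list(conduit("A", 0.01, 1e-3), conduit("B", 0.01, 1e-3),
               conduit("C", 0.01, 1e-3))
  out <- list(C = windkessel_outlet("C", 1e8))
  # cycle: B -> C -> B plus disconnection from the root
  expect_error(
    vessel_network(segs, c(B = "C", C = "B"), "A", out, "A"),
    "cycle|disconnected")
  # two roots
  expect_error(
    vessel_network(segs, c(C = "B"), "A", out, "A"),
    "exactly one root")
  # unknown measurement site
  expect_error(
    vessel_network(segs, c(B = "A", C = "B"), "A", out, "D"),
    "D")
})

test_that("plane-averaged velocity inverts the printed flow/velocity pairs", {
  expect_equal(plane_average_velocity(3.206e-6, 1.568e-3), 0.415,
               tolerance = 5e-4)
  expect_identical(plane_average_velocity(0, 1.568e-3), 0)
  v1 <- plane_average_velocity(2e-6, 1e-3)
  expect_equal(plane_average_velocity(2e-6, 2e-3), v1 / 4)
})

test_that("steady solve reproduces series and divider circuits", {
  mu <- 0.0035
  # series: segment 1e8 into outlet 2e8 at Q = 1e-6 -> 300 Pa
  seg <- conduit_with_resistance("A", 1e8, mu)
  net <- vessel_network(list(seg), topology = setNames(character(0), character(0)),
                        inlet = "A",
                        outlets = list(A = windkessel_outlet("A", 2e8)),
                        measurement_sites = "A")
  sol <- solve_steady(net, 1e-6, viscosity = mu)
  expect_equal(sol$inlet_pressure, 300, tolerance = 1e-9)

  # divider: near-zero trunk feeding total path resistances 1e8 and 3e8
  trunk <- conduit_with_resistance("T", 1, mu)
  bA <- conduit_with_resistance("A", 0.5e8, mu)
  bB <- conduit_with_resistance("B", 1.5e8, mu)
  net2 <- vessel_network(list(trunk, bA, bB), c(A = "T", B = "T"), "T",
                         list(A = windkessel_outlet("A", 0.5e8),
                              B = windkessel_outlet("B", 1.5e8)),
                         measurement_sites = c("A", "B"))
  sol2 <- solve_steady(net2, 1e-6, viscosity = mu)
  expect_equal(unname(sol2$outlet_flows["A"]), 7.5e-7, tolerance = 1e-9)
  expect_equal(unname(sol2$outlet_flows["B"]), 2.5e-7, tolerance = 1e-9)
})

test_that("steady solve matches the dense nodal-analysis oracle", {
  net <- assemble_default_tree()
  mu <- 0.0035
  sol <- solve_steady(net, 4.17e-6, viscosity = mu)
  ora <- oracle_steady(net, 4.17e-6, mu)
  expect_equal(sol$inlet_pressure, ora$inlet_pressure, tolerance = 1e-9)
  i <- match(net$order, sol$segments$segment)
  expect_equal(sol$segments$flow_m3_per_s[i], unname(ora$flows),
               tolerance = 1e-9)
  expect_equal(sol$segments$p_distal_Pa[i], unname(ora$node_pressure),
               tolerance = 1e-9)
})

test_that("steady solve matches the oracle on random trees", {
  set.seed(101)
  for (rep in 1:25) {
    n_seg <- sample(2:8, 1)
    net <- random_tree(n_seg)
    mu <- runif(1, 0.003, 0.02)
    Q <- runif(1, 5e-7, 8e-6)
    sol <- solve_steady(net, Q, viscosity = mu)
    ora <- oracle_steady(net, Q, mu)
    expect_equal(sol$inlet_pressure, ora$inlet_pressure, tolerance = 1e-9)
    i <- match(net$order, sol$segments$segment)
    expect_equal(sol$segments$flow_m3_per_s[i], unname(ora$flows),
                 tolerance = 1e-9)
  }
})

test_that("steady flows are conserved at every junction", {
  set.seed(33)
  for (rep in 1:10) {
    net <- random_tree(sample(3:8, 1))
    sol <- solve_steady(net, 4e-6)
    flows <- setNames(sol$segments$flow_m3_per_s, sol$segments$segment)
    for (s in names(net$children)) {
      ch <- net$children[[s]]
      if (length(ch))
        expect_equal(sum(flows[ch]), unname(flows[s]), tolerance = 1e-10)
    }
  }
})

test_that("raising one outlet resistance redistributes flow to the others", {
  net <- assemble_default_tree()
  base <- solve_steady(net, 4.17e-6)
  set.seed(7)
  for (rep in 1:8) {
    b <- sample(c("ACA", "M1", "M2"), 1)
    fac <- runif(1, 1.2, 30)
    pert <- set_outlet_resistance(net, b,
                                  net$outlets[[b]]$distal_resistance * fac)
    sol <- solve_steady(pert, 4.17e-6)
    expect_lt(sol$outlet_flows[b], base$outlet_flows[b])
    others <- setdiff(names(base$outlet_flows), b)
    expect_true(all(sol$outlet_flows[others] / sum(sol$outlet_flows) >
                      base$outlet_flows[others] / sum(base$outlet_flows)))
  }
})

test_that("pulsatile run reduces to the steady solution for constant inflow", {
  net <- assemble_default_tree()
  wf <- generate_inlet_waveform(waveform_params(peak_to_mean = 1))
  sim <- simulate_pulsatile(net, wf, dt = 2e-3, n_cycles = 3)
  ss <- solve_steady(net, waveform_cycle_mean(wf))
  i <- match(sim$summary$site, ss$segments$segment)
  expect_equal(sim$summary$p_mean_Pa, ss$segments$p_mid_Pa[i],
               tolerance = 1e-3)
  expect_lt(max(sim$summary$p_max_Pa - sim$summary$p_min_Pa), 1e-6)
})

test_that("zero-compliance outlets make the pulsatile run quasi-static", {
  net <- assemble_default_tree(tau = 0)
  wf <- generate_inlet_waveform()
  sim <- simulate_pulsatile(net, wf, dt = 2e-3, n_cycles = 2)
  # spot-check several phases against pointwise steady solves
  for (k in c(1L, 100L, 250L, 400L)) {
    ss <- solve_steady(net, sim$inlet_flow[k])
    i <- match(sim$sites, ss$segments$segment)
    # the stepper's two-pass viscosity refresh vs the steady solver's
    # 1e-9 fixed point leaves sub-ppm differences
    expect_equal(unname(sim$site_pressure[k, ]), ss$segments$p_mid_Pa[i],
                 tolerance = 1e-6)
  }
})

test_that("pulsatile solver conserves flow and settles onto a periodic orbit", {
  net <- assemble_default_tree()
  wf <- generate_inlet_waveform()
  sim <- simulate_pulsatile(net, wf, dt = 1e-3, n_cycles = 5)
  expect_lt(sim$conservation, 1e-8)
  expect_lt(sim$periodicity, 1e-3)
})

test_that("pulsatile solver converges under time-step refinement", {
  net <- assemble_default_tree()
  wf <- generate_inlet_waveform()
  base <- simulate_pulsatile(net, wf, dt = 1e-3, n_cycles = 5)
  half <- simulate_pulsatile(net, wf, dt = 5e-4, n_cycles = 5)
  sub <- half$site_pressure[seq(1, nrow(half$site_pressure), by = 2), ]
  err1 <- max(abs(base$site_pressure - sub)) / max(abs(base$site_pressure))
  expect_lt(err1, 1e-3)
  quarter <- simulate_pulsatile(net, wf, dt = 2.5e-4, n_cycles = 5)
  sub2 <- quarter$site_pressure[seq(1, nrow(quarter$site_pressure), by = 2), ]
  err2 <- max(abs(half$site_pressure - sub2)) / max(abs(half$site_pressure))
  # first order or better: halving dt at least roughly halves the change
  expect_lt(err2, 0.75 * err1)
})

test_that("pulsatile preconditions are enforced", {
  net <- assemble_default_tree()
  wf <- generate_inlet_waveform()
  expect_error(simulate_pulsatile(net, wf, dt = 0.1), "dt")
  expect_error(simulate_pulsatile(net, wf, n_cycles = 1), "n_cycles")
})
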