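# helper: hand-built sweep container for arithmetic-level checks
fake_sweep <- function(severities, p_up, p_down, branch = "M1",
                       R0 = 1e8, p_node = NULL, q_out = NULL) {
  series <- lapply(seq_along(severities), function(i) {
    m <- cbind(ICA = p_up[i], MCA = p_down[i])
    m
  })
  structure(list(branch = branch, severities = severities,
                 healthy_resistance = R0,
                 summary = NULL,
                 outlet = data.frame(
                   severity = severities,
                   p_node_mean_Pa = if (is.null(p_node)) p_up else p_node,
                   q_mean_m3_per_s = if (is.null(q_out))
                     rep(1e-6, length(severities)) else q_out),
                 site_pressure_series = series,
                 method = "steady"),
            class = "sweep_result")
}

test_that("relative sensitivity reproduces the printed percentages", {
  # ICA site, reference M1
  expect_equal(relative_sensitivity(514.88, 220.98), 57.1, tolerance = 0.05 / 57.1)
  expect_equal(relative_sensitivity(514.88, 112.03), 78.2, tolerance = 0.05 / 78.2)
  # MCA site
  expect_equal(relative_sensitivity(542.50, 191.96), 64.61, tolerance = 0.05 / 64.61)
  expect_equal(relative_sensitivity(542.50, 115.30), 78.74, tolerance = 0.05 / 78.74)
  # ACA site
  expect_equal(relative_sensitivity(545.91, 236.36), 56.71, tolerance = 0.05 / 56.71)
  expect_equal(relative_sensitivity(545.91, 120.18), 77.98, tolerance = 0.05 / 77.98)
  # degenerate cases
  expect_equal(relative_sensitivity(100, 100), 0)
  expect_error(relative_sensitivity(0, 10), "zero")
})

test_that("sweeps start at the healthy baseline and redistribute flow", {
  net <- assemble_default_tree()
  wf <- generate_inlet_waveform()
  sw0 <- stenosis_sweep(net, wf, "M1", severities = 0, method = "steady")
  base <- solve_steady(net, waveform_cycle_mean(wf))
  i <- match(sw0$summary$site, base$segments$segment)
  expect_equal(sw0$summary$p_mean_Pa, base$segments$p_mid_Pa[i],
               tolerance = 1e-12)

  sv <- seq(0, 0.6, by = 0.1)
  swM1 <- stenosis_sweep(net, wf, "M1", severities = sv, method = "steady")
  d <- swM1$summary
  expect_true(all(diff(d$q_mean_m3_per_s[d$site == "MCA"]) < 0))
  expect_true(all(diff(d$q_mean_m3_per_s[d$site == "ACA"]) > 0))
  swACA <- stenosis_sweep(net, wf, "ACA", severities = sv, method = "steady")
  d <- swACA$summary
  expect_true(all(diff(d$q_mean_m3_per_s[d$site == "ACA"]) < 0))
  expect_true(all(diff(d$q_mean_m3_per_s[d$site == "MCA"]) > 0))

  expect_error(stenosis_sweep(net, wf, "XX"), "XX")
  expect_error(stenosis_sweep(net, wf, "M1", severities = c(0.1, 0.2)),
               "first severity")
  expect_error(stenosis_sweep(net, wf, "M1", severities = c(0, 0.2, 0.1)),
               "ascending")
})

test_that("sensitivity report compares sweeps at the top severity", {
  net <- assemble_default_tree()
  wf <- generate_inlet_waveform()
  sv <- seq(0, 0.6, by = 0.2)
  sweeps <- lapply(setNames(nm = c("M1", "M2", "ACA")), function(b)
    stenosis_sweep(net, wf, b, severities = sv, method = "steady"))
  rep <- sensitivity_report(sweeps, site = "ICA", reference_branch = "M1")
  expect_equal(rep$relative_sensitivity_pct[rep$branch == "M1"], 0)
  expect_true(all(rep$delta_p_max_Pa >= 0))
  # magnitudes consistent with a direct recomputation
  d <- sweeps$ACA$summary
  dP <- abs(d$p_mean_Pa[d$site == "ICA" & d$severity == 0.6] -
              d$p_mean_Pa[d$site == "ICA" & d$severity == 0])
  expect_equal(rep$delta_p_max_Pa[rep$branch == "ACA"], dP)
})

test_that("reverse-flow onset is located by linear interpolation", {
  sv <- seq(0, 0.6, by = 0.1)
  sw <- fake_sweep(sv, p_up = 100 - 400 * sv, p_down = rep(0, length(sv)))
  th <- reverse_flow_threshold(sw, "ICA", "MCA")
  expect_equal(th$onset_severity, 0.25)
  expect_equal(th$most_negative_gradient_Pa, 100 - 400 * 0.6)
  # all-positive gradient -> none within sweep
  sw2 <- fake_sweep(sv, p_up = 100 + 0 * sv, p_down = rep(10, length(sv)))
  expect_true(is.na(reverse_flow_threshold(sw2, "ICA", "MCA")$onset_severity))
  # invariance to a common pressure offset
  sw3 <- fake_sweep(sv, p_up = 100 - 400 * sv + 777, p_down = rep(777, length(sv)))
  expect_equal(reverse_flow_threshold(sw3, "ICA", "MCA")$onset_severity, 0.25)
  expect_error(reverse_flow_threshold(sw, "ICA", "OA"), "OA")
})

test_that("model reverse-flow conclusions are grid independent", {
  net <- assemble_default_tree()
  wf <- generate_inlet_waveform()
  coarse <- stenosis_sweep(net, wf, "M1", severities = seq(0, 0.6, 0.05),
                           dt = 2e-3, n_cycles = 3)
  fine <- stenosis_sweep(net, wf, "M1", severities = seq(0, 0.6, 0.025),
                         dt = 2e-3, n_cycles = 3)
  a <- reverse_flow_threshold(coarse, "ICA", "MCA")$onset_severity
  b <- reverse_flow_threshold(fine, "ICA", "MCA")$onset_severity
  if (is.na(a) || is.na(b)) {
    expect_identical(is.na(a), is.na(b))
  } else {
    expect_lt(abs(a - b), 0.01)
  }
})

test_that("FFR follows the incremental-resistance definition", {
  # severity 0 -> exactly 1
  sv <- c(0, 0.5)
  sw <- fake_sweep(sv, p_up = c(10000, 10000), p_down = c(0, 0),
                   R0 = 1e8, q_out = c(1e-6, 2000 / (15 * 1e8)))
  expect_identical(compute_ffr(sw, 0)$ffr, 1)
  # P_pre = 10000 Pa, added stenotic drop = 2000 Pa -> FFR 0.8
  f <- compute_ffr(sw, 0.5)
  expect_equal(f$ffr, 0.8)
  expect_equal(f$p_post_Pa, 8000)
  expect_error(compute_ffr(sw, 0.3), "not in the sweep grid")
  swneg <- fake_sweep(sv, p_up = c(-5, -5), p_down = c(0, 0))
  expect_error(compute_ffr(swneg, 0.5), "pre-stenotic")
})

test_that("model FFR decreases strictly with severity on every branch", {
  net <- assemble_default_tree()
  wf <- generate_inlet_waveform()
  for (b in c("M1", "M2", "ACA")) {
    sw <- stenosis_sweep(net, wf, b, severities = seq(0, 0.6, 0.1),
                         method = "steady")
    f <- ffr_curve(sw)
    expect_identical(f$ffr[1], 1)
    expect_true(all(diff(f$ffr) < 0))
    expect_true(all(f$ffr > 0 & f$ffr <= 1))
  }
})
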