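test_that("series_pair: limits, hand values, commutativity, bound", {
  expect_equal(series_pair(3e-12, 3e-12), 1.5e-12)
  expect_equal(series_pair(2e-12, 3e-12), 1.2e-12)
  expect_equal(series_pair(5e-12, Inf), 5e-12)
  expect_equal(series_pair(0, 7e-12), 0)
  expect_error(series_pair(-1e-12, 1e-12), "non-negative")
  set.seed(7)
  c1 <- runif(50, 0, 1e-9)
  c2 <- runif(50, 0, 1e-9)
  expect_equal(series_pair(c1, c2), series_pair(c2, c1))
  expect_true(all(series_pair(c1, c2) <= pmin(c1, c2)))
  # associativity of repeated series composition
  c3 <- runif(50, 0, 1e-9)
  expect_equal(series_pair(series_pair(c1, c2), c3),
               series_pair(c1, series_pair(c2, c3)), tolerance = 1e-12)
})

test_that("total ISFET capacitance composes the two branches", {
  # equal capacitors: C/2 + C/2 = C
  net <- capacitor_network(4e-12, 4e-12, 4e-12, 4e-12)
  expect_equal(total_isfet_capacitance(net), 4e-12)
  # exact fractions for (1, 2, 3, 4) pF
  net2 <- capacitor_network(1e-12, 2e-12, 3e-12, 4e-12)
  expect_equal(total_isfet_capacitance(net2), (2 / 3 + 12 / 7) * 1e-12)
  # dominant oxide and electrolyte leave C_semi + C_Q
  net3 <- capacitor_network(1e-12, 1e-3, 1e-3, 4e-12)
  expect_equal(total_isfet_capacitance(net3), 5e-12, tolerance = 1e-8)
  # monotone non-decreasing in each capacitor
  base <- c(c_semi = 1e-12, c_ox = 2e-12, c_elec = 3e-12, c_q = 4e-12)
  t0 <- total_isfet_capacitance(do.call(capacitor_network, as.list(base)))
  for (f in names(base)) {
    up <- base
    up[f] <- up[f] * 2
    expect_gte(total_isfet_capacitance(do.call(capacitor_network,
                                               as.list(up))), t0)
  }
})

test_that("oxide capacitance: frozen value and exact EOT scaling", {
  g1 <- device_geometry(0.2, 10, 200, eot_nm = 1)
  expect_equal(oxide_capacitance(g1), 1.381224e-11, tolerance = 1e-12)
  g2 <- device_geometry(0.2, 10, 200, eot_nm = 2)
  expect_equal(oxide_capacitance(g1) / oxide_capacitance(g2), 2,
               tolerance = 1e-12)
  # C_OX * EOT invariant across a sweep
  eots <- seq(1, 8, by = 0.5)
  prod <- vapply(eots, function(e) {
    oxide_capacitance(device_geometry(0.2, 10, 200, eot_nm = e)) * e
  }, numeric(1))
  expect_equal(prod / prod[1], rep(1, length(eots)), tolerance = 1e-12)
  expect_error(device_geometry(0.2, 10, 200, eot_nm = 0), "positive")
})

test_that("surface potential is the charge-to-capacitance quotient", {
  expect_equal(surface_potential(0, 5e-12), 0)
  expect_equal(surface_potential(1e-15, 5e-12), 2e-4)
  expect_equal(surface_potential(2e-15, 5e-12),
               2 * surface_potential(1e-15, 5e-12))
  expect_error(surface_potential(1e-15, 0), "positive")
})

test_that("threshold voltage accumulates its terms with slope -1 in psi", {
  expect_equal(threshold_voltage(threshold_params(), 0, 1e-2), 0)
  p <- threshold_params(e_ref = 0.2, chi_sol = 0.003, phi_si = 0.9,
                        q_ox = 1e-4, q_ss = 2e-4, q_b = 3e-4, phi_f = 0.35)
  cox <- 3.4531e-2
  # independent term-by-term accumulation
  expected <- 0.2 - 0.05 + 0.003 - 0.9 - (1e-4 + 2e-4 + 3e-4) / cox +
    2 * 0.35
  expect_equal(threshold_voltage(p, 0.05, cox), expected, tolerance = 1e-12)
  # finite-difference slope in psi
  d <- (threshold_voltage(p, 0.05 + 1e-6, cox) -
          threshold_voltage(p, 0.05 - 1e-6, cox)) / 2e-6
  expect_equal(d, -1, tolerance = 1e-9)
})

test_that("drain current: square law, saturation clamp, continuity", {
  g <- device_geometry(1, 10, 200, eot_nm = 0.6)
  mu <- 150
  vth <- 0.3
  expect_equal(drain_current(bias_point(1, 0), vth, mu, g), 0)
  expect_equal(drain_current(bias_point(0.2, 0.1), vth, mu, g), 0)
  # triode point against a term-by-term oracle
  cox_pa <- 3.9 * pc$eps0 / 0.6e-9
  pref <- mu * 1e-4 * cox_pa * (10 * 200 / 1)
  vgs <- 1; vds <- 0.25
  expect_equal(drain_current(bias_point(vgs, vds), vth, mu, g),
               pref * ((vgs - vth) * vds - vds^2 / 2), tolerance = 1e-12)
  # vertex value at V_DS = V_ov, and clamp beyond it
  vov <- vgs - vth
  isat <- pref * vov^2 / 2
  expect_equal(drain_current(bias_point(vgs, vov), vth, mu, g), isat,
               tolerance = 1e-12)
  expect_equal(drain_current(bias_point(vgs, vov + 0.5), vth, mu, g), isat,
               tolerance = 1e-12)
  # continuity at the saturation boundary
  eps <- 1e-9
  expect_equal(drain_current(bias_point(vgs, vov - eps), vth, mu, g), isat,
               tolerance = 1e-6)
})

test_that("staged sensitivity matches the end-to-end current response", {
  g <- device_geometry_for(sil)
  n0 <- 3e16
  net <- capacitor_network(1e-6, oxide_capacitance(g), 1e-6,
                           cq_degenerate(n0, sil, g))
  p <- threshold_params(e_ref = 0.2, phi_f = 0.05)
  b <- bias_point(1, 0.1)
  dn <- 1e-6 * n0
  chain <- sensitivity_chain(dn, sil, g, net, p, b)
  direct <- current_response(dn, sil, g, net, p, b)
  expect_equal(chain$relative_change, direct, tolerance = 1e-3)
  # zero perturbation and sign
  expect_equal(sensitivity_chain(0, sil, g, net, p, b)$relative_change, 0)
  expect_gt(chain$gm, 0)
  expect_gt(chain$relative_change, 0)
  # zero baseline current is a domain error
  expect_error(sensitivity_chain(dn, sil, g, net, p, bias_point(0, 0.1)),
               "zero")
})
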