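test_that("LCC current aggregation converts and scales exactly", {
  p <- cicr_params()
  expect_equal(aggregate_ical(numeric(0), 50, p), 0)
  # halving the simulated volume at fixed per-volume flux density leaves
  # the whole-cell current unchanged (alpha ~ 1/Omega cancels)
  i_half <- aggregate_ical(rep(1, 5), 25, p)
  i_full <- aggregate_ical(rep(1, 10), 50, p)
  expect_equal(i_half, i_full, tolerance = 1e-12)
  # hand-computed ion-count conversion for a single channel:
  # 1 uM um^3/ms = 1e-21 mol/ms; x 2F C/mol -> A; / C_m F; x v_cell/Omega
  I0 <- 0.5
  by_hand <- -(2 * 96500 * I0 * 1e-21 * 1e3) / (3.1e-4 * 1e-6) *
    (2.58e4 / 50)
  expect_equal(aggregate_ical(I0, 50, p), by_hand, tolerance = 1e-9)
  expect_lt(aggregate_ical(1, 50, p), 0)   # influx is an inward current
})

test_that("NCX aggregation reduces to its symbolic limits", {
  p <- cicr_params()
  expect_equal(aggregate_inaca(0, numeric(0), p), 0)
  # uniform bulk flux: I = (v_cyt F / C_m) j0, independent of Omega
  j0 <- 0.02
  ph <- p$physical
  expected <- ph$v_cyt_frac * ph$v_cell * (ph$F * 1000) * 1e-18 /
    (ph$C_m * 1e-6) * j0
  expect_equal(aggregate_inaca(rep(j0, 100), numeric(0), p), expected,
               tolerance = 1e-12)
  # additivity of the bulk and surface terms
  a <- aggregate_inaca(rep(j0, 10), numeric(0), p)
  b <- aggregate_inaca(rep(0, 10), rep(0.005, 4), p)
  expect_equal(aggregate_inaca(rep(j0, 10), rep(0.005, 4), p), a + b,
               tolerance = 1e-12)
})

test_that("membrane with zero conductances integrates the stimulus exactly", {
  p <- cicr_params(conductances = list(g_na = 0, g_tof = 0, g_tos = 0,
                                       g_k1 = 0, g_kr = 0, g_ks = 0,
                                       g_nak = 0))
  y <- membrane_state(-80, p)
  # no currents, no stimulus: V constant
  y2 <- membrane_step(y, 50, params = p)
  expect_equal(y2[["V"]], -80, tolerance = 1e-10)
  # rectangular current injection: dV = -A * duration exactly
  y3 <- membrane_step(y, 1, i_stim = -40, params = p)
  expect_equal(y3[["V"]], -80 + 40, tolerance = 1e-9)
})

test_that("assembled currents rest at the located equilibrium", {
  p <- cicr_params()
  vr <- find_resting_potential(p)
  expect_lt(vr, -80); expect_gt(vr, -95)
  y <- membrane_state(vr, p)
  cur <- ionic_currents(y, params = p)
  expect_lt(abs(cur$dVdt), 1e-6)
  # without stimulation the potential stays within 1 mV for 500 ms
  for (k in 1:50) y <- membrane_step(y, 10, params = p)
  expect_lt(abs(y[["V"]] - vr), 1)
})

test_that("a stimulated membrane fires and repolarizes without Ca currents", {
  p <- cicr_params()
  y <- membrane_state(params = p)
  v0 <- y[["V"]]
  vs <- numeric(300)
  for (k in 1:300) {
    y <- membrane_step(y, 1, i_stim = if (k == 1) -40 else 0, params = p)
    vs[k] <- y[["V"]]
  }
  expect_gt(max(vs), 10)           # overshoot
  expect_lt(abs(vs[300] - v0), 2)  # return to rest
})

test_that("prescribed AP replay is exact and clamps drive LCC statistics", {
  w <- prescribed_ap_mode(c(0, 1, 2, 10), c(-80, 20, 0, -80))
  expect_equal(w(0), -80)
  expect_equal(w(1.5), 10)   # linear interpolation
  expect_equal(w(50), -80)   # held ends
  expect_error(prescribed_ap_mode(c(0, 0), c(1, 2)))
  # LCC opening is rare at -80 mV and transient at 0 mV: master-equation
  # oracle on the generator
  p0 <- steady_state_occupancy(mahajan_lcc7_rates(-80, 0.3))
  expect_lt(p0[["O"]], 1e-4)
  # step clamp to 0 mV: open probability rises then falls (activation
  # followed by Ca- and V-dependent inactivation)
  Q <- mahajan_lcc7_rates(0, 30)
  me <- master_equation(Q, p0, t_end = 300, dt = 0.05)
  po <- me$p[, "O"]
  expect_gt(max(po[me$time < 20]), 10 * po[1])
  expect_lt(po[length(po)], 0.5 * max(po))
})
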