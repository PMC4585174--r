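test_that("disk Green function has the closed-form values and Dirichlet rim", {
  # center source, field point at half radius: log(2)/(2 pi)
  expect_equal(green_disk(c(100, 0), c(0, 0), 200), log(2) / (2 * pi),
               tolerance = 1e-12)
  # boundary condition for center source
  expect_equal(green_disk(c(0, 200), c(0, 0), 200), 0, tolerance = 1e-12)
  # off-center sources vanish on the rim and are singular at the source
  set.seed(42)
  for (k in 1:50) {
    th_s <- runif(1, 0, 2 * pi); rr <- runif(1, 1, 130)
    src <- rr * c(cos(th_s), sin(th_s))
    th_b <- runif(1, 0, 2 * pi)
    expect_lt(abs(green_disk(200 * c(cos(th_b), sin(th_b)), src, 200)),
              1e-12)
  }
  expect_error(green_disk(c(10, 10), c(10, 10), 200), "singular")
})

test_that("Green function is symmetric and positive inside the disk", {
  set.seed(7)
  for (k in 1:20) {
    a <- runif(2, -80, 80); b <- runif(2, -80, 80)
    if (sum((a - b)^2) < 1) next
    expect_equal(green_disk(a, b, 150), green_disk(b, a, 150),
                 tolerance = 1e-10)
    expect_gt(green_disk(a, b, 150), 0)
  }
})

test_that("axial profile matches its closed form and is monotone", {
  expect_equal(axial_profile(0, -2.2), exp(4.4), tolerance = 1e-12)
  z <- seq(0, 15, by = 0.1)
  Z <- axial_profile(z)
  expect_true(all(diff(Z) < 0))
  expect_true(all(Z > 0))
  expect_equal(axial_profile(1e4), 1, tolerance = 1e-12)
  # effective height from quadrature exceeds the geometric height
  hs <- axial_height(15, -2.2, 1)
  expect_gt(hs, 15)
  # cross-check against an independent midpoint rule
  zz <- seq(0, 15, length.out = 200001)
  mid <- (zz[-1] + zz[-length(zz)]) / 2
  expect_equal(hs, sum(axial_profile(mid)) * (15 / length(mid)),
               tolerance = 1e-6)
})

test_that("cleft geometry enforces its invariants", {
  g <- cleft_geometry(c(0, 30), c(0, 0), c("RyR", "LCC"))
  expect_equal(g$radius, 90)
  expect_equal(g$z, c(15, 0))  # RyR on jSR face, LCC on T-tubule face
  expect_error(cleft_geometry(c(0, 0), c(0, 0), c("RyR", "RyR")),
               "distinct")
  expect_error(cleft_geometry(c(0, 150), c(0, 0), c("RyR", "RyR"),
                              radius = 200), "60")
  # JSON round trip
  p <- tempfile(fileext = ".json")
  cleft_to_json(g, p)
  g2 <- cleft_from_json(p)
  expect_equal(g2$x, g$x)
  expect_equal(g2$radius, g$radius)
  unlink(p)
})

test_that("coupling matrix scales as 1/beta with symmetric planar part", {
  g <- place_channels(8, 2)
  c1 <- assemble_coupling(g, beta = 1)
  c2 <- assemble_coupling(g, beta = 2)
  expect_equal(c2$eta, c1$eta / 2, tolerance = 1e-12)
  expect_true(all(diag(c1$eta) > 0))
  expect_true(all(is.finite(c1$eta)))
  # G-part symmetric: divide out the face factors
  Gpart <- c1$eta / c1$Z
  expect_equal(Gpart, t(Gpart), tolerance = 1e-10)
})

test_that("channel current laws reproduce the stated values", {
  ph <- cicr_params()$physical
  # LCC reversal: zero current when the mouth sits at the GHK reversal
  dV <- 2 * ph$F / (ph$R * ph$T) * 20
  c_rev <- 1800 * exp(-dV)
  expect_equal(channel_current("LCC", c_rev, V = 20), 0,
               tolerance = 1e-10)
  # V -> 0 limit with Table values
  expect_equal(channel_current("LCC", 1, V = 0, J_L = 0.0546),
               0.0546 * 1799, tolerance = 1e-9)
  expect_equal(channel_current("LCC", 1, V = 1e-12, J_L = 0.0546),
               0.0546 * 1799, tolerance = 1e-6)
  # RyR linear law (g given in the printed unit reading of the example)
  expect_equal(channel_current("RyR", 10, c_jsr = 1000, g = 2.33),
               2306.7, tolerance = 1e-10)
})

test_that("solve_cleft handles closed clefts and the scalar closed form", {
  g <- place_channels(1, 0)
  cp <- assemble_coupling(g)
  # all channels closed: mouths at Z * c_bulk, zero currents
  st0 <- solve_cleft(cp, FALSE, c_bulk = 0.275, c_jsr = 1000, V = 0)
  expect_equal(st0$c_mouth, cp$Z * 0.275, tolerance = 1e-12)
  expect_equal(st0$current, 0)
  # vanishing conductance: current -> 0
  st_g0 <- solve_cleft(cp, TRUE, 0.275, 1000, 0, g = 1e-12)
  expect_lt(abs(st_g0$current), 1e-8)
  # single open RyR at the center: scalar closed form
  st1 <- solve_cleft(cp, TRUE, 0.275, 1000, 0, g = 2.33e-3)
  eii <- cp$eta[1, 1]
  I_ref <- 2.33e-3 * (1000 - cp$Z[1] * 0.275) / (1 + 2.33e-3 * eii)
  expect_equal(st1$current[1], I_ref, tolerance = 1e-10)
  expect_lt(st1$residual, 1e-9)
})

test_that("cleft response is linear in currents and monotone in openings", {
  g <- place_channels(12, 3)
  cp <- assemble_coupling(g, beta = 2)
  n <- length(g$x)
  open <- rep(FALSE, n); open[c(1, 3, 5)] <- TRUE
  st <- solve_cleft(cp, open, 0.3, 900, 0)
  # superposition: excess concentration doubles when currents double
  excess <- st$c_mouth - cp$Z * st$c_bulk
  excess2 <- drop(cp$eta %*% (2 * st$current))
  expect_equal(excess2, 2 * excess, tolerance = 1e-12)
  # monotonicity: opening one more RyR raises every mouth concentration
  open2 <- open; open2[7] <- TRUE
  st2 <- solve_cleft(cp, open2, 0.3, 900, 0)
  expect_true(all(st2$c_mouth >= st$c_mouth - 1e-9))
})

test_that("beta calibration is monotone and hits its concentration cap", {
  b60 <- calibrate_beta(target = 60, n_draws = 5)
  b100 <- calibrate_beta(target = 100, n_draws = 5)
  expect_gt(b60, b100)   # stronger buffering for a lower cap
  expect_gt(b60, 1)
  # scaling check: eta ~ 1/beta, so halving the cap ~ doubles beta up to
  # the (small) self-limitation of the currents
  b30 <- calibrate_beta(target = 30, n_draws = 5)
  expect_gt(b30 / b60, 1.6)
  expect_lt(b30 / b60, 2.4)
})
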