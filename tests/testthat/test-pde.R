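test_that("buffer reactions vanish at binding equilibrium", {
  bp <- cicr_params()$buffers
  for (b in bp[c("tnc", "cam", "fluo", "sr")]) {
    c0 <- 0.7
    beq <- b$total * c0 / (b$k_off / b$k_on + c0)
    expect_equal(buffer_reaction(c0, beq, b), 0, tolerance = 1e-12)
  }
  # troponin C at diastolic calcium: Kd ~ 0.605 uM, b* ~ 16.6 uM
  tnc <- bp$tnc
  kd <- tnc$k_off / tnc$k_on
  expect_equal(kd, 0.026 / 0.043, tolerance = 1e-12)
  beq <- tnc$total * 0.275 / (kd + 0.275)
  expect_equal(beq, 53 * 0.275 / (0.026 / 0.043 + 0.275), tolerance = 1e-9)
  expect_equal(beq, 16.6, tolerance = 0.01)
  # calmodulin dissociation constant from the printed rates
  expect_equal(bp$cam$k_off / bp$cam$k_on, 0.25, tolerance = 1e-12)
})

test_that("SERCA flux has its Hill-2 limits", {
  p <- cicr_params()$pump
  expect_equal(pump_flux(0, p), 0)
  expect_equal(pump_flux(p$K_p, p), p$v_max / 2)
  expect_equal(pump_flux(0.2, p), 0.4, tolerance = 1e-12)
  expect_equal(pump_flux(1e9, p), 0.8, tolerance = 1e-6)
})

test_that("NCX flux is linear in g, position-scaled, and reverses in V", {
  p <- cicr_params()$ncx
  ph <- cicr_params()$physical
  j1 <- ncx_flux(0.5, -40, "bulk", p, ph)
  p2 <- utils::modifyList(p, list(g_naca = 2 * p$g_naca))
  expect_equal(ncx_flux(0.5, -40, "bulk", p2, ph), 2 * j1,
               tolerance = 1e-12)
  # near-CRU to bulk ratio is the printed 2.5 : 1.5
  expect_equal(ncx_flux(0.5, -40, "near", p, ph) /
                 ncx_flux(0.5, -40, "bulk", p, ph), 2.5 / 1.5,
               tolerance = 1e-12)
  # sign reversal across a voltage sweep at fixed concentrations
  Vs <- seq(-90, 80, by = 1)
  js <- vapply(Vs, function(V) ncx_flux(0.3, V, "bulk", p, ph), numeric(1))
  expect_lt(js[1], 0)                  # forward mode (extrusion) at rest
  expect_gt(js[length(js)], 0)         # reverse mode at depolarized V
  rev <- stats::uniroot(function(V) ncx_flux(0.3, V, "bulk", p, ph),
                        c(-90, 80))$root
  expect_equal(ncx_flux(0.3, rev, "bulk", p, ph), 0, tolerance = 1e-10)
})

test_that("uniform equilibrium fields have vanishing derivatives", {
  params <- cicr_params()
  grid <- grid_spec(c(2, 2, 1), 0.25, membrane = character(0))
  f <- init_fields(grid, params, c0 = 0.4, S0 = 800)
  d <- pde_rhs(f, grid, params, pump = FALSE, ncx = FALSE,
               pm_flux = FALSE)
  for (nm in names(d)) expect_lt(max(abs(d[[nm]])), 1e-10)
})

test_that("diffusion matches the heat kernel within two percent", {
  p0 <- cicr_params(buffers = list(tnc = list(total = 0),
                                   cam = list(total = 0),
                                   fluo = list(total = 0),
                                   sr = list(total = 0)))
  grid <- grid_spec(c(6, 1, 1), 0.125, membrane = character(0))
  f <- init_fields(grid, p0, c0 = 0, S0 = 0)
  cc <- grid_cell_centers(grid)
  s2_0 <- 0.25^2
  f$c <- exp(-(cc$x - 3)^2 / (2 * s2_0))
  t <- 0; D <- p0$buffers$D_ca; dtp <- 0.02; t_end <- 1.5
  while (t < t_end - 1e-9) {
    st <- pde_step(f, grid, p0, dt = min(dtp, t_end - t), pump = FALSE,
                   ncx = FALSE, pm_flux = FALSE, rtol = 1e-5, atol = 1e-7)
    f <- st$fields; t <- t + st$dt_accepted; dtp <- st$dt_next
  }
  s2_t <- s2_0 + 2 * D * t_end
  pred <- sqrt(s2_0 / s2_t) * exp(-(cc$x - 3)^2 / (2 * s2_t))
  expect_lt(max(abs(f$c - pred)) / max(pred), 0.02)
})

test_that("the time integrator is second-order on linear decay", {
  # b_tnc with zero on-rate decays as db/dt = -k_off * b exactly (the
  # released calcium cannot rebind and does not enter this field)
  k <- 0.4
  params <- cicr_params(buffers = list(tnc = list(total = 0, k_on = 0,
                                                  k_off = k),
                                       cam = list(total = 0, k_on = 0),
                                       fluo = list(total = 0, k_on = 0),
                                       sr = list(total = 0, k_on = 0)))
  grid <- grid_spec(c(0.5, 0.5, 0.5), 0.25, membrane = character(0))
  t_end <- 2
  errs <- vapply(c(0.25, 0.125, 0.0625, 0.03125), function(dt) {
    f <- init_fields(grid, params, c0 = 0, S0 = 0)
    f$b_tnc[] <- 1
    for (k2 in seq_len(round(t_end / dt))) {
      f <- pde_step(f, grid, params, dt = dt, adaptive = FALSE,
                    pump = FALSE, ncx = FALSE, pm_flux = FALSE)$fields
    }
    abs(f$b_tnc[1] - exp(-k * t_end))
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 1.7))
  expect_lt(errs[length(errs)], 1e-4)
})

test_that("tightening the step-control tolerance leaves the solution put", {
  # deterministic relaxation of an off-equilibrium bump with buffers,
  # pump and diffusion active: the step controller must already be
  # resolving the dynamics at the default tolerance
  params <- cicr_params()
  grid <- grid_spec(c(2, 2, 1), 0.25, membrane = character(0))
  checkpoints <- seq(0.5, 20, by = 0.5)
  run_at <- function(rtol, atol) {
    f <- init_fields(grid, params, c0 = 0.275, S0 = 1000)
    cc <- grid_cell_centers(grid)
    f$c <- f$c + 2 * exp(-((cc$x - 1)^2 + (cc$y - 1)^2) / 0.1)
    t <- 0; dtp <- 0.01
    trace <- numeric(0)
    for (tc in checkpoints) {
      while (t < tc - 1e-9) {
        st <- pde_step(f, grid, params, dt = min(dtp, tc - t),
                       ncx = FALSE, pm_flux = FALSE, rtol = rtol,
                       atol = atol)
        f <- st$fields; t <- t + st$dt_accepted; dtp <- st$dt_next
      }
      trace <- c(trace, mean(f$c))
    }
    trace
  }
  loose <- run_at(1e-4, 1e-2)
  tight <- run_at(1e-6, 1e-4)
  expect_lt(max(abs(loose - tight) / abs(tight)), 0.005)
})

test_that("accepted trajectories keep every field non-negative", {
  params <- cicr_params()
  grid <- grid_spec(c(2, 2, 1), 0.25)
  f <- init_fields(grid, params, c0 = 0.05, S0 = 100)
  jc <- numeric(grid$n_cell); jc[10] <- 80
  t <- 0; dtp <- 0.05
  while (t < 5) {
    st <- pde_step(f, grid, params, dt = dtp, j_cru = jc, V = -80)
    f <- st$fields; t <- t + st$dt_accepted; dtp <- st$dt_next
    for (nm in names(f)) expect_true(all(f[[nm]] >= 0))
  }
})

test_that("grid refinement leaves the averaged spark transient in place", {
  # a prescribed spark source (a ~7-channel release for 10 ms) at the
  # domain center; halving the default node spacing must change the
  # peak averaged concentration by under 5%
  params <- cicr_params()
  run_at <- function(h) {
    grid <- grid_spec(c(2, 2, 2), h, membrane = character(0))
    cc <- grid_cell_centers(grid)
    ctr <- which.min((cc$x - 1)^2 + (cc$y - 1)^2 + (cc$z - 1)^2)
    jc <- numeric(grid$n_cell)
    jc[ctr] <- 15 / (params$physical$v_cyt_frac * h^3)  # uM um^3/ms total
    f <- init_fields(grid, params)
    t <- 0; dtp <- 0.02
    peak <- mean(f$c)
    while (t < 15 - 1e-9) {
      src <- if (t < 10) jc else numeric(grid$n_cell)
      st <- pde_step(f, grid, params, dt = min(dtp, 15 - t), j_cru = src,
                     ncx = FALSE, pm_flux = FALSE)
      f <- st$fields; t <- t + st$dt_accepted; dtp <- min(st$dt_next, 0.25)
      peak <- max(peak, mean(f$c))
    }
    peak
  }
  coarse <- run_at(0.25)
  fine <- run_at(0.125)
  expect_lt(abs(coarse - fine) / fine, 0.05)
})
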