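test_that("4-state RyR rates pin the saturation and threshold constants", {
  p <- cicr_params()$ryr$stern4
  # saturation of the luminal-modulated activation as c and c_jsr grow
  r_inf <- stern4_rates(1e9, 1e12)
  expect_equal(r_inf$k_o, 0.9288, tolerance = 1e-6)
  # Hill function through the origin
  expect_equal(stern4_rates(0, 1000)$k_o, 0)
  # midpoint of the 4th-order Hill at the activation threshold
  r_mid <- stern4_rates(8.5, 700)
  r_sat <- stern4_rates(1e9, 700)
  expect_equal(r_mid$k_o, r_sat$k_o / 2, tolerance = 1e-9)
  # inactivation saturates at the printed maximum from the closed state,
  # lambda-fold faster from the open state
  r <- stern4_rates(1e9, 1000)
  expect_equal(r$k_i, 0.0078, tolerance = 1e-6)
  expect_equal(r$k_i_open, 0.0078 * 27.5, tolerance = 1e-6)
  expect_equal(r$k_om, 0.060)
  expect_equal(r$k_im, 0.005)
})

test_that("induction-decay 2-state rates follow the printed power laws", {
  r <- cannell2_rates(100)                   # 0.1 mM
  raw <- 457 * 0.1^2.12
  expect_gt(raw, 0.8)                        # cap engages at this point
  expect_equal(r$k_open, 0.8)
  expect_equal(r$k_close, 0.245 * 0.1^-0.27, tolerance = 1e-9)
  # the cap bounds k_open everywhere
  cc <- 10^seq(-2, 4, length.out = 200)
  expect_true(all(cannell2_rates(cc)$k_open <= 0.8 + 1e-12))
  # below-cap branch matches the law
  r2 <- cannell2_rates(20)                   # 0.02 mM
  expect_equal(r2$k_open, 457 * 0.02^2.12, tolerance = 1e-9)
  # degenerate input
  r0 <- cannell2_rates(0)
  expect_equal(r0$k_open, 0)
  expect_equal(r0$k_close, cicr_params()$ryr$cannell2$k_close_max)
})

test_that("luminal-regulation 2-state rates and phi term are as printed", {
  expect_equal(walker2_rates(1, 0)$phi, 0.8025)
  expect_equal(walker2_rates(1, 1500)$phi, 1.8025)
  r <- walker2_rates(10, 1500)
  expect_equal(r$k_open, 1.107e-4 * 1.8025 * 10^2.1, tolerance = 1e-9)
  expect_equal(r$k_open, 0.0251, tolerance = 2e-3)
})

test_that("7-state LCC generator is admissible with the printed closing rate", {
  for (V in c(-100, -60, -20, 0, 30, 60)) {
    for (cc in c(0.1, 1, 50, 1000)) {
      Q <- mahajan_lcc7_rates(V, cc)
      expect_true(all(is.finite(Q)))
      off <- Q; diag(off) <- 0
      expect_true(all(off >= 0))
      expect_equal(rowSums(Q), rep(0, 7), tolerance = 1e-12,
                   ignore_attr = TRUE)
      expect_equal(Q["O", "C1"], 3)
    }
  }
})

test_that("steady-state occupancy matches independent oracles", {
  # LCC: the null-space solution against long master-equation integration
  Q <- mahajan_lcc7_rates(-10, 20)
  p <- steady_state_occupancy(Q)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_true(all(p > -1e-12))
  # the slowest recovery pathway has a ~10 s time constant; integrate well past it
  me <- master_equation(Q, rep(1 / 7, 7), t_end = 1.2e5, dt = 0.2)
  expect_equal(me$p[nrow(me$p), ], p, tolerance = 5e-3)
  # 4-state RyR: null space against long-run Monte-Carlo frequencies
  # (fast-mixing conditions so the dwell-weighted error is ~3 sigma)
  sc <- markov_scheme("stern4")
  Q4 <- sc$generator(15, 800)
  p4 <- steady_state_occupancy(Q4)
  set.seed(11)
  sim <- simulate_channel(sc, 15, 800, n_events = 20000)
  occ <- tapply(sim$dwell, sim$state, sum) / sum(sim$dwell)
  for (s in names(occ)) {
    expect_lt(abs(occ[[s]] - p4[s]), 0.04)
  }
})

test_that("event clock inverts constant, zero and linearly growing rates", {
  # constant rate: t* = t0 + theta / lambda
  r <- sample_event_time(function(t) 2, t0 = 1, tau = 5, threshold = 3)
  expect_equal(r$time, 1 + 3 / 2, tolerance = 1e-10)
  # zero rate: no event
  r0 <- sample_event_time(function(t) 0, 0, 10, threshold = 0.5)
  expect_true(is.na(r0$time))
  expect_equal(r0$accumulated, 0)
  # linear growth lambda = a (t - t0): t* = t0 + sqrt(2 theta / a)
  a <- 0.7; th <- 1.3
  r1 <- sample_event_time(function(t) a * (t - 2), 2, 10, threshold = th)
  expect_equal(r1$time, 2 + sqrt(2 * th / a), tolerance = 1e-6)
  # accumulated integral carries across windows
  r2 <- sample_event_time(function(t) 1, 0, 1, threshold = 2.5)
  expect_true(is.na(r2$time))
  r3 <- sample_event_time(function(t) 1, 1, 2, threshold = 2.5,
                          accumulated = r2$accumulated)
  expect_equal(r3$time, 2.5, tolerance = 1e-10)
  expect_error(sample_event_time(function(t) -1, 0, 1, 1), "negative")
})

test_that("dwell times are exponential with mean one over the exit rate", {
  set.seed(5)
  sc <- markov_scheme("walker2")
  sim <- simulate_channel(sc, c_di = 25, c_jsr = 1000, n_events = 4000)
  Q <- sc$generator(25, 1000)
  for (s in c("C", "O")) {
    d <- sim$dwell[sim$state == s]
    ks <- suppressWarnings(stats::ks.test(d, "pexp", rate = -Q[s, s]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("2-state open probability equals k_open/(k_open + k_close)", {
  p <- cicr_params()$ryr$walker2
  r <- walker2_rates(30, 800, p)
  p_an <- r$k_open / (r$k_open + r$k_close)
  set.seed(9)
  sc <- markov_scheme("walker2")
  sim <- simulate_channel(sc, 30, 800, n_events = 20000)
  p_emp <- sum(sim$dwell[sim$state == "O"]) / sum(sim$dwell)
  expect_equal(p_emp, p_an, tolerance = 0.05 * max(p_an, 0.2))
})

test_that("neutral batching preserves occupancy statistics and ordering", {
  set.seed(21)
  sc <- markov_scheme("stern4")
  # channels are independent, so the end-of-run state histogram over a
  # large ensemble gives independent samples for the comparison
  run_hist <- function(cap_frac, n = 256, t_total = 60) {
    ens <- channel_ensemble(sc, n, c_di = 12, c_jsr = 800)
    t <- 0
    while (t < t_total) {
      ens <- apply_neutral_batch(ens, tau = min(0.5, t_total - t),
                                 cap_frac = cap_frac)
      t <- t + attr(ens, "elapsed")
    }
    tabulate(ens$states, 4)
  }
  batched <- run_hist(0.1)
  single <- run_hist(1e-9)
  tab <- rbind(batched, single)
  keep <- colSums(tab) > 0
  chi <- suppressWarnings(stats::chisq.test(tab[, keep]))
  expect_gt(chi$p.value, 0.01)
  # empty ensemble window: no spurious conductance flips at zero calcium
  ens <- channel_ensemble(sc, 16, c_di = 0, c_jsr = 800)
  st0 <- ens$states
  ens2 <- apply_neutral_batch(ens, tau = 1)
  expect_equal(attr(ens2, "n_events"), 0)
  expect_true(all((ens2$states == 2L) == (st0 == 2L)))
})

test_that("seeded gating is reproducible", {
  sc <- markov_scheme("cannell2")
  set.seed(123)
  a <- simulate_channel(sc, 40, n_events = 200)
  set.seed(123)
  b <- simulate_channel(sc, 40, n_events = 200)
  expect_identical(a, b)
})
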