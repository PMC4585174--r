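test_that("channel placement builds compact lattices with the rim margin", {
  # a lone RyR sits at the center: radius equals the margin
  g1 <- place_channels(1, 0)
  expect_equal(g1$radius, 60)
  expect_equal(c(g1$x, g1$y), c(0, 0))
  # mixed array keeps every channel at least 60 nm from the rim
  g <- place_channels(30, 8)
  r <- sqrt(g$x^2 + g$y^2)
  expect_true(all(r <= g$radius - 60 + 1e-9))
  expect_equal(sum(g$type == "RyR"), 30)
  expect_equal(sum(g$type == "LCC"), 8)
  # nearest-neighbor RyR spacing equals the lattice pitch
  ry <- which(g$type == "RyR")
  d <- as.matrix(stats::dist(cbind(g$x[ry], g$y[ry])))
  diag(d) <- Inf
  expect_equal(min(d), 30, tolerance = 1e-9)
  # LCCs interleave on the offset lattice (never coincide with RyRs)
  lc <- which(g$type == "LCC")
  dd <- outer(g$x[ry], g$x[lc], `-`)^2 + outer(g$y[ry], g$y[lc], `-`)^2
  expect_gt(min(dd), 100)
})

test_that("CRU population has exponential RyR counts and the 4:1 ratio", {
  set.seed(1)
  pop <- sample_cru_population(domain = c(40, 40, 2), n_discs = 1,
                               crus_per_disc = 5120)
  n_ryr <- vapply(pop, function(u) u$n_ryr, numeric(1))
  n_lcc <- vapply(pop, function(u) u$n_lcc, numeric(1))
  # sample mean within 3 standard errors of 50
  se <- 50 / sqrt(length(n_ryr))
  expect_lt(abs(mean(n_ryr) - 50), 3 * se)
  # exponential variance ~ mean^2 (rounding truncation tolerated)
  expect_lt(abs(stats::var(n_ryr) / mean(n_ryr)^2 - 1), 0.15)
  # per-CRU ratio ~ 4 (integer rounding at small counts)
  expect_lt(abs(stats::median(n_ryr / n_lcc) - 4), 0.6)
  expect_true(all(n_lcc >= 1))
  # jSR volume apportionment proportional to RyR count, summing to the
  # configured fraction of the subvolume
  v <- vapply(pop, function(u) u$v_jsr, numeric(1))
  expect_equal(sum(v), 0.005 * 40 * 40 * 2, tolerance = 1e-9)
  expect_equal(stats::cor(v, n_ryr), 1, tolerance = 1e-9)
  # reproducibility
  set.seed(99)
  a <- sample_cru_population(c(5, 5, 2))
  set.seed(99)
  b <- sample_cru_population(c(5, 5, 2))
  expect_identical(vapply(a, function(u) u$n_ryr, numeric(1)),
                   vapply(b, function(u) u$n_ryr, numeric(1)))
  expect_identical(a[[3]]$center, b[[3]]$center)
})

test_that("calsequestrin factor has its algebraic special cases", {
  p <- cicr_params()$jsr
  expect_equal(jsr_buffer_factor(500, utils::modifyList(p, list(B_csqn = 0))),
               1)
  # at c_jsr = K the factor reduces to (1 + n B / (4 K))^-1
  expect_equal(jsr_buffer_factor(p$K_csqn, p),
               1 / (1 + p$n_csqn * p$B_csqn / (4 * p$K_csqn)),
               tolerance = 1e-12)
  expect_true(all(jsr_buffer_factor(c(0, 10, 1e4), p) <= 1))
  expect_true(all(jsr_buffer_factor(c(0, 10, 1e4), p) > 0))
})

test_that("jSR refill relaxes exponentially and depletion is monotone", {
  p <- cicr_params()$jsr
  # without calsequestrin the refill is a pure exponential with tau = 0.5
  p0 <- utils::modifyList(p, list(B_csqn = 0))
  c0 <- 200; S <- 1000
  out <- jsr_step(c0, S, ryr_efflux = 0, v_jsr = 0.01, dt = 1, params = p0)
  expect_equal(out$c_jsr, S + (c0 - S) * exp(-1 / p0$tau_refill),
               tolerance = 1e-3)
  # relaxation is monotone toward S
  cs <- Reduce(function(c, k) jsr_step(c, S, 0, 0.01, 0.2, p0)$c_jsr,
               1:20, accumulate = TRUE, init = c0)
  expect_true(all(diff(cs) > 0))
  expect_true(all(cs <= S))
  # refill disabled, channels draining: monotone depletion to zero
  pslow <- utils::modifyList(p, list(tau_refill = 1e12))
  c <- 500
  cs <- c()
  for (k in 1:40) {
    c <- suppressWarnings(jsr_step(c, 1000, ryr_efflux = 1, v_jsr = 0.01,
                                   dt = 1, params = pslow)$c_jsr)
    cs <- c(cs, c)
  }
  expect_true(all(diff(cs) <= 1e-12))
  expect_equal(cs[length(cs)], 0)
})

test_that("bulk source deposits conserve the channel current exactly", {
  params <- cicr_params()
  grid <- grid_spec(c(4, 4, 2), 0.25)
  set.seed(3)
  pop <- sample_cru_population(c(4, 4, 2), crus_per_disc = 4)
  totals <- c(2.5, 0, 1.0, 0.3)
  J <- cru_bulk_source(pop, totals, grid, params)
  # volume integral, cytosol-fraction weighted, equals the total current
  got <- sum(J) * grid$h^3 * params$physical$v_cyt_frac
  expect_equal(got, sum(totals), tolerance = 1e-12)
  # additivity over disjoint CRUs
  J1 <- cru_bulk_source(pop, c(2.5, 0, 0, 0), grid, params)
  J2 <- cru_bulk_source(pop, c(0, 0, 1.0, 0.3), grid, params)
  expect_equal(J1 + J2, J, tolerance = 1e-12)
  expect_equal(cru_bulk_source(pop, rep(0, 4), grid, params),
               numeric(grid$n_cell))
})

test_that("jSR refill sink mirrors the refill term of the jSR equation", {
  params <- cicr_params()
  grid <- grid_spec(c(4, 4, 2), 0.25)
  set.seed(3)
  pop <- sample_cru_population(c(4, 4, 2), crus_per_disc = 4)
  refill <- c(100, 0, -40, 10)  # (S - c_jsr)/tau, uM/ms
  J <- jsr_refill_sink(pop, refill, grid, params)
  v <- vapply(pop, function(u) u$v_jsr, numeric(1))
  # SR-volume-weighted integral equals sum of v_jsr * refill (amount
  # conservation between network SR and jSRs)
  expect_equal(sum(J) * grid$h^3 * params$physical$v_sr_frac,
               sum(v * refill), tolerance = 1e-12)
  # halving the refill rate (e.g. doubling tau) halves the sink
  expect_equal(jsr_refill_sink(pop, refill / 2, grid, params), J / 2,
               tolerance = 1e-12)
  # equal concentrations: no sink
  expect_equal(jsr_refill_sink(pop, rep(0, 4), grid, params),
               numeric(grid$n_cell))
})
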