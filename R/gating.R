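#' RyR gating rates: 4-state scheme
#'
#' Rates of the four-state RyR model (resting R, open O, inactivated I,
#' resting-inactivated RI). Activation R->O and RI->I is a fourth-order
#' Hill function of dyadic Ca2+ saturating at `k_ac_max`, multiplied by a
#' first-order luminal modulation `c_jsr / (c_jsr + K_jsr)`. Inactivation
#' is a first-order Hill function of dyadic Ca2+ saturating at `k_in_max`
#' from the closed state (R -> RI) and is asymmetric: it proceeds
#' `lambda`-fold faster from the open state (O -> I), which makes open
#' channels inactivate quickly while closed channels rarely do. `k_om`
#' closes the channel, `k_im` recovers from inactivation.
#'
#' @param c_di dyadic Ca2+ at the channel mouth, uM.
#' @param c_jsr junctional-SR free Ca2+, uM.
#' @param params the `ryr$stern4` block of [cicr_params()].
#' @return Named list of rates (ms^-1): `k_o` (activation, luminal
#'   modulated), `k_om`, `k_i` (closed-state inactivation), `k_i_open`
#'   (`lambda * k_i`), `k_im`.
#' @export
stern4_rates <- function(c_di, c_jsr, params = cicr_params()$ryr$stern4) {
  stopifnot(all(c_di >= 0), all(c_jsr >= 0))
  f_jsr <- c_jsr / (c_jsr + params$K_jsr)
  h4 <- c_di^4 / (params$K_ac^4 + c_di^4)
  k_i <- params$k_in_max * c_di / (params$K_in + c_di)
  list(k_o = params$k_ac_max * h4 * f_jsr,
       k_om = params$k_om,
       k_i = k_i,
       k_i_open = k_i * params$lambda,
       k_im = params$k_im)
}

#' RyR gating rates: induction-decay 2-state scheme
#'
#' Power-law opening and closing rates fitted to spark data. The fitted
#' laws take dyadic Ca2+ in mM; the opening rate is capped at
#' `k_open_max` and the (diverging) closing rate at `k_close_max` as
#' `c_di -> 0`.
#'
#' @param c_di dyadic Ca2+ at the mouth, uM.
#' @param params the `ryr$cannell2` block of [cicr_params()].
#' @return Named list with `k_open`, `k_close` (ms^-1).
#' @export
cannell2_rates <- function(c_di, params = cicr_params()$ryr$cannell2) {
  stopifnot(all(c_di >= 0))
  c_mM <- c_di * 1e-3
  k_open <- ifelse(c_mM > 0,
                   pmin(params$A_open * c_mM^params$p_open, params$k_open_max),
                   0)
  k_close <- ifelse(c_mM > 0,
                    pmin(params$A_close * c_mM^params$p_close,
                         params$k_close_max),
                    params$k_close_max)
  list(k_open = k_open, k_close = k_close)
}

#' RyR gating rates: luminal-regulation 2-state scheme
#'
#' Opening rate `k_plus * phi * c_di^eta` with the luminal regulation
#' term `phi = phi_b + (c_jsr / phi_k)^4`; constant closing rate. The
#' opening rate is theoretically unbounded; simulations track the largest
#' value encountered.
#'
#' @param c_di dyadic Ca2+ at the mouth, uM.
#' @param c_jsr junctional-SR free Ca2+, uM.
#' @param params the `ryr$walker2` block of [cicr_params()].
#' @return Named list with `k_open`, `k_close` (ms^-1) and `phi`.
#' @export
walker2_rates <- function(c_di, c_jsr, params = cicr_params()$ryr$walker2) {
  stopifnot(all(c_di >= 0), all(c_jsr >= 0))
  phi <- params$phi_b + (c_jsr / params$phi_k)^4
  list(k_open = params$k_plus * phi * c_di^params$eta,
       k_close = params$k_close,
       phi = phi)
}

# LCC 7-state rate set at (V, cp); cp is the Ca2+ concentration at the
# channel mouth in uM. Reconstruction of the rabbit LCC Markov scheme with
# the package's threshold constants: Ca-driven inactivation factor
# fcp = 1/(1+(k_p0/cp)^3) and the k6/tau_Ca threshold c_p_bar.
.lcc7_rate_set <- function(V, cp, params) {
  po_inf <- 1 / (1 + exp(-V / 8))
  alpha <- po_inf / params$tau_po
  beta <- max(1 - po_inf, 1e-12) / params$tau_po
  fcp <- 1 / (1 + (params$k_p0 / max(cp, 1e-12))^3)
  s1_bar <- 0.0182688; k1_bar <- 0.024168
  s1 <- s1_bar * fcp
  k1 <- k1_bar * fcp
  # microscopic-reversibility partners; fcp cancels where it would give 0/0
  s2 <- (s1_bar / k1_bar) * params$k2 * (params$r1 / params$r2)
  s2p <- params$s1p * (params$k21p / params$k1p) * (params$r1 / params$r2)
  Ps <- 1 / (1 + exp(-(V + 40) / 11.32))
  u <- (cp / params$c_p_bar)^4
  tca <- (78.0329 + 0.1 * u) / (1 + u)
  k5 <- (1 - Ps) / tca
  k6 <- fcp * Ps / tca
  k5p <- (1 - Ps) / params$T_ba
  k6p <- Ps / params$T_ba
  e3 <- exp(-(V + 40) / 3)
  k3 <- e3 / (3 * (1 + e3))
  k4 <- k3 * (alpha / beta) * (k1_bar / params$k2) * ((1 - Ps) / Ps) *
    ifelse(Ps > 0, 1, 0)
  k4p <- k3 * (alpha / beta) * (params$k1p / params$k21p) * ((1 - Ps) / Ps)
  list(alpha = alpha, beta = beta, r1 = params$r1, r2 = params$r2,
       s1 = s1, s2 = s2, s1p = params$s1p, s2p = s2p,
       k1 = k1, k2 = params$k2, k1p = params$k1p, k2p = params$k21p,
       k3 = k3, k4 = k4, k5 = k5, k6 = k6,
       k3p = k3, k4p = k4p, k5p = k5p, k6p = k6p, fcp = fcp)
}

#' LCC gating rates: 7-state scheme
#'
#' Generator of the seven-state L-type channel model (closed C2, C1, open
#' O, Ca2+-inactivated I1Ca, I2Ca, and Ca2+-independent inactivated I1Ba,
#' I2Ba). Voltage activation proceeds C2 -> C1 -> O with time constant
#' `tau_po`; inactivation is both Ca2+-dependent (threshold `k_p0` on the
#' mouth concentration) and voltage-dependent; recovery loops close
#' through I2 states back to C2. Closing O -> C1 at the constant `r2`.
#'
#' @param V membrane potential, mV.
#' @param c_mouth Ca2+ at the channel mouth, uM.
#' @param params the `lcc` block of [cicr_params()].
#' @return 7 x 7 generator matrix (ms^-1), rows = from-state, with state
#'   names `C2, C1, O, I1Ca, I2Ca, I1Ba, I2Ba`; row sums are zero.
#' @export
mahajan_lcc7_rates <- function(V, c_mouth, params = cicr_params()$lcc) {
  stopifnot(is.finite(V))
  r <- .lcc7_rate_set(V, c_mouth, params)
  st <- lcc_states()
  Q <- matrix(0, 7, 7, dimnames = list(st, st))
  Q["C2", "C1"] <- r$alpha;  Q["C1", "C2"] <- r$beta
  Q["C1", "O"] <- r$r1;      Q["O", "C1"] <- r$r2
  Q["C1", "I1Ca"] <- r$k1;   Q["I1Ca", "C1"] <- r$k2
  Q["C1", "I1Ba"] <- r$k1p;  Q["I1Ba", "C1"] <- r$k2p
  Q["O", "I1Ca"] <- r$s1;    Q["I1Ca", "O"] <- r$s2
  Q["O", "I1Ba"] <- r$s1p;   Q["I1Ba", "O"] <- r$s2p
  Q["I1Ca", "I2Ca"] <- r$k3; Q["I2Ca", "I1Ca"] <- r$k4
  Q["I1Ba", "I2Ba"] <- r$k3p; Q["I2Ba", "I1Ba"] <- r$k4p
  Q["C2", "I2Ca"] <- r$k6;   Q["I2Ca", "C2"] <- r$k5
  Q["C2", "I2Ba"] <- r$k6p;  Q["I2Ba", "C2"] <- r$k5p
  diag(Q) <- -rowSums(Q)
  Q
}

#' @rdname mahajan_lcc7_rates
#' @export
lcc_states <- function() c("C2", "C1", "O", "I1Ca", "I2Ca", "I1Ba", "I2Ba")

#' Markov scheme descriptor
#'
#' Wraps a gating scheme behind a common interface: state names, the
#' conducting state, and a generator-matrix function of the local inputs.
#'
#' @param name one of `"stern4"`, `"cannell2"`, `"walker2"`,
#'   `"mahajan_lcc7"`.
#' @param params full [cicr_params()] list supplying the scheme constants.
#' @return A list of class `"markov_scheme"` with elements `name`,
#'   `states`, `open` (index of the conducting state), and
#'   `generator(c_di, c_jsr, V)`.
#' @export
markov_scheme <- function(name = c("stern4", "cannell2", "walker2",
                                   "mahajan_lcc7"),
                          params = cicr_params()) {
  name <- match.arg(name)
  sc <- switch(
    name,
    stern4 = {
      pr <- params$ryr$stern4
      list(states = c("R", "O", "I", "RI"), open = 2L,
           generator = function(c_di, c_jsr = 1000, V = 0) {
             r <- stern4_rates(c_di, c_jsr, pr)
             Q <- matrix(0, 4, 4,
                         dimnames = list(c("R", "O", "I", "RI"),
                                         c("R", "O", "I", "RI")))
             Q["R", "O"] <- r$k_o;       Q["O", "R"] <- r$k_om
             Q["O", "I"] <- r$k_i_open;  Q["I", "O"] <- r$k_im
             Q["R", "RI"] <- r$k_i;      Q["RI", "R"] <- r$k_im
             Q["RI", "I"] <- r$k_o;      Q["I", "RI"] <- r$k_om
             diag(Q) <- -rowSums(Q)
             Q
           })
    },
    cannell2 = {
      pr <- params$ryr$cannell2
      list(states = c("C", "O"), open = 2L,
           generator = function(c_di, c_jsr = 1000, V = 0) {
             r <- cannell2_rates(c_di, pr)
             Q <- matrix(c(-r$k_open, r$k_open, r$k_close, -r$k_close),
                         2, 2, byrow = TRUE,
                         dimnames = list(c("C", "O"), c("C", "O")))
             Q
           })
    },
    walker2 = {
      pr <- params$ryr$walker2
      list(states = c("C", "O"), open = 2L,
           generator = function(c_di, c_jsr = 1000, V = 0) {
             r <- walker2_rates(c_di, c_jsr, pr)
             Q <- matrix(c(-r$k_open, r$k_open, r$k_close, -r$k_close),
                         2, 2, byrow = TRUE,
                         dimnames = list(c("C", "O"), c("C", "O")))
             Q
           })
    },
    mahajan_lcc7 = {
      pr <- params$lcc
      list(states = lcc_states(), open = 3L,
           generator = function(c_di, c_jsr = NULL, V = 0) {
             mahajan_lcc7_rates(V, c_di, pr)
           })
    })
  structure(c(list(name = name), sc), class = "markov_scheme")
}

#' @export
print.markov_scheme <- function(x, ...) {
  cat(sprintf("<markov_scheme> %s: %d states, conducting = %s\n",
              x$name, length(x$states), x$states[x$open]))
  invisible(x)
}

#' Steady-state occupancy of a generator
#'
#' Stationary distribution `p` with `p Q = 0`, `sum(p) = 1`.
#'
#' @param Q generator matrix (rows = from-state).
#' @return Named probability vector.
#' @export
steady_state_occupancy <- function(Q) {
  n <- nrow(Q)
  A <- rbind(t(Q), rep(1, n))
  b <- c(rep(0, n), 1)
  p <- drop(qr.solve(A, b))
  names(p) <- rownames(Q)
  p
}

#' Event time of an integrated-propensity clock
#'
#' Time-dependent Gillespie sampling: the next event occurs when the
#' running integral of the propensity crosses an exponential threshold.
#' The propensity is taken piecewise-linear on an internal grid, so the
#' integral is trapezoidal and the crossing inside an interval is solved
#' exactly from the quadratic accumulated integral (exact for constant
#' and linearly varying rates).
#'
#' @param propensity function of time, `>= 0` on the window.
#' @param t0 window start, ms.
#' @param tau window length, ms.
#' @param threshold random threshold (e.g. `rexp(1)`); the event fires
#'   when `accumulated + integral` reaches it.
#' @param accumulated propensity integral already accumulated before
#'   `t0`.
#' @param n_grid number of sub-intervals for the piecewise-linear
#'   approximation.
#' @return A list with `time` (event time, or `NA` if no crossing in the
#'   window) and `accumulated` (integral up to the event or window end).
#' @export
sample_event_time <- function(propensity, t0, tau, threshold,
                              accumulated = 0, n_grid = 64L) {
  stopifnot(tau >= 0, threshold >= accumulated - 1e-15)
  if (tau == 0) return(list(time = NA_real_, accumulated = accumulated))
  ts <- seq(t0, t0 + tau, length.out = n_grid + 1L)
  lam <- vapply(ts, propensity, numeric(1))
  if (any(lam < 0)) stop("negative propensity")
  A <- accumulated
  for (k in seq_len(n_grid)) {
    h <- ts[k + 1L] - ts[k]
    inc <- (lam[k] + lam[k + 1L]) / 2 * h
    if (A + inc >= threshold && inc > 0) {
      # solve A + l0 s + (l1-l0) s^2 / (2h) = threshold for s in [0, h]
      l0 <- lam[k]; slope <- (lam[k + 1L] - lam[k]) / h
      need <- threshold - A
      s <- if (abs(slope) < 1e-14) {
        need / l0
      } else {
        (-l0 + sqrt(l0^2 + 2 * slope * need)) / slope
      }
      s <- min(max(s, 0), h)
      return(list(time = ts[k] + s, accumulated = threshold))
    }
    A <- A + inc
  }
  list(time = NA_real_, accumulated = A)
}

#' Simulate a single channel at fixed conditions
#'
#' Continuous-time Markov-chain simulation of one channel with the
#' generator held at fixed `(c_di, c_jsr, V)`. Used for dwell-time and
#' occupancy statistics. Uses R's RNG (respects `set.seed()`).
#'
#' @param scheme a [markov_scheme()].
#' @param c_di,c_jsr,V fixed local conditions.
#' @param n_events number of transitions to simulate.
#' @param init initial state index; default samples the stationary
#'   distribution.
#' @return A data frame with columns `state` (name), `dwell` (ms) and
#'   `to` (next state).
#' @export
simulate_channel <- function(scheme, c_di, c_jsr = 1000, V = 0,
                             n_events = 1000L, init = NULL) {
  Q <- scheme$generator(c_di, c_jsr, V)
  n <- nrow(Q)
  if (is.null(init)) {
    p <- steady_state_occupancy(Q)
    init <- sample.int(n, 1, prob = pmax(p, 0))
  }
  st <- integer(n_events); dw <- numeric(n_events); to <- integer(n_events)
  s <- init
  for (k in seq_len(n_events)) {
    rates <- Q[s, ]; rates[s] <- 0
    tot <- sum(rates)
    if (tot <= 0) stop("absorbing state reached")
    st[k] <- s
    dw[k] <- stats::rexp(1, tot)
    s <- sample.int(n, 1, prob = rates / tot)
    to[k] <- s
  }
  data.frame(state = rownames(Q)[st], dwell = dw, to = rownames(Q)[to],
             stringsAsFactors = FALSE)
}

#' Create a channel ensemble at fixed conditions
#'
#' A set of independent channels of one scheme, each with its own
#' integrated-propensity clock (accumulated integral and exponential
#' threshold). Initial states are drawn from the stationary distribution
#' at the given conditions.
#'
#' @param scheme a [markov_scheme()].
#' @param n number of channels.
#' @param c_di,c_jsr,V fixed local conditions.
#' @return A list of class `"channel_ensemble"`.
#' @export
channel_ensemble <- function(scheme, n, c_di, c_jsr = 1000, V = 0) {
  Q <- scheme$generator(c_di, c_jsr, V)
  p <- pmax(steady_state_occupancy(Q), 0)
  states <- sample.int(nrow(Q), n, replace = TRUE, prob = p)
  structure(list(scheme = scheme, n = n, states = states,
                 acc = numeric(n), theta = stats::rexp(n),
                 c_di = c_di, c_jsr = c_jsr, V = V, t = 0),
            class = "channel_ensemble")
}

#' Advance an ensemble with neutral-transition batching
#'
#' Executes, over the window `[t, t + tau]`, every transition that does
#' not change conductance (batched, in time order per channel), and at
#' most `ceiling(cap_frac * N_s)` conductance-changing events, where
#' `N_s` is the number of conductance-changing events predicted in the
#' window. The step is truncated at the time of the last realized
#' conductance event, so conductance events are never reordered. With
#' `cap_frac = NA` (or `N_s = 0`) the full window is consumed.
#'
#' @param ens a [channel_ensemble()].
#' @param tau window length, ms.
#' @param cap_frac fraction of predicted conductance events realized per
#'   step (the batching rule); use `1e-9` to force one event per step.
#' @return Updated ensemble; attributes `elapsed` (accepted step) and
#'   `n_events` (conductance events realized).
#' @export
apply_neutral_batch <- function(ens, tau, cap_frac = 0.1) {
  Qfun <- ens$scheme$generator
  Q <- Qfun(ens$c_di, ens$c_jsr, ens$V)
  open_state <- ens$scheme$open
  n_state <- nrow(Q)
  # predict per-channel first conductance-changing event within the window
  cand_t <- rep(Inf, ens$n)
  cand_to <- integer(ens$n)
  sim <- list(states = ens$states, acc = ens$acc, theta = ens$theta)
  # channel-by-channel forward simulation; neutral transitions executed,
  # conductance transitions recorded and the channel frozen there
  pend <- vector("list", ens$n)
  for (i in seq_len(ens$n)) {
    t_loc <- 0
    s <- sim$states[i]; A <- sim$acc[i]; th <- sim$theta[i]
    hist_i <- list()
    repeat {
      rates <- Q[s, ]; rates[s] <- 0
      tot <- sum(rates)
      if (tot <= 0) { A <- A; break }
      t_cross <- t_loc + (th - A) / tot
      if (t_cross > tau) { A <- A + tot * (tau - t_loc); break }
      dest <- sample.int(n_state, 1, prob = rates / tot)
      conduct <- (s == open_state) != (dest == open_state)
      if (conduct) {
        cand_t[i] <- t_cross; cand_to[i] <- dest
        A <- th   # frozen at the crossing until realized
        break
      }
      hist_i[[length(hist_i) + 1L]] <- c(t_cross, dest)
      s <- dest; t_loc <- t_cross; A <- 0; th <- stats::rexp(1)
    }
    pend[[i]] <- list(state = s, acc = A, theta = th, hist = hist_i)
  }
  ns <- sum(is.finite(cand_t))
  if (ns == 0 || is.na(cap_frac)) {
    t_acc <- tau
    realize <- integer(0)
  } else {
    k <- max(1L, ceiling(cap_frac * ns))
    ord <- order(cand_t)
    realize <- ord[seq_len(min(k, ns))]
    realize <- realize[is.finite(cand_t[realize])]
    t_acc <- max(cand_t[realize])
  }
  # commit: neutral history up to t_acc; conductance events in `realize`
  for (i in seq_len(ens$n)) {
    pi <- pend[[i]]
    s <- ens$states[i]; A <- ens$acc[i]; th <- ens$theta[i]
    t_loc <- 0
    for (h in pi$hist) {
      if (h[1] > t_acc) break
      s <- h[2]; t_loc <- h[1]; A <- 0; th <- NA
    }
    if (is.na(th)) th <- stats::rexp(1)
    if (i %in% realize) {
      s <- cand_to[i]; A <- 0; th <- stats::rexp(1)
    } else {
      rates <- Q[s, ]; rates[s] <- 0
      tot <- sum(rates)
      if (is.finite(cand_t[i]) && cand_t[i] <= t_acc) {
        # predicted but not realized: clock stays at the threshold
        A <- ens$theta[i]
        th <- ens$theta[i]
      } else if (tot > 0) {
        A <- if (identical(s, ens$states[i]) && !length(pi$hist))
          ens$acc[i] + tot * t_acc else tot * (t_acc - t_loc)
      }
    }
    ens$states[i] <- s; ens$acc[i] <- min(A, th); ens$theta[i] <- th
  }
  ens$t <- ens$t + t_acc
  attr(ens, "elapsed") <- t_acc
  attr(ens, "n_events") <- length(realize)
  ens
}
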