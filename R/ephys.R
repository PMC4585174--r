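# Membrane-potential module: rabbit ventricular ionic model behind a
# swappable parameter interface, aggregation of CRU LCC currents and of
# the spatially integrated NCX flux into whole-cell currents, and a
# prescribed-AP clamp mode for testing the Ca2+ subsystem in isolation.

# parameter list consumed by the compiled membrane model
.mem_pars <- function(params) {
  ph <- params$physical
  c(params$conductances,
    list(na_o = ph$na_o, k_i = ph$k_i, k_o = ph$k_o,
         nai = params$ncx$nai, frt = .frt(ph)))
}

#' Membrane state
#'
#' State vector of the membrane model: voltage plus Hodgkin-Huxley gates
#' (`m, h, j` for the fast Na+ current, `xr`, `xs1, xs2`, `xtos, ytos`,
#' `xtof, ytof` for the K+ currents), initialized at their steady-state
#' values for the given voltage.
#'
#' @param V membrane potential, mV; default is the numerically located
#'   resting potential of the assembled current set.
#' @param params a [cicr_params()].
#' @return Named numeric vector of length 11.
#' @export
membrane_state <- function(V = NULL, params = cicr_params()) {
  if (is.null(V)) V <- find_resting_potential(params)
  y <- mahajan_init_cpp(V, .mem_pars(params))
  names(y) <- c("V", "m", "h", "j", "xr", "xs1", "xs2", "xtos", "ytos",
                "xtof", "ytof")
  y
}

#' Ionic currents at a membrane state
#'
#' Evaluates every ionic current (pA/pF) and the voltage derivative at a
#' given state, with externally supplied L-type and exchanger currents.
#'
#' @param state a [membrane_state()] vector.
#' @param i_cal,i_naca external L-type Ca2+ and Na+/Ca2+-exchanger
#'   currents, pA/pF.
#' @param ci bulk cytosolic Ca2+ (uM), modulating the slow delayed
#'   rectifier conductance.
#' @param params a [cicr_params()].
#' @return Named list: `dVdt` plus currents `i_na`, `i_k1`, `i_kr`,
#'   `i_ks`, `i_tof`, `i_tos`, `i_nak`.
#' @export
ionic_currents <- function(state, i_cal = 0, i_naca = 0, ci = 0.275,
                           params = cicr_params()) {
  mahajan_currents_cpp(unname(state), .mem_pars(params), i_cal, i_naca, ci)
}

#' Resting potential of the ionic model
#'
#' Voltage at which the total ionic current vanishes with every gate at
#' its steady state (no L-type or stimulus current).
#'
#' @param params a [cicr_params()].
#' @param interval search bracket, mV.
#' @return Resting potential, mV.
#' @export
find_resting_potential <- function(params = cicr_params(),
                                   interval = c(-95, -60)) {
  mp <- .mem_pars(params)
  f <- function(V) {
    y <- mahajan_init_cpp(V, mp)
    mahajan_currents_cpp(y, mp, 0, 0, 0.275)$dVdt
  }
  stats::uniroot(f, interval, tol = 1e-8)$root
}

#' Advance the membrane model
#'
#' Integrates `dV/dt = -(I_ion + I_stim)` and the gate kinetics over
#' `dt` with classical Runge-Kutta sub-steps, holding the externally
#' supplied currents fixed.
#'
#' @param state a [membrane_state()] vector.
#' @param dt step, ms.
#' @param i_cal,i_naca external currents, pA/pF (held constant).
#' @param i_stim stimulus current, pA/pF (negative depolarizes).
#' @param ci bulk cytosolic Ca2+, uM.
#' @param params a [cicr_params()].
#' @param hmax sub-step cap, ms.
#' @return Updated named state vector.
#' @export
membrane_step <- function(state, dt, i_cal = 0, i_naca = 0, i_stim = 0,
                          ci = 0.275, params = cicr_params(),
                          hmax = 0.01) {
  stopifnot(dt > 0)
  y <- mahajan_step_cpp(unname(state), .mem_pars(params), dt, hmax,
                        i_cal, i_naca, i_stim, ci)
  if (abs(y[1]) > 200) {
    stop("membrane potential diverged beyond +/-200 mV")
  }
  names(y) <- c("V", "m", "h", "j", "xr", "xs1", "xs2", "xtos", "ytos",
                "xtof", "ytof")
  y
}

#' Aggregate single-channel LCC currents into the whole-cell current
#'
#' `I_CaL = -2 alpha * sum(I_LCC)` with `alpha = F v_cell / (C_m Omega)`,
#' which converts the summed single-channel amount flux (uM um^3/ms,
#' positive into the cell) into pA/pF and scales the simulated subvolume
#' `Omega` up to the whole cell exactly.
#'
#' @param i_lcc single-channel LCC currents, uM um^3/ms (summed).
#' @param omega simulated volume, um^3.
#' @param params a [cicr_params()].
#' @return Whole-cell L-type current, pA/pF (negative inward).
#' @export
aggregate_ical <- function(i_lcc, omega, params = cicr_params()) {
  ph <- params$physical
  scale <- 2 * (ph$F * 1000) * 1e-18 / (ph$C_m * 1e-6) *
    (ph$v_cell / omega)
  -scale * sum(i_lcc)
}

#' Aggregate NCX fluxes into the whole-cell exchanger current
#'
#' Spatial integral of the bulk exchanger flux plus the plasma-membrane
#' boundary flux, scaled from the simulated subvolume/area to the whole
#' cell:
#' `I_NaCa = (v_cyt F)/(v_cell C_m) [ (v_cell/Omega) int_Omega J dV +
#' (A_cell/Gamma) int_Gamma J_pm dA ]`.
#'
#' @param j_bulk per-cell bulk NCX flux, uM/ms.
#' @param j_pm per-face membrane area flux, uM um/ms (may be empty).
#' @param params a [cicr_params()].
#' @return Whole-cell exchanger current, pA/pF.
#' @export
aggregate_inaca <- function(j_bulk, j_pm = numeric(0),
                            params = cicr_params()) {
  ph <- params$physical
  scale <- ph$v_cyt_frac * (ph$F * 1000) * 1e-18 / (ph$C_m * 1e-6)
  a_cell <- ph$C_m * 1e6 / ph$c_spec
  scale * (ph$v_cell * mean(j_bulk) +
             (if (length(j_pm)) a_cell * mean(j_pm) else 0))
}

#' Prescribed action-potential waveform
#'
#' Replaces the membrane ODE with a prescribed `V(t)` (piecewise-linear
#' interpolation, end values held), so the Ca2+ subsystem can be driven
#' without the ionic model.
#'
#' @param time sample times, ms (strictly increasing).
#' @param voltage voltages, mV.
#' @return An object of class `"ap_waveform"`; callable as a function of
#'   time.
#' @export
prescribed_ap_mode <- function(time, voltage) {
  stopifnot(length(time) == length(voltage), length(time) >= 2,
            all(diff(time) > 0), all(is.finite(voltage)))
  f <- stats::approxfun(time, voltage, rule = 2)
  structure(f, time = time, voltage = voltage, class = "ap_waveform")
}
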