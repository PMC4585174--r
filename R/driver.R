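# Simulation driver: configuration, the coupled hybrid run, protocol
# observables (APD/DI, gain, restitution), and output writers.

#' Simulation configuration
#'
#' Assembles everything a run needs: domain and grid, CRU density, RyR
#' scheme and cleft buffer factor, pacing protocol, tolerances, and
#' parameter overrides. Presets: `"subdomain"` (5 x 5 x 2 um, ~36 CRUs at
#' reference density — the desk-scale workhorse), `"zdisc"` (one full
#' 15 x 15 x 2 um disc, 320 CRUs), `"micro"` (2 x 2 x 2 um, ~6 CRUs, for
#' fast multi-beat protocols).
#'
#' @param preset `"subdomain"`, `"zdisc"`, or `"micro"`.
#' @param ryr_scheme `"stern4"`, `"cannell2"`, or `"walker2"`.
#' @param beta cleft buffer factor; default is the scheme's calibrated
#'   value (1 for the 4-state scheme, 2.5 for the 2-state schemes).
#' @param params a [cicr_params()] (override any table value here).
#' @param domain,grid_h,n_discs,crus_per_disc geometry overrides.
#' @param bcl basic cycle length, ms.
#' @param n_beats number of paced beats.
#' @param stim_start first stimulus time, ms.
#' @param stim_amp stimulus amplitude: the 1 ms current injection that
#'   depolarizes a passive membrane by this many mV (or the direct offset
#'   when `stim_mode = "offset"`).
#' @param stim_dur stimulus duration, ms.
#' @param stim_mode `"current"` or `"offset"`.
#' @param t_end simulated time, ms; default `stim_start + n_beats * bcl`.
#' @param dt_out output-clock interval, ms.
#' @param c0,S0,cjsr0 initial cytosolic, network-SR and junctional-SR
#'   free Ca2+, uM.
#' @param clamp optional [prescribed_ap_mode()] waveform: voltage-clamp
#'   mode (no ionic model).
#' @param closed_system disable SERCA, NCX, stimulus and LCC conduction
#'   (conservation testing).
#' @param rtol,atol,lin_tol,tau_max,jsr_substep numerical controls.
#' @param cap_frac event-batching fraction (the `0.1 N_s` rule).
#' @param force_ns1 force at most one conductance event per step.
#' @param event_log record every conductance-changing event.
#' @param snap_times times (ms) at which to snapshot the 3-D `c` and `S`
#'   fields.
#' @return A list of class `"cicr_config"`.
#' @export
sim_config <- function(preset = c("subdomain", "zdisc", "micro"),
                       ryr_scheme = c("stern4", "cannell2", "walker2"),
                       beta = NULL, params = cicr_params(),
                       domain = NULL, grid_h = 0.25, n_discs = 1,
                       crus_per_disc = NULL,
                       bcl = 350, n_beats = 1, stim_start = 5,
                       stim_amp = 40, stim_dur = 1,
                       stim_mode = c("current", "offset"),
                       t_end = NULL, dt_out = 0.5,
                       c0 = 0.275, S0 = 1000, cjsr0 = 1000,
                       clamp = NULL, closed_system = FALSE,
                       rtol = 1e-4, atol = 1e-2, lin_tol = 1e-6,
                       tau_max = 0.25, jsr_substep = 1e-3,
                       cap_frac = 0.1, force_ns1 = FALSE,
                       event_log = FALSE, snap_times = numeric(0)) {
  preset <- match.arg(preset)
  ryr_scheme <- match.arg(ryr_scheme)
  stim_mode <- match.arg(stim_mode)
  if (is.null(domain)) {
    domain <- switch(preset,
                     subdomain = c(5, 5, 2 * n_discs),
                     zdisc = c(15, 15, 2 * n_discs),
                     micro = c(2, 2, 2 * n_discs))
  }
  if (is.null(beta)) beta <- params$ryr[[ryr_scheme]]$beta
  if (is.null(t_end)) t_end <- stim_start + n_beats * bcl
  cfg <- list(preset = preset, ryr_scheme = ryr_scheme, beta = beta,
              params = params, domain = domain, grid_h = grid_h,
              n_discs = n_discs, crus_per_disc = crus_per_disc,
              bcl = bcl, n_beats = n_beats, stim_start = stim_start,
              stim_amp = stim_amp, stim_dur = stim_dur,
              stim_mode = stim_mode, t_end = t_end, dt_out = dt_out,
              c0 = c0, S0 = S0, cjsr0 = cjsr0, clamp = clamp,
              closed_system = closed_system, rtol = rtol, atol = atol,
              lin_tol = lin_tol, tau_max = tau_max,
              jsr_substep = jsr_substep, cap_frac = cap_frac,
              force_ns1 = force_ns1, event_log = event_log,
              snap_times = snap_times)
  class(cfg) <- "cicr_config"
  cfg
}

#' @export
print.cicr_config <- function(x, ...) {
  cat(sprintf(
    "<cicr_config> %s preset, %s RyRs (beta = %g), %g x %g x %g um,\n  BCL %g ms x %d beat(s), t_end %g ms\n",
    x$preset, x$ryr_scheme, x$beta, x$domain[1], x$domain[2], x$domain[3],
    x$bcl, x$n_beats, x$t_end))
  invisible(x)
}

# pack the RyR scheme constants for the engine (all schemes; id selects)
.ryr_pack <- function(params, scheme) {
  st <- params$ryr$stern4; ca <- params$ryr$cannell2
  wa <- params$ryr$walker2
  list(scheme = match(scheme, c("stern4", "cannell2", "walker2")) - 1L,
       g = params$ryr$g,
       kacmax = st$k_ac_max, kinmax = st$k_in_max, Kac = st$K_ac,
       Kin = st$K_in, kom = st$k_om, kim = st$k_im, Kjsr = st$K_jsr,
       lambda = st$lambda,
       Aopen = ca$A_open, popen = ca$p_open, kopenmax = ca$k_open_max,
       Aclose = ca$A_close, pclose = ca$p_close,
       kclosemax = ca$k_close_max,
       kplus = wa$k_plus, eta = wa$eta, kclose = wa$k_close,
       phib = wa$phi_b, phik = wa$phi_k)
}

.lcc_pack <- function(params) {
  l <- params$lcc
  list(JL = l$J_L, kp0 = l$k_p0, cpbar = l$c_p_bar, taupo = l$tau_po,
       r1 = l$r1, r2 = l$r2, s1p = l$s1p, k1p = l$k1p, k2 = l$k2,
       k21p = l$k21p, Tba = l$T_ba)
}

# initial channel states drawn from the scheme's stationary distribution
# at the initial local conditions (uses R's RNG)
.init_states <- function(geom, coupling, config, V0) {
  params <- config$params
  sc_ryr <- markov_scheme(config$ryr_scheme, params)
  sc_lcc <- markov_scheme("mahajan_lcc7", params)
  n <- length(geom$type)
  st <- integer(n)
  for (i in seq_len(n)) {
    cdi <- coupling$Z[i] * config$c0
    sc <- if (geom$type[i] == "RyR") sc_ryr else sc_lcc
    p <- pmax(steady_state_occupancy(
      sc$generator(cdi, config$cjsr0, V0)), 0)
    st[i] <- sample.int(length(p), 1, prob = p) - 1L
  }
  st
}

#' Run a coupled simulation
#'
#' Samples the CRU population, precomputes every cleft coupling matrix,
#' initializes channel states from their stationary distributions, and
#' runs the hybrid deterministic/stochastic time-stepping engine over the
#' configured protocol.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; drives both the population sampling and the
#'   gating stream (same seed, same trajectory).
#' @return An object of class `"cicr_sim"`: `traces` (tibble on the
#'   uniform output clock), `population`, `config`, `metadata` (resolved
#'   defaults: beta, seed, calsequestrin constants, initial SR load),
#'   `max_kopen` (largest RyR opening rate encountered, ms^-1),
#'   `fields` (final concentration fields), `events` (if logged),
#'   `snapshots`, and engine diagnostics.
#' @export
run_simulation <- function(config, seed = 1) {
  stopifnot(inherits(config, "cicr_config"))
  params <- config$params
  set.seed(seed)
  grid <- grid_spec(config$domain, config$grid_h)
  pop <- sample_cru_population(config$domain, config$n_discs,
                               config$crus_per_disc, params = params)
  cc <- grid_cell_centers(grid)
  V0 <- if (!is.null(config$clamp)) config$clamp(0)
        else find_resting_potential(params)
  ph <- params$physical

  fnaca <- rep(params$ncx$f_low, grid$n_cell)
  crus_packed <- vector("list", length(pop))
  for (k in seq_along(pop)) {
    cru <- pop[[k]]
    coup <- assemble_coupling(cru$geom, D_c = params$buffers$D_ca,
                              beta = config$beta,
                              phi0 = params$cleft$phi0,
                              kappa = params$cleft$kappa)
    d2 <- (cc$x - cru$center[1])^2 + (cc$y - cru$center[2])^2 +
      (cc$z - cru$center[3])^2
    src <- which(d2 <= cru$R_cru^2)
    if (!length(src)) src <- which.min(d2)
    rim <- which(d2 <= (cru$R_cru + grid$h)^2)
    if (!length(rim)) rim <- which.min(d2)
    fnaca[src] <- params$ncx$f_high
    g <- ifelse(cru$geom$type == "RyR", params$ryr$g, params$lcc$J_L)
    crus_packed[[k]] <- list(
      eta = coup$eta, Z = coup$Z, g = g,
      is_ryr = as.integer(cru$geom$type == "RyR"),
      states0 = .init_states(cru$geom, coup, config, V0),
      src_cells = as.integer(src - 1L),
      rim_cells = as.integer(rim - 1L),
      center_cell = as.integer(which.min(d2) - 1L),
      v_jsr = cru$v_jsr, cjsr0 = config$cjsr0)
  }

  fields <- init_fields(grid, params, config$c0, config$S0)
  closed <- isTRUE(config$closed_system)
  pde_pars <- .pack_pde(grid, params, fnaca,
                        pump = !closed, ncx = !closed, pm_flux = !closed)
  mem <- list(pars = .mem_pars(params),
              y0 = unname(membrane_state(V0, params)),
              clamp = !is.null(config$clamp),
              wave_t = if (!is.null(config$clamp))
                attr(config$clamp, "time") else numeric(0),
              wave_v = if (!is.null(config$clamp))
                attr(config$clamp, "voltage") else numeric(0))
  stim_times <- if (closed) numeric(0)
    else config$stim_start + config$bcl * (seq_len(config$n_beats) - 1)
  protocol <- list(stim_times = stim_times,
                   stim_amp = config$stim_amp / max(config$stim_dur, 1e-9),
                   stim_dur = config$stim_dur,
                   t_end = config$t_end, dt_out = config$dt_out,
                   snap_times = config$snap_times)
  if (config$stim_mode == "offset") protocol$stim_amp <- config$stim_amp
  omega <- prod(config$domain)
  a_cell <- ph$C_m * 1e6 / ph$c_spec
  numerics <- list(
    seed = as.double(seed), rtol = config$rtol, atol = config$atol,
    lin_tol = config$lin_tol, tau_max = config$tau_max, tau_min = 1e-7,
    tau0 = 0.01, cap_frac = config$cap_frac,
    force_ns1 = isTRUE(config$force_ns1),
    jsr_substep = config$jsr_substep,
    tau_refill = params$jsr$tau_refill,
    n_csqn = params$jsr$n_csqn, B_csqn = params$jsr$B_csqn,
    K_csqn = params$jsr$K_csqn,
    no_lcc = closed, event_log = isTRUE(config$event_log),
    kd_fluo = params$buffers$fluo$k_off / params$buffers$fluo$k_on,
    fmax_fluo = params$buffers$fluo$total,
    ical_scale = 2 * (ph$F * 1000) * 1e-18 / (ph$C_m * 1e-6) *
      (ph$v_cell / omega),
    inaca_scale = ph$v_cyt_frac * (ph$F * 1000) * 1e-18 /
      (ph$C_m * 1e-6),
    vcell = ph$v_cell, acell = a_cell, omega = omega,
    vcyt_frac = ph$v_cyt_frac, vsr_frac = ph$v_sr_frac,
    delta = .delta_2frt(ph), c_ext = ph$c_ext,
    mem_hmax = 0.01,
    stim_mode = if (config$stim_mode == "offset") 1L else 0L)

  out <- run_engine_cpp(.fields_to_vec(fields),
                        c(grid$nx, grid$ny, grid$nz), grid$h,
                        pde_pars, crus_packed, .ryr_pack(params,
                        config$ryr_scheme), .lcc_pack(params),
                        mem, protocol, numerics)

  traces <- tibble::as_tibble(as.data.frame(out$traces))
  md <- list(seed = seed, beta = config$beta,
             ryr_scheme = config$ryr_scheme,
             g_ryr_um3_per_ms = params$ryr$g,
             calsequestrin = params$jsr[c("n_csqn", "B_csqn", "K_csqn")],
             S0 = config$S0, cjsr0 = config$cjsr0,
             apd_criterion = "APD90",
             n_cru = length(pop),
             n_ryr = sum(vapply(pop, function(u) u$n_ryr, numeric(1))),
             n_lcc = sum(vapply(pop, function(u) u$n_lcc, numeric(1))),
             v_rest = V0, omega = omega)
  res <- list(traces = traces, population = pop, config = config,
              metadata = md, max_kopen = out$max_kopen,
              fields = .vec_to_fields(out$y, grid), grid = grid,
              cjsr = as.numeric(out$cjsr),
              events = if (isTRUE(config$event_log))
                tibble::as_tibble(out$events) else NULL,
              snapshots = if (length(config$snap_times))
                list(times = config$snap_times, c = out$snap_c,
                     S = out$snap_S) else NULL,
              diagnostics = list(n_steps = out$n_steps,
                                 n_rejects = out$n_rejects,
                                 n_lin_it = out$n_lin_it,
                                 timing = out$timing))
  class(res) <- "cicr_sim"
  res
}

#' @export
print.cicr_sim <- function(x, ...) {
  cat(sprintf(
    "<cicr_sim> %s / %s, %d CRUs, %.0f ms simulated (%d steps)\n",
    x$config$preset, x$config$ryr_scheme, length(x$population),
    max(x$traces$t), as.integer(x$diagnostics$n_steps)))
  cat(sprintf("  peak [Ca]_i %.3f uM, max RyR open %.1f%%\n",
              max(x$traces$c_avg), 100 * max(x$traces$frac_ryr_open)))
  invisible(x)
}

#' Stochastic time step from the event-batching rule
#'
#' Given per-CRU first-event times within the deterministic window, the
#' stochastic step is the time by which at most `ceiling(cap_frac * N_s)`
#' conductance-changing events have occurred, where `N_s` counts CRUs
#' with an event in the window; without events the full window is used.
#'
#' @param tau_i per-CRU event times (CRUs without an event carry
#'   `tau_det`).
#' @param tau_det deterministic window, ms.
#' @param cap_frac batching fraction.
#' @return `tau_stoc` (ms).
#' @export
select_stochastic_timestep <- function(tau_i, tau_det, cap_frac = 0.1) {
  stopifnot(all(tau_i <= tau_det + 1e-12))
  ev <- sort(tau_i[tau_i < tau_det])
  if (!length(ev)) return(tau_det)
  k <- min(max(1L, ceiling(cap_frac * length(ev))), length(ev))
  ev[k]
}

#' Fluorescence-calibrated calcium estimate
#'
#' Converts bound indicator (Ca2+-bound Fluo-4) to an apparent free
#' calcium via the in-vitro calibration
#' `K_d (F - F_min)/(F_max - F)` with `F_min = 0` and `F_max` the total
#' indicator concentration.
#'
#' @param F bound indicator, uM (`0 <= F <= F_max`).
#' @param params a [cicr_params()].
#' @return Apparent `[Ca2+]`, uM (`Inf` with a warning at saturation).
#' @export
fluo4_readout <- function(F, params = cicr_params()) {
  fl <- params$buffers$fluo
  f_max <- fl$total
  stopifnot(all(F >= 0), all(F <= f_max + 1e-9))
  kd <- fl$k_off / fl$k_on
  out <- ifelse(F >= f_max, Inf, kd * F / (f_max - F))
  if (any(!is.finite(out))) warning("Fluo-4 saturated; readout infinite")
  out
}

#' Excitation-contraction coupling gain
#'
#' Ratio of time-integrated RyR release flux to time-integrated LCC
#' trigger influx over a window (trapezoidal integration on the output
#' clock).
#'
#' @param time sample times, ms.
#' @param j_rel,j_ca release and trigger flux traces, uM/ms.
#' @param window numeric length-2 `(t0, t1)`, ms.
#' @return Gain (dimensionless); `NA` with a warning when the trigger
#'   integral vanishes.
#' @export
compute_gain <- function(time, j_rel, j_ca, window = range(time)) {
  stopifnot(length(time) == length(j_rel), length(time) == length(j_ca))
  keep <- time >= window[1] & time <= window[2]
  tt <- time[keep]
  if (length(tt) < 2) return(NA_real_)
  trap <- function(y) sum(diff(tt) * (head(y, -1) + tail(y, -1)) / 2)
  den <- trap(j_ca[keep])
  if (abs(den) < 1e-300) {
    warning("zero trigger influx in window; gain undefined")
    return(NA_real_)
  }
  trap(j_rel[keep]) / den
}

#' Action-potential duration and diastolic interval per beat
#'
#' APD is measured by a percent-repolarization criterion (default
#' APD90): from stimulus onset to the time the falling voltage crosses
#' `peak - frac * (peak - baseline)`, with the baseline taken just
#' before the stimulus. `DI = BCL - APD`.
#'
#' @param time,V voltage trace on the output clock.
#' @param stim_times stimulus onsets, ms.
#' @param bcl basic cycle length, ms.
#' @param frac repolarization fraction (0.9 = APD90).
#' @return Tibble with one row per beat: `beat`, `apd`, `di`,
#'   `repolarized`.
#' @export
compute_apd_di <- function(time, V, stim_times, bcl, frac = 0.9) {
  out <- lapply(seq_along(stim_times), function(b) {
    t0 <- stim_times[b]
    t1 <- if (b < length(stim_times)) stim_times[b + 1] else max(time) + 1
    pre <- which(time < t0)
    base <- if (length(pre)) V[max(pre)] else V[1]
    inbeat <- which(time >= t0 & time < t1)
    if (length(inbeat) < 3) {
      return(tibble::tibble(beat = b, apd = NA_real_, di = NA_real_,
                            repolarized = FALSE))
    }
    tv <- time[inbeat]; vv <- V[inbeat]
    ipk <- which.max(vv)
    thr <- vv[ipk] - frac * (vv[ipk] - base)
    below <- which(vv <= thr & seq_along(vv) > ipk)
    if (!length(below)) {
      return(tibble::tibble(beat = b, apd = NA_real_, di = NA_real_,
                            repolarized = FALSE))
    }
    i2 <- below[1]; i1 <- i2 - 1
    tc <- tv[i1] + (thr - vv[i1]) / (vv[i2] - vv[i1]) * (tv[i2] - tv[i1])
    apd <- tc - t0
    tibble::tibble(beat = b, apd = apd, di = bcl - apd,
                   repolarized = TRUE)
  })
  do.call(rbind, out)
}

#' Constant-BCL restitution protocol
#'
#' Paces the model at each cycle length, discards conditioning beats,
#' and reports APD and DI per retained beat.
#'
#' @param config a [sim_config()]; its `bcl`, `n_beats` and `t_end` are
#'   overridden per run.
#' @param bcls cycle lengths, ms.
#' @param n_beats beats per cycle length.
#' @param discard conditioning beats to drop.
#' @param seed integer seed (one independent run per BCL).
#' @return Tibble: `bcl`, `beat`, `apd`, `di`.
#' @export
restitution_protocol <- function(config, bcls = c(350, 300, 250),
                                 n_beats = 2, discard = 1, seed = 1) {
  stopifnot(n_beats > discard)
  out <- lapply(seq_along(bcls), function(i) {
    cfg <- config
    cfg$bcl <- bcls[i]
    cfg$n_beats <- n_beats
    cfg$t_end <- cfg$stim_start + n_beats * bcls[i]
    sim <- run_simulation(cfg, seed = seed + (i - 1))
    st <- cfg$stim_start + bcls[i] * (seq_len(n_beats) - 1)
    apd <- compute_apd_di(sim$traces$t, sim$traces$V, st, bcls[i])
    apd <- apd[apd$beat > discard, , drop = FALSE]
    apd$bcl <- bcls[i]
    apd[, c("bcl", "beat", "apd", "di")]
  })
  do.call(rbind, out)
}

# legacy-ASCII VTK writer for a scalar field on the structured grid
.write_vtk <- function(field, grid, path, name = "ca") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "cicrsim field snapshot", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", grid$nx, grid$ny, grid$nz),
               sprintf("ORIGIN %g %g %g", grid$h / 2, grid$h / 2,
                       grid$h / 2),
               sprintf("SPACING %g %g %g", grid$h, grid$h, grid$h),
               sprintf("POINT_DATA %d", grid$n_cell),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(field, digits = 9, trim = TRUE, scientific = TRUE),
             con)
  invisible(path)
}

#' Write run outputs
#'
#' Writes the time-series traces (CSV), the resolved configuration and
#' metadata with a configuration hash (JSON), final concentration fields
#' (legacy-ASCII VTK, one file per field), field snapshots if recorded,
#' and the event log if present.
#'
#' @param sim a [run_simulation()] result.
#' @param dir output directory (created if missing).
#' @return Invisibly, the vector of files written.
#' @export
write_outputs <- function(sim, dir) {
  stopifnot(inherits(sim, "cicr_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  cfg <- sim$config
  cfg$params <- unclass(cfg$params)
  cfg$clamp <- if (!is.null(cfg$clamp))
    list(time = attr(cfg$clamp, "time"),
         voltage = attr(cfg$clamp, "voltage")) else NULL
  cfg_json <- jsonlite::toJSON(list(config = unclass(cfg),
                                    metadata = sim$metadata),
                               digits = NA, auto_unbox = TRUE,
                               null = "null")
  tf <- tempfile(); writeLines(cfg_json, tf)
  hash <- unname(tools::md5sum(tf)); unlink(tf)

  p <- file.path(dir, "traces.csv")
  tr <- sim$traces
  utils::write.csv(tr, p, row.names = FALSE)
  files <- c(files, p)
  p <- file.path(dir, "config.json")
  full <- jsonlite::toJSON(list(config = unclass(cfg),
                                metadata = sim$metadata,
                                config_hash = hash),
                           digits = NA, auto_unbox = TRUE, null = "null")
  writeLines(full, p)
  files <- c(files, p)
  for (f in c("c", "S")) {
    p <- file.path(dir, sprintf("field_%s.vtk", f))
    .write_vtk(sim$fields[[f]], sim$grid, p, name = f)
    files <- c(files, p)
  }
  # reproducible geometry: the full CRU population, clefts included
  pop_json <- lapply(sim$population, function(u)
    list(id = u$id, center = u$center, n_ryr = u$n_ryr, n_lcc = u$n_lcc,
         v_jsr = u$v_jsr, R_cru = u$R_cru, R_jsr = u$R_jsr,
         cleft = unclass(u$geom)))
  p <- file.path(dir, "population.json")
  writeLines(jsonlite::toJSON(pop_json, digits = NA, auto_unbox = TRUE), p)
  files <- c(files, p)
  if (!is.null(sim$snapshots)) {
    for (k in seq_along(sim$snapshots$times)) {
      p <- file.path(dir, sprintf("snap_c_%04.0fms.vtk",
                                  sim$snapshots$times[k]))
      .write_vtk(sim$snapshots$c[, k], sim$grid, p, name = "c")
      files <- c(files, p)
    }
  }
  if (!is.null(sim$events)) {
    p <- file.path(dir, "events.csv")
    utils::write.csv(sim$events, p, row.names = FALSE)
    files <- c(files, p)
  }
  manifest <- file.path(dir, "manifest.json")
  writeLines(jsonlite::toJSON(list(files = basename(files),
                                   config_hash = hash),
                              auto_unbox = TRUE), manifest)
  invisible(c(files, manifest))
}
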