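#' Structured simulation grid
#'
#' Cell-centered finite-volume grid over a box `[0, L1] x [0, L2] x
#' [0, L3]`. Faces tagged as plasma membrane carry the NCX boundary flux
#' of the cytosolic Ca2+ field; all other boundaries are no-flux.
#'
#' @param L numeric length-3 domain extents, um.
#' @param h cell spacing, um (must divide all extents).
#' @param membrane axes whose two bounding faces are plasma membrane
#'   (subset of `c("x", "y", "z")`).
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(L = c(5, 5, 2), h = 0.25, membrane = c("x", "y")) {
  stopifnot(length(L) == 3, h > 0, all(membrane %in% c("x", "y", "z")))
  n <- round(L / h)
  if (max(abs(n * h - L)) > 1e-9) stop("h must divide the domain extents")
  if (any(n < 1)) stop("empty grid")
  structure(list(nx = n[1], ny = n[2], nz = n[3], h = h, L = L,
                 n_cell = prod(n), membrane = membrane),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d cells, h = %g um (%g x %g x %g um)\n",
              x$nx, x$ny, x$nz, x$h, x$L[1], x$L[2], x$L[3]))
  invisible(x)
}

#' @rdname grid_spec
#' @param grid a `grid_spec`.
#' @return `grid_cell_centers()`: data frame of cell-center coordinates
#'   in grid storage order (x fastest).
#' @export
grid_cell_centers <- function(grid) {
  ix <- seq_len(grid$nx) - 0.5
  iy <- seq_len(grid$ny) - 0.5
  iz <- seq_len(grid$nz) - 0.5
  g <- expand.grid(x = ix * grid$h, y = iy * grid$h, z = iz * grid$h)
  g
}

# number of membrane faces adjoining each cell
.membrane_faces <- function(grid) {
  m <- integer(grid$n_cell)
  arr <- array(0L, c(grid$nx, grid$ny, grid$nz))
  if ("x" %in% grid$membrane) {
    arr[1, , ] <- arr[1, , ] + 1L; arr[grid$nx, , ] <- arr[grid$nx, , ] + 1L
  }
  if ("y" %in% grid$membrane) {
    arr[, 1, ] <- arr[, 1, ] + 1L; arr[, grid$ny, ] <- arr[, grid$ny, ] + 1L
  }
  if ("z" %in% grid$membrane) {
    arr[, , 1] <- arr[, , 1] + 1L; arr[, , grid$nz] <- arr[, , grid$nz] + 1L
  }
  as.integer(arr)
}

#' Initialize concentration fields
#'
#' Cytosolic free Ca2+ at `c0` with every buffer at binding equilibrium,
#' network-SR Ca2+ at `S0` with the SR buffer at equilibrium.
#'
#' @param grid a [grid_spec()].
#' @param params a [cicr_params()].
#' @param c0 initial cytosolic free Ca2+, uM.
#' @param S0 initial network-SR free Ca2+, uM.
#' @return Named list of per-cell vectors: `c`, `b_tnc`, `b_cam`,
#'   `b_fluo`, `S`, `B_sr`, with class `"concentration_fields"`.
#' @export
init_fields <- function(grid, params = cicr_params(), c0 = 0.275,
                        S0 = 1000) {
  eq <- function(b, c) b$total * c / (b$k_off / b$k_on + c)
  bp <- params$buffers
  n <- grid$n_cell
  structure(list(
    c = rep(c0, n),
    b_tnc = rep(eq(bp$tnc, c0), n),
    b_cam = rep(eq(bp$cam, c0), n),
    b_fluo = rep(eq(bp$fluo, c0), n),
    S = rep(S0, n),
    B_sr = rep(eq(bp$sr, S0), n)
  ), class = "concentration_fields")
}

#' Buffer reaction rate
#'
#' Mass-action binding rate `R = k_on (b_tot - b) c - k_off b` (uM/ms);
#' positive when calcium is binding.
#'
#' @param c free Ca2+, uM.
#' @param b bound-buffer concentration, uM (`0 <= b <= b_tot`).
#' @param buffer a buffer block of [cicr_params()] (`total`, `k_on`,
#'   `k_off`).
#' @return Binding rate, uM/ms.
#' @export
buffer_reaction <- function(c, b, buffer) {
  stopifnot(all(b >= -1e-12), all(b <= buffer$total + 1e-9))
  buffer$k_on * (buffer$total - b) * c - buffer$k_off * b
}

#' SERCA uptake flux
#'
#' Hill-2 pump flux `V_max c^2 / (K_p^2 + c^2)`, a sink for cytosolic
#' Ca2+ and (scaled by the cytosol:SR volume ratio) a source for the SR.
#'
#' @param c cytosolic free Ca2+, uM.
#' @param params the `pump` block of [cicr_params()].
#' @return Flux, uM/ms.
#' @export
pump_flux <- function(c, params = cicr_params()$pump) {
  stopifnot(all(c >= 0))
  params$v_max * c^2 / (params$K_p^2 + c^2)
}

#' Na+/Ca2+-exchanger flux
#'
#' Voltage- and concentration-dependent exchanger flux (positive = Ca2+
#' entry, i.e. reverse mode), with allosteric cytosolic Ca2+ activation,
#' multiplied by the position-dependent density factor: `f_high` within
#' one source radius of a CRU center, `f_low` elsewhere in the bulk,
#' `f_surf` on the plasma membrane.
#'
#' @param c local cytosolic free Ca2+, uM (> 0).
#' @param V membrane potential, mV.
#' @param position `"near"` (CRU-adjacent), `"bulk"`, or `"surface"`.
#' @param params the `ncx` block of [cicr_params()].
#' @param physical the `physical` block of [cicr_params()].
#' @return Flux, uM/ms.
#' @export
ncx_flux <- function(c, V, position = c("bulk", "near", "surface"),
                     params = cicr_params()$ncx,
                     physical = cicr_params()$physical) {
  stopifnot(all(c > 0))
  position <- match.arg(position)
  f <- switch(position, near = params$f_high, bulk = params$f_low,
              surface = params$f_surf)
  frt <- .frt(physical)
  csm <- c * 1e-3                       # uM -> mM
  cao <- physical$c_ext * 1e-3
  nai <- params$nai; nao <- physical$na_o
  ea <- exp(params$xi * V * frt)
  eb <- exp((params$xi - 1) * V * frt)
  num <- nai^3 * cao * ea - nao^3 * csm * eb
  den <- (1 + params$k_sat * eb) *
    (params$K_m_cao * nai^3 + params$K_m_nao^3 * csm +
       params$K_m_nai^3 * cao * (1 + csm / params$K_m_cai) +
       params$K_m_cai * nao^3 * (1 + (nai / params$K_m_nai)^3) +
       nai^3 * cao + nao^3 * csm)
  allo <- 1 / (1 + (params$c_naca / c)^3)
  f * params$g_naca * allo * num / den
}

# discrete no-flux Laplacian of a per-cell vector (R reference)
.laplacian <- function(u, grid) {
  a <- array(u, c(grid$nx, grid$ny, grid$nz))
  out <- array(0, dim(a))
  shift <- function(a, d, axis) {
    idx <- rep(list(quote(expr = )), 3)
    n <- dim(a)[axis]
    src <- pmin(pmax(seq_len(n) + d, 1L), n)   # mirror = no-flux ghost
    idx[[axis]] <- src
    do.call(`[`, c(list(a), idx, list(drop = FALSE)))
  }
  for (axis in 1:3) {
    out <- out + shift(a, 1L, axis) + shift(a, -1L, axis) - 2 * a
  }
  as.numeric(out) / grid$h^2
}

#' Right-hand side of the bulk reaction-diffusion system
#'
#' Assembles the time derivatives of all six bulk fields: diffusion with
#' no-flux boundaries (plus the NCX flux of `c` through membrane faces),
#' buffer reactions, SERCA uptake (sink in `c`, volume-scaled source in
#' `S`), bulk NCX, CRU release sources, and the jSR refill sink. This is
#' the reference implementation used for verification; the time stepper
#' ([pde_step()]) evaluates an equivalent compiled form.
#'
#' @param fields a [init_fields()] list.
#' @param grid a [grid_spec()].
#' @param params a [cicr_params()].
#' @param V membrane potential, mV (for NCX).
#' @param j_cru CRU source field (uM/ms), or `NULL`.
#' @param j_jsr jSR refill sink field on `S` (uM/ms), or `NULL`.
#' @param fnaca per-cell NCX density factor; default `f_low` everywhere.
#' @param pump,ncx,pm_flux logical switches (SERCA, bulk NCX, membrane
#'   NCX flux).
#' @return Named list of derivative vectors (uM/ms).
#' @export
pde_rhs <- function(fields, grid, params = cicr_params(), V = -87,
                    j_cru = NULL, j_jsr = NULL, fnaca = NULL,
                    pump = TRUE, ncx = TRUE, pm_flux = TRUE) {
  bp <- params$buffers
  R_tnc <- buffer_reaction(fields$c, fields$b_tnc, bp$tnc)
  R_cam <- buffer_reaction(fields$c, fields$b_cam, bp$cam)
  R_fluo <- buffer_reaction(fields$c, fields$b_fluo, bp$fluo)
  R_sr <- buffer_reaction(fields$S, fields$B_sr, bp$sr)
  jp <- if (pump) pump_flux(fields$c, params$pump) else 0
  jn <- 0
  if (ncx) {
    if (is.null(fnaca)) fnaca <- rep(params$ncx$f_low, grid$n_cell)
    base <- ncx_flux(pmax(fields$c, 1e-6), V, "bulk",
                     params$ncx, params$physical) / params$ncx$f_low
    jn <- fnaca * base
  }
  dc <- bp$D_ca * .laplacian(fields$c, grid) + jn - jp -
    (R_tnc + R_cam + R_fluo)
  if (!is.null(j_cru)) dc <- dc + j_cru
  if (pm_flux) {
    mf <- .membrane_faces(grid)
    if (any(mf > 0)) {
      a_cell <- params$physical$C_m * 1e6 / params$physical$c_spec
      depth <- params$physical$v_cell / a_cell
      jpm <- params$ncx$f_surf *
        ncx_flux(pmax(fields$c, 1e-6), V, "bulk", params$ncx,
                 params$physical) / params$ncx$f_low * depth
      dc <- dc + mf * jpm / grid$h
    }
  }
  dS <- bp$D_sr * .laplacian(fields$S, grid) - R_sr +
    params$physical$v_cyt_frac / params$physical$v_sr_frac * jp
  if (!is.null(j_jsr)) dS <- dS - j_jsr
  list(
    c = dc,
    b_tnc = bp$tnc$D * .laplacian(fields$b_tnc, grid) + R_tnc,
    b_cam = bp$cam$D * .laplacian(fields$b_cam, grid) + R_cam,
    b_fluo = bp$fluo$D * .laplacian(fields$b_fluo, grid) + R_fluo,
    S = dS,
    B_sr = bp$sr$D * .laplacian(fields$B_sr, grid) + R_sr
  )
}

# flatten parameter blocks for the compiled PDE kernel
.pack_pde <- function(grid, params, fnaca = NULL,
                      pump = TRUE, ncx = TRUE, pm_flux = TRUE) {
  bp <- params$buffers
  ph <- params$physical
  if (is.null(fnaca)) fnaca <- rep(params$ncx$f_low, grid$n_cell)
  a_cell <- ph$C_m * 1e6 / ph$c_spec   # pF / (pF/um^2) = um^2
  list(
    D = c(bp$D_ca, bp$tnc$D, bp$cam$D, bp$fluo$D, bp$D_sr, bp$sr$D),
    kon = c(bp$tnc$k_on, bp$cam$k_on, bp$fluo$k_on),
    koff = c(bp$tnc$k_off, bp$cam$k_off, bp$fluo$k_off),
    btot = c(bp$tnc$total, bp$cam$total, bp$fluo$total),
    ksr_on = bp$sr$k_on, ksr_off = bp$sr$k_off, bsr_tot = bp$sr$total,
    pump_vmax = params$pump$v_max, pump_kp = params$pump$K_p,
    pump_on = as.integer(pump),
    ncx_on = as.integer(ncx), pm_on = as.integer(pm_flux),
    g_naca = params$ncx$g_naca, k_sat = params$ncx$k_sat,
    xi = params$ncx$xi,
    kmnai = params$ncx$K_m_nai, kmnao = params$ncx$K_m_nao,
    kmcai = params$ncx$K_m_cai, kmcao = params$ncx$K_m_cao,
    c_naca = params$ncx$c_naca, nai = params$ncx$nai,
    cao = ph$c_ext * 1e-3, nao = ph$na_o,
    frt = .frt(ph),
    f_cell = as.numeric(fnaca), f_low = params$ncx$f_low,
    f_surf = params$ncx$f_surf,
    depth = ph$v_cell / a_cell,
    memb = .membrane_faces(grid),
    vcyt_over_vsr = ph$v_cyt_frac / ph$v_sr_frac
  )
}

# fields list <-> flat state vector (order: c, b_tnc, b_cam, b_fluo, S, B_sr)
.fields_to_vec <- function(fields) {
  c(fields$c, fields$b_tnc, fields$b_cam, fields$b_fluo, fields$S,
    fields$B_sr)
}
.vec_to_fields <- function(y, grid) {
  n <- grid$n_cell
  structure(list(c = y[1:n], b_tnc = y[n + 1:n], b_cam = y[2 * n + 1:n],
                 b_fluo = y[3 * n + 1:n], S = y[4 * n + 1:n],
                 B_sr = y[5 * n + 1:n]),
            class = "concentration_fields")
}

#' Linearly-implicit adaptive PDE step
#'
#' Advances the semi-discretized bulk system by one step of a two-stage
#' L-stable second-order Rosenbrock scheme with an embedded first-order
#' error estimate; the stage systems are solved matrix-free by BiCGSTAB
#' (relative tolerance `lin_tol`) with a per-cell block-Jacobi
#' preconditioner. The accepted step may be smaller than the proposal.
#'
#' @param fields a [init_fields()] list.
#' @param grid a [grid_spec()].
#' @param params a [cicr_params()].
#' @param dt proposed step, ms.
#' @param V membrane potential (for NCX), mV.
#' @param j_cru,j_jsr frozen source/sink fields (uM/ms), or `NULL`.
#' @param fnaca per-cell NCX factor or `NULL`.
#' @param rtol,atol step-control tolerances (weighted RMS norm).
#' @param lin_tol linear-solver relative tolerance.
#' @param adaptive if `FALSE`, take exactly `dt` regardless of the error
#'   estimate (used for convergence studies).
#' @param pump,ncx,pm_flux physics switches as in [pde_rhs()].
#' @return List: `fields` (advanced), `dt_accepted`, `dt_next`
#'   (controller suggestion), `err` (weighted error of the accepted
#'   step), `n_reject`.
#' @export
pde_step <- function(fields, grid, params = cicr_params(), dt,
                     V = -87, j_cru = NULL, j_jsr = NULL, fnaca = NULL,
                     rtol = 1e-4, atol = 1e-2, lin_tol = 1e-6,
                     adaptive = TRUE, pump = TRUE, ncx = TRUE,
                     pm_flux = TRUE) {
  stopifnot(dt > 0)
  pars <- .pack_pde(grid, params, fnaca, pump, ncx, pm_flux)
  n <- grid$n_cell
  if (is.null(j_cru)) j_cru <- numeric(n)
  if (is.null(j_jsr)) j_jsr <- numeric(n)
  out <- pde_step_cpp(.fields_to_vec(fields),
                      c(grid$nx, grid$ny, grid$nz), grid$h, pars,
                      j_cru, j_jsr, V, dt, rtol, atol, lin_tol,
                      as.logical(adaptive))
  if (out$dt_accepted <= 0) {
    stop("pde_step(): step-size underflow below minimum step; ",
         "the system appears unstable at this resolution")
  }
  list(fields = .vec_to_fields(out$y, grid),
       dt_accepted = out$dt_accepted, dt_next = out$dt_next,
       err = out$err, n_reject = out$n_reject)
}
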