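#' Place channels in a cleft
#'
#' RyRs occupy a regular square lattice (pitch `pitch`) on the junctional
#' SR face, filled outward from the cylinder axis; LCCs occupy the
#' interleaved (half-pitch offset) lattice on the T-tubule face. The
#' cylinder radius is the outermost channel distance plus the rim margin.
#'
#' @param n_ryr,n_lcc channel counts (`n_ryr >= 1`, `n_lcc >= 0`).
#' @param pitch lattice pitch, nm.
#' @param margin rim margin, nm.
#' @param height cleft height, nm.
#' @param a_ch mouth regularization radius, nm.
#' @return A [cleft_geometry()].
#' @export
place_channels <- function(n_ryr, n_lcc, pitch = 30, margin = 60,
                           height = 15, a_ch = 1.5) {
  stopifnot(n_ryr >= 1, n_lcc >= 0)
  lattice_sites <- function(n, offset) {
    m <- ceiling(sqrt(n)) + 2L
    g <- seq(-m, m) * pitch + offset
    sites <- expand.grid(x = g, y = g)
    sites <- sites[order(sites$x^2 + sites$y^2, sites$x, sites$y), ]
    sites[seq_len(n), , drop = FALSE]
  }
  ry <- lattice_sites(n_ryr, 0)
  x <- ry$x; y <- ry$y; type <- rep("RyR", n_ryr)
  if (n_lcc > 0) {
    lc <- lattice_sites(n_lcc, pitch / 2)
    x <- c(x, lc$x); y <- c(y, lc$y)
    type <- c(type, rep("LCC", n_lcc))
  }
  cleft_geometry(x, y, type, radius = max(sqrt(x^2 + y^2)) + margin,
                 height = height, margin = margin, a_ch = a_ch)
}

#' Sample a CRU population
#'
#' Draws the calcium-release-unit population for a simulated subvolume:
#' RyR counts are exponential with the configured mean (rounded up to at
#' least 1), LCC counts follow the 4:1 RyR:LCC ratio, CRU centers sit on
#' z-disc planes (spacing 2 um) on a jittered square lattice in the
#' cross-section, and the aggregate junctional-SR volume fraction of the
#' subvolume is apportioned to CRUs proportionally to their RyR counts.
#' Uses R's RNG (`set.seed()` makes populations reproducible).
#'
#' @param domain numeric length-3, subvolume extents (um).
#' @param n_discs number of z-discs; must fit in `domain[3]` at 2 um
#'   spacing.
#' @param crus_per_disc CRUs per disc; default preserves the reference
#'   density of 320 per 15 x 15 um disc.
#' @param mean_ryr mean RyRs per CRU.
#' @param ryr_lcc_ratio RyR:LCC ratio.
#' @param params a [cicr_params()] list.
#' @return A list of class `"cru_population"`; each element has `id`,
#'   `center` (um), `geom` ([cleft_geometry()]), `n_ryr`, `n_lcc`,
#'   `v_jsr` (um^3), `R_cru`, `R_jsr` (um).
#' @export
sample_cru_population <- function(domain = c(5, 5, 2), n_discs = 1,
                                  crus_per_disc = NULL, mean_ryr = 50,
                                  ryr_lcc_ratio = 4,
                                  params = cicr_params()) {
  stopifnot(n_discs >= 1, length(domain) == 3, all(domain > 0))
  spacing <- 2
  if (n_discs * spacing > domain[3] + 1e-9) {
    stop("domain too short for ", n_discs, " z-discs at ", spacing,
         " um spacing")
  }
  if (is.null(crus_per_disc)) {
    crus_per_disc <- max(1L, round(320 * domain[1] * domain[2] / 225))
  }
  n_tot <- n_discs * crus_per_disc
  n_ryr <- pmax(1L, as.integer(round(stats::rexp(n_tot, 1 / mean_ryr))))
  n_lcc <- pmax(1L, as.integer(round(n_ryr / ryr_lcc_ratio)))
  v_jsr_tot <- params$physical$v_jsr_frac * prod(domain)
  v_jsr <- v_jsr_tot * n_ryr / sum(n_ryr)
  crus <- vector("list", n_tot)
  k <- 0L
  for (d in seq_len(n_discs)) {
    z <- (d - 0.5) * spacing
    m <- ceiling(sqrt(crus_per_disc))
    px <- domain[1] / m; py <- domain[2] / m
    sites <- expand.grid(ix = seq_len(m) - 0.5, iy = seq_len(m) - 0.5)
    sites <- sites[sample.int(nrow(sites), crus_per_disc), , drop = FALSE]
    cx <- sites$ix * px + stats::runif(crus_per_disc, -0.3, 0.3) * px
    cy <- sites$iy * py + stats::runif(crus_per_disc, -0.3, 0.3) * py
    for (i in seq_len(crus_per_disc)) {
      k <- k + 1L
      geom <- place_channels(n_ryr[k], n_lcc[k],
                             pitch = params$cleft$pitch,
                             margin = params$cleft$margin,
                             height = params$cleft$height,
                             a_ch = params$cleft$a_ch)
      R_cru <- geom$radius * 1e-3   # nm -> um; source sphere ~ cleft size
      ctr <- c(min(max(cx[i], R_cru), domain[1] - R_cru),
               min(max(cy[i], R_cru), domain[2] - R_cru),
               z)
      crus[[k]] <- list(id = k, center = ctr, geom = geom,
                        n_ryr = n_ryr[k], n_lcc = n_lcc[k],
                        v_jsr = v_jsr[k], R_cru = R_cru, R_jsr = R_cru)
    }
  }
  structure(crus, class = "cru_population")
}

#' @export
print.cru_population <- function(x, ...) {
  nr <- vapply(x, function(u) u$n_ryr, numeric(1))
  cat(sprintf("<cru_population> %d CRUs, mean RyR %.1f (range %d-%d)\n",
              length(x), mean(nr), min(nr), max(nr)))
  invisible(x)
}

#' Calsequestrin fast-buffering factor
#'
#' `beta_jsr = 1 / (1 + n K B / (K + c)^2)` from the fast-buffer
#' approximation of calsequestrin binding in the junctional SR.
#'
#' @param c_jsr free jSR Ca2+, uM.
#' @param params the `jsr` block of [cicr_params()].
#' @return Factor in (0, 1].
#' @export
jsr_buffer_factor <- function(c_jsr, params = cicr_params()$jsr) {
  1 / (1 + params$n_csqn * params$K_csqn * params$B_csqn /
         (params$K_csqn + c_jsr)^2)
}

#' Advance junctional-SR calcium
#'
#' Integrates `dc_jsr/dt = beta_jsr * ((S - c_jsr)/tau_refill -
#' sum(I_RyR)/v_jsr)` over `dt` with linearized internal sub-steps of at
#' most `params$substep` ms, refreshing `beta_jsr` every sub-step.
#'
#' @param c_jsr free jSR Ca2+ at the step start, uM.
#' @param S_local network-SR free Ca2+ at the CRU location, uM (held
#'   constant over the step).
#' @param ryr_efflux total RyR release current of this CRU, uM um^3/ms
#'   (held constant).
#' @param v_jsr jSR volume, um^3.
#' @param dt step, ms.
#' @param params the `jsr` block of [cicr_params()].
#' @return List with `c_jsr` (end of step), `refill_mean` (time-averaged
#'   refill rate `(S - c_jsr)/tau_refill`, uM/ms), and `clamped` (TRUE if
#'   the concentration had to be clamped at zero).
#' @export
jsr_step <- function(c_jsr, S_local, ryr_efflux, v_jsr, dt,
                     params = cicr_params()$jsr) {
  stopifnot(dt > 0, v_jsr > 0)
  n_sub <- max(1L, ceiling(dt / params$substep))
  h <- dt / n_sub
  c <- c_jsr
  refill_int <- 0
  clamped <- FALSE
  drain <- ryr_efflux / v_jsr
  for (i in seq_len(n_sub)) {
    b <- jsr_buffer_factor(c, params)
    # linearized-implicit update in the refill term
    num <- c + h * b * (S_local / params$tau_refill - drain)
    c_new <- num / (1 + h * b / params$tau_refill)
    if (c_new < 0) { c_new <- 0; clamped <- TRUE }
    refill_int <- refill_int + h * (S_local - (c + c_new) / 2) /
      params$tau_refill
    c <- c_new
  }
  if (clamped) warning("jSR calcium clamped at zero (check parameters)")
  list(c_jsr = c, refill_mean = refill_int / dt, clamped = clamped)
}

# cells of `grid` whose centers lie within `radius` of `center`;
# falls back to the nearest cell for spheres below grid resolution
.sphere_cells <- function(grid, center, radius) {
  cc <- grid_cell_centers(grid)
  d2 <- (cc$x - center[1])^2 + (cc$y - center[2])^2 + (cc$z - center[3])^2
  idx <- which(d2 <= radius^2)
  if (!length(idx)) idx <- which.min(d2)
  idx
}

#' Map CRU channel currents to a bulk source field
#'
#' Each CRU deposits its total channel current uniformly inside a sphere
#' of radius `R_cru` around its center, scaled to cytosolic concentration
#' per the bidomain volume fractions. The discrete field is renormalized
#' per sphere so that the grid integral matches the analytic total
#' exactly; spheres below grid resolution degenerate to the nearest cell.
#'
#' @param crus a [sample_cru_population()] result.
#' @param totals numeric vector: total current (LCC + RyR) per CRU,
#'   uM um^3/ms.
#' @param grid a [grid_spec()].
#' @param params a [cicr_params()] list.
#' @return Numeric vector over grid cells, uM/ms.
#' @export
cru_bulk_source <- function(crus, totals, grid, params = cicr_params()) {
  stopifnot(length(totals) == length(crus))
  J <- numeric(grid$n_cell)
  vol <- grid$h^3
  scale <- 1 / params$physical$v_cyt_frac
  for (i in seq_along(crus)) {
    if (totals[i] == 0) next
    idx <- .sphere_cells(grid, crus[[i]]$center, crus[[i]]$R_cru)
    J[idx] <- J[idx] + scale * totals[i] / (length(idx) * vol)
  }
  J
}

#' Junctional-SR refill sink on the network-SR field
#'
#' Each CRU removes `v_jsr_i * (S(r_i) - c_jsr_i) / tau_refill` from the
#' network SR, distributed uniformly in its refill sphere and scaled by
#' the SR volume fraction, mirroring the refill source of the jSR
#' equation so that SR-to-jSR transfer conserves calcium.
#'
#' @param crus a [sample_cru_population()] result.
#' @param refill numeric vector per CRU: refill rate `(S - c_jsr) /
#'   tau_refill` (uM/ms; typically the time-averaged value from
#'   [jsr_step()]).
#' @param grid a [grid_spec()].
#' @param params a [cicr_params()] list.
#' @return Numeric sink field over grid cells, uM/ms (subtract from the
#'   `S` equation).
#' @export
jsr_refill_sink <- function(crus, refill, grid, params = cicr_params()) {
  stopifnot(length(refill) == length(crus))
  J <- numeric(grid$n_cell)
  vol <- grid$h^3
  scale <- 1 / params$physical$v_sr_frac
  for (i in seq_along(crus)) {
    if (refill[i] == 0) next
    idx <- .sphere_cells(grid, crus[[i]]$center, crus[[i]]$R_jsr)
    J[idx] <- J[idx] + scale * crus[[i]]$v_jsr * refill[i] /
      (length(idx) * vol)
  }
  J
}
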