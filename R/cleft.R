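#' Dirichlet Green function of the disk
#'
#' Green function of the planar Laplacian on a disk of radius `R` with
#' homogeneous Dirichlet boundary (it vanishes on the rim), evaluated by
#' the image-charge construction. Used to superpose channel point sources
#' in the quasistatic dyadic-cleft solution.
#'
#' For a source at the disk center the closed form `log(R/||r||)/(2*pi)`
#' is used. Evaluation at the source point itself is singular; the
#' regularized self-coupling of [assemble_coupling()] must be used there.
#'
#' @param r evaluation point, numeric length-2 (same length unit as `R`).
#' @param r_i source point, numeric length-2, strictly inside the disk.
#' @param R disk radius (> 0).
#' @return Dimensionless Green-function value.
#' @examples
#' green_disk(c(100, 0), c(0, 0), 200)  # = log(2)/(2*pi)
#' green_disk(c(200, 0), c(50, 30), 200)  # rim: 0 (to rounding)
#' @export
green_disk <- function(r, r_i, R) {
  stopifnot(length(r) == 2, length(r_i) == 2, R > 0)
  d2 <- sum((r - r_i)^2)
  if (d2 == 0) {
    stop("green_disk(): evaluation at the source point is singular; ",
         "use the regularized self-coupling")
  }
  nrm_i <- sqrt(sum(r_i^2))
  if (sqrt(sum(r^2)) > R * (1 + 1e-12) || nrm_i >= R) {
    stop("green_disk(): points must lie inside the disk (source strictly)")
  }
  if (nrm_i == 0) {
    return(log(R / sqrt(sum(r^2))) / (2 * pi))
  }
  q <- R / nrm_i
  r_img <- q^2 * r_i
  log(sqrt(sum((r_img - r)^2)) / (q * sqrt(d2))) / (2 * pi)
}

#' Axial electro-diffusion profile of the cleft
#'
#' Vertical enhancement factor `Z(z) = exp(-2*phi0*exp(-kappa*z))` created
#' by the surface-charge potential of the T-tubule membrane. With the
#' default `phi0 = -2.2` the factor is ~81.5 at the T-tubule face (z = 0)
#' and decays monotonically to 1 with height.
#'
#' @param z height above the T-tubule face, nm (vectorized).
#' @param phi0 dimensionless surface potential (negative for a
#'   Ca2+-attracting membrane).
#' @param kappa inverse Debye screening length, nm^-1.
#' @return `Z(z)`, dimensionless, `> 0`.
#' @export
axial_profile <- function(z, phi0 = -2.2, kappa = 1) {
  exp(-2 * phi0 * exp(-kappa * z))
}

#' Effective cleft height
#'
#' `h* = integral of Z(z) over the cleft height`. Exceeds the geometric
#' height whenever `phi0 < 0`.
#'
#' @param height cleft height, nm.
#' @inheritParams axial_profile
#' @return Effective height in nm.
#' @export
axial_height <- function(height = 15, phi0 = -2.2, kappa = 1) {
  stats::integrate(axial_profile, 0, height, phi0 = phi0, kappa = kappa,
                   rel.tol = 1e-10)$value
}

#' Cleft geometry of one calcium release unit
#'
#' Describes the dyadic cleft as a cylinder of radius `radius` and height
#' `height` with RyRs on the junctional-SR (top) face and LCCs on the
#' T-tubule (bottom) face.
#'
#' @param x,y planar channel-mouth coordinates, nm, measured from the
#'   cylinder axis.
#' @param type character vector, `"RyR"` or `"LCC"` per channel.
#' @param radius cylinder radius, nm. Defaults to the outermost channel
#'   distance plus the margin.
#' @param height cleft height, nm.
#' @param margin minimum clearance between any channel and the rim, nm.
#' @param a_ch channel-mouth regularization radius, nm.
#' @return An object of class `"cleft_geometry"`.
#' @export
cleft_geometry <- function(x, y, type,
                           radius = NULL, height = 15, margin = 60,
                           a_ch = 1.5) {
  stopifnot(length(x) == length(y), length(type) == length(x),
            all(type %in% c("RyR", "LCC")))
  r <- sqrt(x^2 + y^2)
  if (is.null(radius)) radius <- max(r) + margin
  if (radius < margin) stop("cleft radius cannot be below the rim margin")
  if (any(r > radius - margin + 1e-9)) {
    stop("every channel must lie at least ", margin, " nm from the rim")
  }
  pos <- cbind(x, y)
  if (anyDuplicated(pos)) stop("channel positions must be pairwise distinct")
  structure(
    list(x = x, y = y, type = type,
         # RyRs sit on the jSR (top) face, LCCs on the T-tubule (bottom) face
         z = ifelse(type == "RyR", height, 0),
         radius = radius, height = height, margin = margin, a_ch = a_ch),
    class = "cleft_geometry")
}

#' @export
print.cleft_geometry <- function(x, ...) {
  cat(sprintf("<cleft_geometry> R = %.0f nm, %d RyR + %d LCC\n",
              x$radius, sum(x$type == "RyR"), sum(x$type == "LCC")))
  invisible(x)
}

#' Serialize / restore a cleft geometry
#'
#' Plain-JSON representation of a CRU cleft for reproducible geometry.
#' @param geom a [cleft_geometry()] object.
#' @param path file path; if `NULL`, the JSON string is returned.
#' @return `cleft_to_json()`: the path (or JSON string) invisibly;
#'   `cleft_from_json()`: a `cleft_geometry` object.
#' @export
cleft_to_json <- function(geom, path = NULL) {
  s <- jsonlite::toJSON(unclass(geom), digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(invisible(as.character(s)))
  writeLines(s, path)
  invisible(path)
}

#' @rdname cleft_to_json
#' @export
cleft_from_json <- function(path) {
  g <- jsonlite::fromJSON(path)
  cleft_geometry(g$x, g$y, g$type, radius = g$radius, height = g$height,
                 margin = g$margin, a_ch = g$a_ch)
}

#' Assemble the cleft coupling matrix
#'
#' Precomputes the pairwise coupling coefficients
#' `eta(r_i -> r_j) = Z(z_j) * G(r_j, r_i) / (beta * h* * D_c)`
#' that map single-channel currents (uM um^3/ms) to concentration
#' increments (uM) at every channel mouth. The singular self-coupling is
#' regularized as the average of the Green function over a channel-mouth
#' disk of radius `a_ch`, which for the disk Green function has the closed
#' form `(log((R^2 - d^2)/(R * a_ch)) + 1/2)/(2*pi)` at source distance
#' `d` from the axis. The matrix depends only on geometry and is computed
#' once per CRU before a simulation.
#'
#' @param geom a [cleft_geometry()].
#' @param D_c cytosolic Ca2+ diffusion coefficient, um^2/ms.
#' @param beta linear cleft buffer factor (>= 1 attenuates coupling).
#' @param phi0,kappa axial profile parameters, see [axial_profile()].
#' @return A list of class `"cleft_coupling"` with elements `eta`
#'   (n x n matrix, `eta[j, i]` couples current i to mouth j), `Z`
#'   (axial factor at each mouth), `h_star` (um), `beta`, and the
#'   geometry.
#' @export
assemble_coupling <- function(geom, D_c = 0.22, beta = 1,
                              phi0 = -2.2, kappa = 1) {
  stopifnot(inherits(geom, "cleft_geometry"), D_c > 0, beta >= 1)
  n <- length(geom$x)
  h_star_nm <- axial_height(geom$height, phi0, kappa)
  h_star <- h_star_nm * 1e-3                  # nm -> um
  Z <- axial_profile(geom$z, phi0, kappa)
  R <- geom$radius
  x <- geom$x; y <- geom$y
  d2i <- x^2 + y^2                       # squared distances from the axis
  d2 <- outer(x, x, `-`)^2 + outer(y, y, `-`)^2   # [j, i] = |r_j - r_i|^2
  q2 <- ifelse(d2i > 0, R^2 / d2i, Inf)  # q_i^2
  Q2 <- matrix(q2, n, n, byrow = TRUE)   # [j, i] = q_i^2
  dotji <- outer(x, x) + outer(y, y)     # [j, i] = r_j . r_i
  e2 <- matrix(d2i, n, n) - 2 * Q2 * dotji +
    Q2^2 * matrix(d2i, n, n, byrow = TRUE)       # |r_j - q_i^2 r_i|^2
  G <- ifelse(is.finite(Q2),
              log(e2 / (Q2 * d2)) / (4 * pi),
              log(R^2 / matrix(pmax(d2i, 1e-300), n, n)) / (4 * pi))
  diag(G) <- (log((R^2 - d2i) / (R * geom$a_ch)) + 0.5) / (2 * pi)
  eta <- sweep(G, 1, Z, `*`) / (beta * h_star * D_c)
  if (any(!is.finite(eta)) || any(diag(eta) <= 0)) {
    stop("invalid coupling matrix; check geometry")
  }
  structure(list(eta = eta, Z = Z, h_star = h_star, beta = beta,
                 geom = geom, D_c = D_c, phi0 = phi0, kappa = kappa),
            class = "cleft_coupling")
}

#' Single-channel current laws
#'
#' RyR: linear permeation `I = g * (c_jsr - c_mouth)`. LCC: GHK-type flux
#' `I = J_L * dV * (c_ext * exp(-dV) - c_mouth) / (1 - exp(-dV))` with
#' `dV = 2FV/(RT)`; the analytic `V -> 0` limit `J_L * (c_ext - c_mouth)`
#' is used near zero to avoid the 0/0 form. Currents are in uM um^3/ms
#' (1 uM um^3 ~ 602 ions); multiply by `2F` to convert to pA (0.193 pA
#' per uM um^3/ms).
#'
#' @param kind `"RyR"` or `"LCC"`.
#' @param c_mouth mouth Ca2+ concentration, uM.
#' @param c_jsr junctional-SR free Ca2+, uM (RyR only).
#' @param V membrane potential, mV (LCC only).
#' @param g RyR permeability, um^3/ms.
#' @param J_L LCC conductance, um^3/ms.
#' @param c_ext external Ca2+, uM.
#' @param physical physical-constant block of [cicr_params()].
#' @return Current in uM um^3/ms (positive into the cleft).
#' @export
channel_current <- function(kind, c_mouth, c_jsr = NULL, V = NULL,
                            g = 2.33e-3, J_L = 0.0546, c_ext = 1800,
                            physical = cicr_params()$physical) {
  stopifnot(all(c_mouth >= 0))
  if (kind == "RyR") {
    stopifnot(!is.null(c_jsr))
    return(g * (c_jsr - c_mouth))
  }
  stopifnot(kind == "LCC", !is.null(V))
  dV <- .delta_2frt(physical) * V
  ifelse(abs(dV) < 1e-9,
         J_L * (c_ext - c_mouth),
         J_L * dV * (c_ext * exp(-dV) - c_mouth) / (1 - exp(-dV)))
}

#' Solve the quasistatic cleft
#'
#' Solves the linear system obtained by inserting the channel current laws
#' into the Green-function superposition evaluated at each open channel
#' mouth. Closed channels carry zero current; their mouth concentrations
#' follow from the superposition of the open-channel currents. With all
#' channels closed every mouth sits at `Z(z_i) * c_bulk`.
#'
#' @param coupling a [assemble_coupling()] result.
#' @param open logical vector, one flag per channel.
#' @param c_bulk bulk Ca2+ at the cleft rim, uM.
#' @param c_jsr junctional-SR free Ca2+, uM.
#' @param V membrane potential, mV.
#' @param g,J_L,c_ext,physical current-law parameters, see
#'   [channel_current()].
#' @return A list of class `"cleft_state"`: `c_mouth` (uM per channel),
#'   `current` (uM um^3/ms, zero when closed), `open`, `c_bulk`, `c_jsr`,
#'   `V`, and `residual` (max absolute defect of the superposition
#'   identity at open mouths).
#' @export
solve_cleft <- function(coupling, open, c_bulk, c_jsr, V,
                        g = 2.33e-3, J_L = 0.0546, c_ext = 1800,
                        physical = cicr_params()$physical) {
  stopifnot(inherits(coupling, "cleft_coupling"),
            length(open) == nrow(coupling$eta))
  n <- length(open)
  Z <- coupling$Z
  eta <- coupling$eta
  is_ryr <- coupling$geom$type == "RyR"
  I <- numeric(n)
  if (any(open)) {
    oo <- which(open)
    dV <- .delta_2frt(physical) * V
    # current law I_k = A_k - B_k * c_k at each open mouth
    A <- B <- numeric(length(oo))
    for (k in seq_along(oo)) {
      ch <- oo[k]
      if (is_ryr[ch]) {
        A[k] <- g * c_jsr; B[k] <- g
      } else if (abs(dV) < 1e-9) {
        A[k] <- J_L * c_ext; B[k] <- J_L
      } else {
        A[k] <- J_L * dV * c_ext * exp(-dV) / (1 - exp(-dV))
        B[k] <- J_L * dV / (1 - exp(-dV))
      }
    }
    # (I + diag(B) %*% eta_oo) I = A - B * Z_o c_bulk
    M <- diag(length(oo)) + B * eta[oo, oo, drop = FALSE]
    rhs <- A - B * (Z[oo] * c_bulk)
    Io <- tryCatch(solve(M, rhs),
                   error = function(e) stop("singular cleft system: ",
                                            conditionMessage(e)))
    I[oo] <- Io
  }
  c_mouth <- Z * c_bulk + drop(eta %*% I)
  resid <- 0
  if (any(open)) {
    oo <- which(open)
    law <- ifelse(is_ryr[oo],
                  g * (c_jsr - c_mouth[oo]),
                  channel_current("LCC", c_mouth[oo], V = V, J_L = J_L,
                                  c_ext = c_ext, physical = physical))
    resid <- max(abs(law - I[oo]))
  }
  structure(list(c_mouth = c_mouth, current = I, open = open,
                 c_bulk = c_bulk, c_jsr = c_jsr, V = V, residual = resid),
            class = "cleft_state")
}

#' Calibrate the cleft buffer factor
#'
#' The linear buffer factor `beta` emulates the fast dyadic buffering
#' (calmodulin, ATP, indicator dye) that the two-state RyR schemes were
#' fitted under. It is chosen against the sustained-release operating
#' point of the scheme: with a fraction `frac_open` of the RyRs of a
#' mean-sized release unit open at the depleted quasi-steady junctional
#' SR load `c_jsr`, the largest concentration seen by a closed RyR mouth
#' is brought to `target`. The default target (60 uM) keeps the
#' luminal-regulated opening rate within the sub-0.7 ms^-1 regime that
#' the source simulations report encountering, while the mouth of an
#' open channel stays within the 30-100 uM range of spatially resolved
#' spark models.
#'
#' @param target maximum closed-RyR mouth concentration at the reference
#'   operating point, uM.
#' @param n_ryr,n_lcc reference cleft size.
#' @param frac_open fraction of RyRs open in the reference condition.
#' @param c_jsr,c_bulk reference junctional-SR and bulk Ca2+, uM.
#' @param params a [cicr_params()].
#' @param interval search interval for `beta`.
#' @param n_draws random open-set draws averaged over (fixed internal
#'   stream; does not touch R's RNG).
#' @return The calibrated `beta` (dimensionless, >= 1).
#' @export
calibrate_beta <- function(target = 60, n_ryr = 50, n_lcc = 12,
                           frac_open = 0.3, c_jsr = 400, c_bulk = 1,
                           params = cicr_params(),
                           interval = c(1, 500), n_draws = 20) {
  geom <- place_channels(n_ryr, n_lcc, pitch = params$cleft$pitch,
                         margin = params$cleft$margin,
                         height = params$cleft$height,
                         a_ch = params$cleft$a_ch)
  ir <- which(geom$type == "RyR")
  n_open <- max(1L, round(frac_open * n_ryr))
  draws <- withr::with_seed(1203, replicate(n_draws, sample(ir, n_open),
                                            simplify = FALSE))
  metric <- function(beta) {
    cp <- assemble_coupling(geom, D_c = params$buffers$D_ca, beta = beta,
                            phi0 = params$cleft$phi0,
                            kappa = params$cleft$kappa)
    worst <- vapply(draws, function(oo) {
      open <- rep(FALSE, length(geom$x)); open[oo] <- TRUE
      st <- solve_cleft(cp, open, c_bulk, c_jsr, V = 0, g = params$ryr$g,
                        J_L = params$lcc$J_L,
                        c_ext = params$physical$c_ext,
                        physical = params$physical)
      max(st$c_mouth[setdiff(ir, oo)])
    }, numeric(1))
    max(worst) - target
  }
  stats::uniroot(metric, interval, tol = 1e-3)$root
}
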