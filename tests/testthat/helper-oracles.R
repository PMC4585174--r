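# Independent numerical oracles used by the tests.

# Finite-difference solve of the planar cleft equation on a disk:
# lap f = -(1/(h* Dc)) sum_i I_i delta_a(r - r_i), f = 0 on the rim.
# Returns the FD coupling matrix eta_fd[j, i] (uM per unit current),
# built channel-by-channel from unit-current solves, with the same
# mouth-disk regularization as the Green-function implementation.
fd_cleft_eta <- function(geom, beta = 1, D_c = 0.22, h = 1.25,
                         phi0 = -2.2, kappa = 1) {
  requireNamespace("Matrix", quietly = TRUE)
  R <- geom$radius
  h_star <- axial_height(geom$height, phi0, kappa) * 1e-3  # um
  gx <- seq(-R + h / 2, R - h / 2, by = h)
  gg <- expand.grid(x = gx, y = gx)
  inside <- gg$x^2 + gg$y^2 < R^2
  idx <- integer(nrow(gg)); idx[inside] <- seq_len(sum(inside))
  n <- sum(idx > 0)
  nx <- length(gx)
  ks <- which(inside)
  kx <- (ks - 1) %% nx + 1; ky <- (ks - 1) %/% nx + 1
  # off-diagonal entries toward in-disk neighbors; outside neighbors are
  # Dirichlet-0 ghosts and contribute nothing
  ii <- idx[ks]; jj <- idx[ks]; vv <- rep(-4, n)
  for (off in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    ok <- kx + off[1] >= 1 & kx + off[1] <= nx &
      ky + off[2] >= 1 & ky + off[2] <= nx
    nb <- ks[ok] + off[1] + off[2] * nx
    keep <- inside[nb]
    ii <- c(ii, idx[ks[ok]][keep]); jj <- c(jj, idx[nb[keep]])
    vv <- c(vv, rep(1, sum(keep)))
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv / h^2, dims = c(n, n))
  # unit-current sources spread over the mouth disk
  n_ch <- length(geom$x)
  B <- matrix(0, n, n_ch)
  mouth_cells <- vector("list", n_ch)
  for (ch in seq_len(n_ch)) {
    d2 <- (gg$x - geom$x[ch])^2 + (gg$y - geom$y[ch])^2
    cells <- which(inside & d2 <= geom$a_ch^2)
    if (!length(cells)) cells <- which(inside)[which.min(d2[inside])]
    mouth_cells[[ch]] <- idx[cells]
    w <- 1 / (length(cells) * h^2)          # integrates to 1
    B[idx[cells], ch] <- w / (h_star * D_c)
  }
  F <- as.matrix(Matrix::solve(A, -B))      # f fields per unit current
  Z <- axial_profile(geom$z, phi0, kappa)
  eta <- matrix(0, n_ch, n_ch)
  for (i in seq_len(n_ch)) {
    for (j in seq_len(n_ch)) {
      val <- if (i == j) {
        mean(F[mouth_cells[[j]], i])
      } else {
        # bilinear interpolation at the mouth of channel j
        fd_interp(F[, i], gg, gx, idx, geom$x[j], geom$y[j])
      }
      eta[j, i] <- Z[j] * val / beta
    }
  }
  eta
}

fd_interp <- function(f, gg, gx, idx, x, y) {
  h <- gx[2] - gx[1]
  i0 <- findInterval(x, gx); j0 <- findInterval(y, gx)
  nx <- length(gx)
  get <- function(i, j) {
    k <- (j - 1) * nx + i
    if (idx[k] > 0) f[idx[k]] else 0
  }
  wx <- (x - gx[i0]) / h; wy <- (y - gx[j0]) / h
  (1 - wx) * (1 - wy) * get(i0, j0) + wx * (1 - wy) * get(i0 + 1, j0) +
    (1 - wx) * wy * get(i0, j0 + 1) + wx * wy * get(i0 + 1, j0 + 1)
}

# solve the self-consistent current system for a given coupling matrix
# (the same algebra as solve_cleft, driven by an externally supplied eta)
cleft_currents_for_eta <- function(eta, geom, open, c_bulk, c_jsr, V,
                                   g = 2.33e-3, J_L = 0.0546,
                                   c_ext = 1800, phi0 = -2.2, kappa = 1) {
  Z <- axial_profile(geom$z, phi0, kappa)
  physical <- cicr_params()$physical
  dV <- 2 * physical$F / (physical$R * physical$T) * V
  oo <- which(open)
  A <- Bc <- numeric(length(oo))
  for (k in seq_along(oo)) {
    ch <- oo[k]
    if (geom$type[ch] == "RyR") {
      A[k] <- g * c_jsr; Bc[k] <- g
    } else if (abs(dV) < 1e-9) {
      A[k] <- J_L * c_ext; Bc[k] <- J_L
    } else {
      A[k] <- J_L * dV * c_ext * exp(-dV) / (1 - exp(-dV))
      Bc[k] <- J_L * dV / (1 - exp(-dV))
    }
  }
  M <- diag(length(oo)) + Bc * eta[oo, oo, drop = FALSE]
  I <- solve(M, A - Bc * (Z[oo] * c_bulk))
  Ifull <- numeric(length(open)); Ifull[oo] <- I
  list(current = Ifull, c_mouth = Z * c_bulk + drop(eta %*% Ifull))
}

# deterministic master-equation integration of a generator (oracle for
# occupancy transients)
master_equation <- function(Q, p0, t_end, dt = 0.01) {
  p <- p0
  out <- list()
  times <- seq(0, t_end, by = dt)
  for (t in times) {
    out[[length(out) + 1]] <- p
    p <- p + dt * drop(p %*% Q)
    p <- pmax(p, 0); p <- p / sum(p)
  }
  m <- do.call(rbind, out)
  colnames(m) <- rownames(Q)
  list(time = times, p = m)
}
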