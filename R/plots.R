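# Plotting and broom-style summaries for simulation results.

#' Tidy a simulation result
#'
#' Long-format view of the recorded observables, one row per
#' (time, variable).
#'
#' @param x a `cicr_sim`.
#' @param variables columns of `x$traces` to keep (default: the
#'   headline observables).
#' @param ... unused.
#' @return A tibble with columns `t`, `variable`, `value`.
#' @export
tidy.cicr_sim <- function(x, variables = c("V", "c_avg", "c_exp",
                                           "j_rel", "j_ca",
                                           "frac_ryr_open"), ...) {
  tr <- x$traces
  keep <- intersect(variables, names(tr))
  out <- lapply(keep, function(v)
    tibble::tibble(t = tr$t, variable = v, value = tr[[v]]))
  do.call(rbind, out)
}

#' One-row summary of a simulation
#'
#' @param x a `cicr_sim`.
#' @param ... unused.
#' @return A tibble with peak averaged calcium (uM), time to peak from
#'   the first stimulus (ms), maximum open-RyR percentage, early gain
#'   (first 50 ms of the AP), APD90 of the first beat, the largest RyR
#'   opening rate encountered, and the CRU count.
#' @export
glance.cicr_sim <- function(x, ...) {
  tr <- x$traces
  cfg <- x$config
  t0 <- cfg$stim_start
  ipk <- which.max(tr$c_avg)
  apd <- compute_apd_di(tr$t, tr$V,
                        t0 + cfg$bcl * (seq_len(cfg$n_beats) - 1),
                        cfg$bcl)
  gain <- compute_gain(tr$t, tr$j_rel, tr$j_ca, c(t0, t0 + 50))
  tibble::tibble(
    peak_ca = max(tr$c_avg),
    time_to_peak = tr$t[ipk] - t0,
    max_ryr_open_pct = 100 * max(tr$frac_ryr_open),
    gain_early = gain,
    apd90 = apd$apd[1],
    max_kopen = x$max_kopen,
    n_cru = length(x$population))
}

#' Plot a simulation result
#'
#' Voltage, averaged cytosolic calcium (with the fluorescence-calibrated
#' estimate), release/trigger fluxes, and the open-RyR fraction on a
#' shared time axis.
#'
#' @param object a `cicr_sim`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cicr_sim <- function(object, ...) {
  d <- tidy.cicr_sim(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~variable, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.cicr_sim <- function(x, ...) print(autoplot.cicr_sim(x, ...))

#' Plot a dyadic-cleft concentration profile
#'
#' Planar map of the quasistatic cleft concentration for a given open
#' configuration, evaluated on a polar-to-Cartesian raster from the
#' Green-function superposition.
#'
#' @param coupling a [assemble_coupling()].
#' @param state a [solve_cleft()] result.
#' @param n raster resolution per axis.
#' @param z height at which to evaluate the axial factor, nm.
#' @return A ggplot object.
#' @export
plot_cleft_profile <- function(coupling, state, n = 101, z = 15) {
  geom <- coupling$geom
  R <- geom$radius
  xs <- seq(-R, R, length.out = n)
  gr <- expand.grid(x = xs, y = xs)
  keep <- gr$x^2 + gr$y^2 < R^2 * 0.999
  gr <- gr[keep, ]
  Zf <- axial_profile(z, coupling$phi0, coupling$kappa)
  val <- vapply(seq_len(nrow(gr)), function(i) {
    s <- state$c_bulk
    for (k in seq_along(state$current)) {
      if (state$current[k] == 0) next
      p <- c(gr$x[i], gr$y[i])
      src <- c(geom$x[k], geom$y[k])
      G <- if (sum((p - src)^2) < geom$a_ch^2) {
        (log((R^2 - sum(src^2)) / (R * geom$a_ch)) + 0.5) / (2 * pi)
      } else green_disk(p, src, R)
      s <- s + state$current[k] * G /
        (coupling$beta * coupling$h_star * coupling$D_c)
    }
    Zf * s
  }, numeric(1))
  gr$c <- val
  ggplot2::ggplot(gr, ggplot2::aes(.data$x, .data$y, fill = .data$c)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = "[Ca2+] (uM)") +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
}

#' Plot a restitution curve
#'
#' @param restitution a [restitution_protocol()] tibble.
#' @return A ggplot object (APD against preceding DI).
#' @export
plot_restitution <- function(restitution) {
  ggplot2::ggplot(restitution,
                  ggplot2::aes(x = .data$di, y = .data$apd)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "DI (ms)", y = "APD (ms)") +
    ggplot2::theme_minimal()
}
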