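#' Default model parameters
#'
#' Builds the full parameter set of the multiscale calcium-cycling model:
#' buffering and diffusion constants, SERCA and Na+/Ca2+-exchanger (NCX)
#' constants, physical constants and ionic concentrations, RyR/LCC channel
#' parameters for every gating scheme, and the ionic-current peak
#' conductances of the rabbit ventricular membrane model.
#'
#' Units follow the conventions used throughout the package: concentrations
#' in micromolar (uM), lengths in micrometres (um) except cleft geometry
#' (nanometres, nm), time in milliseconds (ms), single-channel amounts per
#' time in uM um^3/ms (1 uM um^3 = 1e-21 mol, approximately 602 ions), and
#' membrane currents in pA/pF.
#'
#' @param ... named overrides. Nested components can be replaced wholesale
#'   (e.g. `pump = list(v_max = 0.4)` merges into the pump block).
#'
#' @return A named list of parameter blocks with class `"cicr_params"`:
#'   `buffers` (cytosolic/SR buffer kinetics and diffusion), `pump`,
#'   `ncx`, `physical`, `cleft`, `ryr` (one sub-list per scheme), `lcc`,
#'   `jsr`, and `conductances`.
#'
#' @examples
#' p <- cicr_params()
#' p$pump$v_max
#' p2 <- cicr_params(pump = list(v_max = 0.4))
#' p2$pump$v_max
#' @export
cicr_params <- function(...) {
  p <- list(
    ## cytosolic buffers: troponin C (stationary), calmodulin (mobile),
    ## Fluo-4 (mobile); SR lumenal buffer
    buffers = list(
      # troponin C, stationary (diffusion exposed but zero by default)
      tnc  = list(total = 53.0,   k_on = 0.043,  k_off = 0.026,  D = 0.0),
      cam  = list(total = 133.0,  k_on = 0.8,    k_off = 0.2,    D = 0.04),
      fluo = list(total = 133.0,  k_on = 0.0488, k_off = 0.0439, D = 0.033),
      sr   = list(total = 1500.0, k_on = 0.1,    k_off = 60.0,   D = 0.01),
      D_ca = 0.22,   # cytosolic free Ca2+ diffusion, um^2/ms
      D_sr = 0.20    # SR free Ca2+ diffusion, um^2/ms
    ),
    pump = list(v_max = 0.8, K_p = 0.2),  # SERCA, uM/ms and uM
    ncx = list(
      # exchanger strength: the source electrophysiology model uses
      # 0.84 uM/ms; a per-second reading would make the exchanger current
      # ~1e-4 pA/pF, orders below the reported current traces
      g_naca = 0.84,     # uM/ms
      k_sat = 0.2, xi = 0.35,
      K_m_nai = 12.3, K_m_nao = 87.5,    # mM
      K_m_cai = 0.0036, K_m_cao = 1.3,   # mM
      c_naca = 0.3,                      # uM, allosteric Ca activation
      f_high = 2.5, f_low = 1.5, f_surf = 0.5,
      nai = 12.0                         # mM, internal Na+ (held constant)
    ),
    physical = list(
      C_m = 3.1e-4,        # uF
      v_cell = 2.58e4,     # um^3  (2.58e-5 ul)
      F = 96.5,            # C/mmol
      R = 8.315,           # J/(mol K)
      T = 308,             # K
      na_o = 136, k_i = 140, k_o = 5.4,  # mM
      c_ext = 1800,        # uM external Ca2+
      v_sr_frac = 0.1,     # nu_sr / nu_cell
      v_jsr_frac = 0.005,  # nu_jsr / nu_cell (all jSRs combined)
      v_cyt_frac = 0.895,  # nu_cyt / nu_cell
      # specific membrane capacitance used to derive the cell surface
      # area A_cell = C_m / c_spec (not printed; 1 uF/cm^2 = 0.01 pF/um^2)
      c_spec = 0.01        # pF/um^2
    ),
    cleft = list(
      height = 15,        # nm
      phi0 = -2.2,        # dimensionless surface-charge potential
      kappa = 1,          # nm^-1
      margin = 60,        # nm, channel-to-rim margin
      pitch = 30,         # nm, RyR lattice pitch
      a_ch = 1.5,         # nm, channel-mouth regularization radius
      beta = 1            # linear cleft buffer factor (scheme default below)
    ),
    ryr = list(
      g = 2.33e-3,        # um^3/ms (printed 2.33 um^3/s)
      stern4 = list(
        k_ac_max = 0.9288,  # ms^-1 (928.8 s^-1)
        k_in_max = 0.0078,  # ms^-1 (7.8 s^-1)
        K_ac = 8.5, K_in = 8.5,  # uM
        k_om = 0.060, k_im = 0.005,  # ms^-1
        K_jsr = 550,        # uM
        lambda = 27.5,      # asymmetry of closed-state inactivation
        beta = 1
      ),
      cannell2 = list(
        A_open = 457,       # ms^-1 per mM^2.12 (4.57e5 s^-1)
        p_open = 2.12,
        k_open_max = 0.8,   # ms^-1
        A_close = 0.245,    # ms^-1 per mM^-0.27 (245 s^-1)
        p_close = -0.27,
        k_close_max = 2.0,  # ms^-1 cap as c_di -> 0
        beta = 4      # calibrate_beta(): closed-mouth cap during sustained release
      ),
      walker2 = list(
        k_plus = 1.107e-4,  # ms^-1 uM^-eta
        eta = 2.1,
        # closing rate: printed as 0.2 s^-1, implemented as 0.2 ms^-1.
        # A 5 s mean open time makes the scheme's stationary diastolic
        # open fraction ~3.5%, whose standing release flux overwhelms
        # uptake and extrusion within milliseconds; the source model
        # closes at a comparable per-millisecond rate.
        k_close = 0.2,      # ms^-1
        phi_b = 0.8025,
        phi_k = 1500,       # uM
        beta = 4      # calibrate_beta()
      )
    ),
    lcc = list(
      J_L = 0.0546,       # um^3/ms single-channel conductance
      k_p0 = 90,          # uM, Ca-induced inactivation threshold
      c_p_bar = 60,       # uM, threshold for Ca dependence of k6
      tau_po = 1,         # ms activation time constant
      r1 = 0.3, r2 = 3,   # ms^-1 opening/closing
      s1p = 0.00195, k1p = 0.00413, k2 = 1e-4, k21p = 0.00224,  # ms^-1
      T_ba = 450          # ms
    ),
    jsr = list(
      tau_refill = 0.5,   # ms (refill-flux constant tau_d)
      n_csqn = 15, B_csqn = 400, K_csqn = 600,  # calsequestrin, uM
      substep = 1e-4      # ms, internal linearized substep
    ),
    conductances = list(
      g_na = 12.0, g_tof = 0.11, g_tos = 0.04, g_k1 = 0.3,
      g_kr = 0.0125, g_ks = 0.1386, g_nak = 1.5   # mS/uF
    )
  )
  ov <- list(...)
  if (length(ov)) {
    stopifnot(!is.null(names(ov)), all(nzchar(names(ov))))
    p <- utils::modifyList(p, ov)
  }
  class(p) <- "cicr_params"
  p
}

#' @export
print.cicr_params <- function(x, ...) {
  cat("<cicr_params> blocks:", paste(names(x), collapse = ", "), "\n")
  invisible(x)
}

# thermal voltage factor delta = 2F/(RT) in mV^-1 (F in C/mmol)
.delta_2frt <- function(physical) {
  2 * physical$F / (physical$R * physical$T)
}

# F/(RT) per mV
.frt <- function(physical) physical$F / (physical$R * physical$T)
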