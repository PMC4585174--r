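# cicrsim

Multiscale stochastic simulation of calcium-induced calcium release
(CICR) in ventricular cardiomyocytes.

Cardiac excitation–contraction coupling spans five orders of magnitude
in space: L-type calcium channels (LCCs) and ryanodine receptors (RyRs)
face each other across ~15 nm dyadic clefts, their local control of
release is decided by concentration gradients over tens of nanometres,
and the summed output of thousands of release units (CRUs) shapes the
whole-cell calcium transient and the action potential. `cicrsim` is for
modellers who want all of those scales in one coupled, seedable
simulation rather than a common-pool approximation.

## The model in brief

* **Dyadic cleft** — quasistatic profile from the Dirichlet Green
  function of the disk, `G(r, r_i) = log(‖r̂_i − r‖ / (q‖r_i − r‖))/2π`
  with `q = R/‖r_i‖`, an axial surface-charge enhancement
  `Z(z) = exp(−2φ₀ e^{−κz})`, and a linear cleft buffer factor β.
  Mouth concentrations and single-channel currents — RyR
  `I = g(c_jsr − c)`, LCC GHK flux with `δ = 2FV/RT` — are solved
  self-consistently as one small linear system per CRU from a
  precomputed coupling matrix.
* **Gating** — every RyR and LCC is a continuous-time Markov chain
  (4-state RyR with Hill-4 activation and asymmetric inactivation;
  two 2-state RyR schemes — induction-decay power laws and luminal
  regulation `k⁺φc^2.1`; a 7-state LCC). Event times come from
  integrated-propensity clocks (time-dependent Gillespie), with
  conductance-neutral transitions batched and the stochastic step set
  by the `0.1·N_s` event rule.
* **Junctional SR** — per-CRU depletion/refill with fast calsequestrin
  buffering `β_jsr = (1 + nKB/(K+c)²)^{-1}`.
* **Bulk** — 3-D bidomain reaction–diffusion (cytosolic Ca²⁺, troponin
  C, calmodulin, Fluo-4, network-SR Ca²⁺, SR buffer) on a structured
  finite-volume grid, advanced by an L-stable Rosenbrock method with
  matrix-free BiCGSTAB solves; SERCA uptake and a position-weighted
  Na⁺/Ca²⁺ exchanger.
* **Membrane** — rabbit ventricular ionic model; `I_CaL` is the exact
  scale-up of the single-channel LCC currents,
  `I_CaL = −2α ΣI_LCC`, `α = F·ν_cell/(C_m·Ω)`.

See the methods vignette (`vignettes/calcium-cycling-model.Rmd`) for
equations, parameter tables, numerical choices and known limitations.

## Worked example

A stimulated action potential in a density-preserving 5 × 5 × 2 μm
subdomain (~36 CRUs) with the 4-state RyR scheme:

```r
library(cicrsim)
cfg <- sim_config("subdomain", "stern4", grid_h = 0.5,
                  t_end = 120, dt_out = 1)
sim <- run_simulation(cfg, seed = 42)
print(sim)
#> <cicr_sim> subdomain / stern4, 36 CRUs, 120 ms simulated (7027 steps)
#>   peak [Ca]_i 1.083 uM, max RyR open 42.0%
glance(sim)[c("peak_ca", "time_to_peak", "max_ryr_open_pct")]
#>   peak_ca time_to_peak max_ryr_open_pct
#> 1    1.08            8               42
```

The stimulus at 5 ms fires the sodium upstroke, LCC openings trigger
CICR, and the spatially averaged cytosolic calcium (`peak_ca`, μM)
peaks 8 ms after the stimulus while 42% of all RyRs are simultaneously
open — under this scheme and this desk-scale geometry release ignites
cleft-by-cleft and synchronizes quickly (the vignette discusses how
this compares with production-scale behaviour). `sim$traces` is a
tibble on a uniform output clock with the membrane potential, every
ionic current, averaged concentrations, release/trigger fluxes and
open-channel fractions; `autoplot(sim)` plots the headline traces, and
`write_outputs(sim, dir)` writes CSV traces, JSON configuration with a
hash, and legacy-ASCII VTK snapshots of the 3-D fields.

Other entry points: `solve_cleft()` (one cleft, any open pattern),
`markov_scheme()`/`simulate_channel()` (gating statistics),
`pde_step()` (bulk integrator), `membrane_step()` (ionic model),
`restitution_protocol()` (constant-BCL pacing), and
`calibrate_beta()` (cleft buffer calibration). A thin command-line
wrapper lives in `exec/cicrsim`.

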