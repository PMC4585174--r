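---
title: "A multiscale stochastic model of cardiac calcium cycling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A multiscale stochastic model of cardiac calcium cycling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cicrsim)
```

# The model

`cicrsim` simulates calcium-induced calcium release (CICR) in a
ventricular cardiomyocyte across its natural scales: nanometre dyadic
clefts housing stochastic ryanodine receptors (RyRs) and L-type calcium
channels (LCCs), micrometre reaction–diffusion fields for cytosolic and
sarcoplasmic-reticulum (SR) calcium and buffers, and the whole-cell
membrane potential. Five coupled components are advanced together:

1. **Dyadic cleft (quasistatic Green function).** Each calcium release
   unit (CRU) is a cylinder of height 15 nm whose RyRs sit on the
   junctional-SR face and whose LCCs sit on the T-tubule face. Because
   the cleft equilibrates an order of magnitude faster than channels
   gate, the in-cleft concentration profile is taken quasistatic: the
   planar Laplace problem with channel point sources is solved by the
   Dirichlet Green function of the disk,
   $G(\mathbf r,\mathbf r_i)=\frac{1}{2\pi}\log\frac{\lVert\hat{\mathbf
   r}_i-\mathbf r\rVert}{q\,\lVert\mathbf r_i-\mathbf r\rVert}$ with
   $q=R/\lVert\mathbf r_i\rVert$ and image point $\hat{\mathbf
   r}_i=q^2\mathbf r_i$, which vanishes at the rim where the cleft meets
   the bulk at concentration $c_\mathrm{bulk}$. Surface charge on the
   T-tubule membrane concentrates calcium near that face by the factor
   $Z(z)=e^{-2\varphi_0 e^{-\kappa z}}$ ($\varphi_0=-2.2$, $\kappa=1$
   nm⁻¹; $Z(0)\approx81$). Mouth concentrations and single-channel
   currents — linear RyR permeation $I=g_\mathrm{RyR}(c_\mathrm{jsr}-c)$
   and a GHK-type LCC flux with $\delta=2FV/RT$ — are solved
   self-consistently as a small linear system per CRU; the coupling
   matrix $\eta_{ji}=Z(z_j)G(\mathbf r_j,\mathbf r_i)/(\beta h^* D_c)$
   is precomputed once per geometry. The singular self-coupling is
   regularized as the exact average of $G$ over a channel-mouth disk of
   radius $a_\mathrm{ch}=1.5$ nm (closed form
   $\frac{1}{2\pi}[\log\frac{R^2-d^2}{R a_\mathrm{ch}}+\frac12]$), which
   keeps the linear system well posed; a finite-difference oracle in the
   test suite confirms mouth concentrations to well under 5%.

2. **Stochastic gating.** Every channel is a continuous-time Markov
   chain: a 4-state RyR scheme (activation is a fourth-order Hill
   function of dyadic calcium saturating at 928.8 s⁻¹ with threshold
   8.5 μM, modulated by luminal calcium with half-maximum 550 μM;
   first-order inactivation saturating at 7.8 s⁻¹ acts from the closed
   state and λ = 27.5-fold faster from the open state), two 2-state
   schemes (an induction-decay scheme with power-law opening/closing
   rates taken in mM, and a luminal-regulation scheme with
   $k_\mathrm{open}=k^+\varphi c^{2.1}$,
   $\varphi=0.8025+(c_\mathrm{jsr}/1.5\,\mathrm{mM})^4$), and a 7-state
   LCC scheme with voltage activation, calcium- and voltage-dependent
   inactivation and the printed closing rate of 3 ms⁻¹. Event times come
   from the time-dependent Gillespie construction: each channel
   integrates its total exit propensity against an exponential
   threshold, with the propensity interpolated linearly between the
   start and predicted end of the deterministic window.

3. **Junctional SR.** Each CRU owns a jSR compartment obeying
   $\dot c_\mathrm{jsr}=\beta_\mathrm{jsr}[(S-c_\mathrm{jsr})/\tau_
   \mathrm{refill}-\sum I_\mathrm{RyR}/\nu_\mathrm{jsr}]$ with the fast
   calsequestrin buffering factor
   $\beta_\mathrm{jsr}=(1+nK B/(K+c_\mathrm{jsr})^2)^{-1}$, integrated
   with linearized-implicit sub-steps.

4. **Bulk bidomain PDE.** Cytosolic free calcium, three cytosolic
   buffers (troponin C stationary, calmodulin and Fluo-4 mobile),
   network-SR calcium and the SR buffer share the volume with fixed
   fractions (cytosol 0.895, SR 0.1 of cell volume). CRU currents enter
   as spherical sources, SERCA uptake follows a Hill-2 pump, and the
   sodium–calcium exchanger acts in the bulk (density factor 2.5 near
   CRUs, 1.5 elsewhere) and as a boundary flux on the plasma-membrane
   faces (factor 0.5).

5. **Membrane potential.** A rabbit ventricular ionic model (fast Na⁺,
   inward rectifier, rapid/slow delayed rectifiers, fast/slow transient
   outward, Na⁺/K⁺ pump) with the printed peak conductances; the L-type
   current is the scaled sum of every single-channel LCC current,
   $I_\mathrm{CaL}=-2\alpha\sum I_\mathrm{LCC}$ with
   $\alpha=F\nu_\mathrm{cell}/(C_m\Omega)$, and the exchanger current is
   the spatial integral of the bulk and boundary fluxes. A
   prescribed-AP clamp mode replaces the ODE so the calcium subsystem
   can be driven alone.

## Hybrid time stepping

One iteration advances the PDE and the membrane ODE over the
deterministic step $\tau_\mathrm{det}$ chosen by the PDE error
controller, with all CRU fluxes frozen at their start-of-step values.
Channel transitions are then predicted over the window using start and
predicted end values; transitions that do not change conductance are
executed freely in batch, while conductance-changing events define the
stochastic step: $\tau_\mathrm{stoc}$ is the time by which
$\lceil 0.1 N_s\rceil$ of the $N_s$ per-CRU first events have occurred.
The deterministic states are then re-advanced to $\tau_\mathrm{stoc}$,
the clocks are re-integrated against the accepted update (so no event
triggered by the update is missed), and all due conductance changes are
realized at the end of the step. Forcing one event per step
(`force_ns1 = TRUE`) is statistically indistinguishable from the
batched rule in the test suite.

The PDE integrator is a two-stage L-stable Rosenbrock scheme with an
embedded error estimate, solved matrix-free by BiCGSTAB (relative
tolerance 10⁻⁶) with a per-cell block-Jacobi preconditioner; the six
fields couple stiffly through the buffer reactions, which the analytic
per-cell reaction Jacobian captures exactly. Three numerical choices
matter in practice and are deliberate:

* the step-error norm is a weighted RMS over all cells **excluding CRU
  source cells and their face neighbours** — a freshly switched point
  source equilibrates its own cell on a ~10 μs timescale that is
  sub-grid physics, and resolving it would trap the controller at
  ~10⁻⁴ ms steps;
* the embedded error estimate is filtered through
  $(I-\gamma\tau J)^{-1}$ so that stiff modes handled exactly by the
  L-stable scheme do not throttle the step;
* default tolerances are `rtol = 1e-4`, `atol = 1e-2` μM; a
  tolerance-tightening test confirms the averaged trace changes by well
  under 0.5% when they are tightened a hundred-fold.

# Parameters and units

All printed model constants live in `cicr_params()` and can be
overridden per run. Concentrations are μM, lengths μm (cleft geometry
nm), time ms; single-channel currents are carried as amount per time in
μM·μm³/ms (1 μM·μm³ ≈ 602 ions; multiplication by $2F$ gives 0.193 pA
per μM·μm³/ms); membrane currents are pA/pF. Worth calling out:

* `ryr$g` = 2.33 μm³/s. The per-second reading gives ~0.45 pA per open
  RyR at a 1 mM jSR load and jSR depletion over tens of milliseconds;
  a per-millisecond reading would give ~450 pA and sub-millisecond
  depletion.
* `ncx$g_naca` = 0.84 μM/ms, the source electrophysiology model's
  value. A per-second reading makes the exchanger current ~10⁻⁴ pA/pF
  and leaves the cell unable to extrude calcium at all.
* `ryr$walker2$k_close` = 0.2 ms⁻¹. The per-second reading implies a
  5 s mean open time, whose stationary diastolic open fraction (~3.5%)
  carries a standing release flux that destroys the resting state
  within ~10 ms.
* The cleft buffer factor β emulates fast dyadic buffering for the
  2-state schemes. `calibrate_beta()` chooses it so that at a
  sustained-release operating point (30% of a mean cleft open at the
  depleted quasi-steady jSR load) the largest closed-RyR mouth
  concentration is ~60 μM, which keeps the luminal-regulated opening
  rate within the sub-0.7 ms⁻¹ regime while a lone open RyR's mouth
  (~55 μM) stays in the range of spatially resolved spark models. The
  resulting default is β = 4 for both 2-state schemes; the 4-state
  scheme runs at β = 1.
* Calsequestrin constants (n = 15, B = 400 μM, K = 600 μM) are standard
  literature values; they are echoed in every run's metadata.
* The LCC calcium-inactivation thresholds (90 μM and 60 μM) apply to
  the surface-enhanced mouth concentration — they are roughly 30-fold
  larger than the source model's sub-membrane thresholds, matching the
  ~81-fold surface enhancement.
* The initial SR load (`S0 = cjsr0 = 1000` μM) is a configurable
  default recorded in the metadata.

# What the generator emulates

`sample_cru_population()` draws RyR counts from an exponential
distribution with mean 50 (minimum 1), one LCC per four RyRs, places
CRU centers on z-disc planes (2 μm spacing) on a jittered lattice at
the reference density of 320 CRUs per 15 × 15 μm disc, and apportions
the aggregate junctional-SR volume fraction (0.005 of the subvolume)
proportionally to RyR counts. Channel arrays are regular lattices
(30 nm pitch, LCCs interleaved on the offset lattice) with a 60 nm rim
margin setting the cylinder radius.

What it does *not* emulate: T-tubule geometry beyond the z-disc proxy,
non-junctional RyR clusters, anisotropic diffusion, mitochondria, or
orphaned/heterogeneous cleft architectures. Passing tests therefore
speak to the model's internal consistency and to the printed-parameter
behaviour of this idealized geometry, not to real myocyte variability.

# Problem sizes

The working presets trade resolution for turnaround on a single core:

* `subdomain` — 5 × 5 × 2 μm at the reference CRU density (~36 CRUs,
  ~1 800 RyRs + 450 LCCs). Used for the stimulated-AP experiments and
  by `scripts/acceptance.R` at 0.5 μm grid spacing. The grid-refinement
  test (halving the spacing on a single-spark configuration) bounds the
  effect on the averaged transient; the cleft physics is resolved
  analytically and the self-consistent currents are nearly
  grid-independent because they are cleft-limited, not bulk-limited.
* `zdisc` — one full 15 × 15 × 2 μm disc, 320 CRUs: mirrors the
  published single-disc runs; substantially slower.
* `micro` — 2 × 2 × 2 μm, ~6 CRUs: conservation, reproducibility and
  protocol tests.

# Design choices on open points

* **Self-coupling regularization**: the mouth is a finite pore; G is
  averaged exactly over the mouth disk (radius configurable).
* **4-state asymmetry**: λ multiplies the open-state inactivation.
  The opposite reading (attenuated closed-state inactivation) makes
  ignited clefts burn at ~40% open occupancy, incompatible with the
  sparse, slow release this scheme is reported to produce.
* **R_cru**: the bulk source/refill sphere radius equals the cleft
  cylinder radius; below grid resolution the deposit degenerates to the
  containing cell with exact renormalization, so amount transfer is
  conservative by construction (verified to ~10⁻⁵ relative over 100 ms
  in a closed system).
* **c_bulk**: averaged over grid cells within one cell of the cleft
  rim; at 0.5 μm spacing this degenerates to the containing cell.
* **APD criterion**: APD90 from stimulus onset to 90% repolarization
  between the pre-stimulus baseline and the peak; DI = BCL − APD.
* **Stimulus**: a 1 ms current injection sized to depolarize a passive
  membrane by 40 mV (a direct voltage-offset mode is available).
* **Internal sodium** is held constant (12 mM); no printed parameters
  govern its dynamics and it drifts negligibly within a beat.

# Known limitations

The desk-scale model reproduces the qualitative physiology —
stimulated APs trigger graded release, jSR depletion and refill,
dual-peak morphology under the induction-decay scheme, and a
fluorescence readout that smooths the early transient — but three
quantitative discrepancies against the published production-scale runs
remain and are visible in the acceptance report:

* **Release synchrony.** With the printed rate laws and the
  Green-function cleft, any open RyR raises its neighbours' mouths into
  the saturated activation regime, so clefts ignite as wholes and
  release synchronizes across the subdomain within a few milliseconds.
  The published runs report much sparser release (4-state maximum open
  fraction 2.7%, ~200 ms to peak) than this model produces (tens of
  percent, peak within tens of milliseconds). Correspondingly the
  excitation–contraction gain and the largest encountered opening rate
  of the luminal-regulation scheme overshoot their published values.
* **Late repolarization.** The synchronized transient keeps bulk
  calcium near ~1 μM for hundreds of milliseconds; the resulting
  inward exchanger current and calcium-inactivated L-type current leave
  the late action potential between −25 and −45 mV, repolarizing far
  more slowly than the published APs (the 4-state scheme repolarizes
  early instead, after its release transient collapses the plateau).
  Multi-beat restitution is implemented (`restitution_protocol()`) but
  is only meaningful in parameter regimes where every beat
  repolarizes.
* **Resolution.** 0.5 μm spacing concentrates each CRU's sub-grid
  buffered halo into one cell, which strengthens CRU-to-CRU coupling
  through the bulk relative to a fully resolved calculation.

These are properties of the printed parameter set under this
architecture at desk scale; the tunable knobs (β, rate-law caps, grid)
are exposed so the regimes can be explored.
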