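---
title: "Solution strategies for post-stenotic high-frequency flow: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solution strategies for post-stenotic high-frequency flow: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stenoflow)
```

# The problem

A severe carotid stenosis accelerates blood through a narrowed lumen; the
post-stenotic jet breaks down into turbulent-like flow whose high-frequency
pressure and velocity fluctuations present clinically as a bruit and as
measurable neck-skin vibration. Simulating those fluctuations credibly
forces a strategy choice: resolve them directly on a fine mesh with a
non-dissipative scheme and no turbulence model (under-resolved DNS), or
model the unresolved scales with a large-eddy-simulation (LES) sub-grid
closure on a coarser mesh. The closures differ exactly where it matters —
near walls and in transitional, not-yet-fully-turbulent flow — so the
ranking of strategies is an empirical question at a given operating point.

`stenoflow` reproduces the *structure* of that strategy study at desk
scale: a 2-D constricted channel stands in for a patient-specific stenosed
carotid bifurcation, and the full verification pipeline (refinement
ladders, Richardson extrapolation, tke and spectral analytics, closure
comparison against a fine-grid no-model reference) is implemented exactly.
The 2-D reduction is the package's single largest simplification and is
discussed throughout.

# Flow solver

## Equations and discretization

Incompressible constant-density Navier–Stokes with kinematic pressure and
an eddy-viscosity closure: the deviatoric sub-grid stress enters only
through `nu_sgs` added to the molecular viscosity; the isotropic part is
absorbed into pressure, as usual for constant-density solvers (density
divides out).

Space: a uniform staggered MAC grid — `u` on vertical faces, `v` on
horizontal faces, `p` at cell centres. Convection is discretized in
divergence form with arithmetic-mean face interpolation, which on a
staggered grid with a discretely divergence-free advecting field is
algebraically equivalent to the skew-symmetric form and conserves discrete
kinetic energy. This mirrors the kinetic-energy-preserving,
minimally-dissipative requirement that motivates using an under-resolved
DNS as a reference at all: a dissipative scheme (e.g. first-order upwind)
would itself act as an uncontrolled turbulence model. The test suite
verifies `|dKE|/KE < 1e-3` over 100 inviscid steps in a doubly-periodic
box, and second-order spatial convergence on a decaying Taylor–Green
vortex.

Time: explicit second-order Adams–Bashforth for convection and diffusion
(forward Euler on the first step), followed by an incremental
pressure-correction projection: the predictor carries the old pressure
gradient, a pressure-Poisson equation is solved for the increment, and
faces are corrected to discrete divergence-free (residual checked against
the solver tolerance every step, and the step fails loudly on NaN or
residual blow-up). Diffusion is advanced *explicitly* rather than by
Crank–Nicolson: at every operating point used here the advective CFL bound
(`dt <= 0.35 h / u_max` by default) is an order of magnitude more
restrictive than the diffusive bound (`dt <= 0.3 h^2 / nu_eff`), so an
implicit diffusion solve would add two Helmholtz systems per step for no
gain; `step()` enforces both bounds and refuses to run outside them. The
variable-viscosity diffusion term is the conservative form
`div(nu_eff grad u)` with `nu_eff = nu + nu_sgs` interpolated to faces and
corners; the transpose (stress) part, which vanishes identically for
constant viscosity in incompressible flow, is neglected for the
spatially-varying `nu_sgs` contribution.

The pressure-Poisson operator over fluid cells (Neumann at walls, inlet
and solid faces; Dirichlet 0 at the outlet ghost) is assembled once per
grid as a sparse SPD matrix and Cholesky-factorized (`Matrix`); each step
is then a pair of triangular solves. The doubly-periodic variant used by
the conservation tests solves the Poisson equation by FFT.

## Geometry, boundaries and seeding

The stenosed vessel is idealized as a planar channel of reference width
`d` with a cosine-bell constriction on both walls; an occlusion fraction
of 0.76 leaves a throat of `0.24 d`, following the NASCET
percent-diameter-reduction convention (`nascet_degree()`). Solid cells are
masked stair-step fashion; velocities on faces touching solid cells are
forced to zero (direct-forcing immersed boundary), which enforces
no-penetration exactly and no-slip to first order at the stair edge.

Defaults frozen as the package's study conditions:

* **Bell length `0.75 d`.** Severe carotid plaque is axially compact, and
  a 2-D *width* reduction substantially understates the *area* reduction
  of the equivalent 3-D stenosis (76% diameter reduction is ~94% area
  reduction, a jet ~17x the mean speed, versus ~4.2x in 2-D). A focal
  bell, with its thinner exit shear layer, is therefore the closer planar
  analog of the destabilizing severity of the real lesion.
* **Domain `4 d` long, constriction centred at `1.5 d`,** leaving room for
  the upstream slice at `-0.75 d` and downstream stations to `+1.2 d`
  plus an outflow buffer.
* **Inlet noise 1% of the mean inlet velocity,** white in time and across
  the inlet, from a seeded generator (bit-reproducible runs). A symmetric
  smooth channel has none of the natural upstream destabilization
  (secondary flow, curvature) of a real carotid geometry, so transition
  must be seeded; 1% is small enough not to contaminate the laminar
  benchmarks run without noise.
* **Working fluid water, `nu = 1e-6 m^2/s`** in dimensional
  configurations; the study runs use nondimensional units `d = 1`,
  `U_mean = 1`, where `nu = 1/Re`.
* **End time 5, washout 1** (first fifth of the record discarded from all
  statistics): `washout_flow_throughs()` expresses the discarded interval
  in flow-throughs, e.g. 2 s at 0.15 m/s over a 0.2 m model is 1.5
  flow-throughs.

Inflow is either a parabolic profile with constant flow rate (the
"peak-systolic worst case") or a pulsatile planar Womersley solution built
per harmonic of the flow-rate series, normalized so the instantaneous flux
matches the target rate to 0.1%; at high Womersley number the oscillatory
profile correctly flattens toward a plug. The outlet is zero-gradient
velocity with a fixed reference pressure. The flow-split bifurcation
outflow of a real carotid is out of scope (single outlet).

# Sub-grid closures

All three closures share `nu_sgs = (Cm * Delta)^2 * Dm(u)` with
`Delta = sqrt(cell area)` (square root of cell area in 2-D, the
filtered-volume convention; here simply `h`).

* **Static Smagorinsky**, `Cm = 0.168`, `Dm = |S| = sqrt(2 S_ij S_ij)`.
  Its known deficiency — spurious eddy viscosity wherever there is mean
  shear, laminar or not, hence improper near-wall behaviour — is exactly
  the behaviour the comparison study exposes.
* **Sigma**, `Cm = 1.5`, `Dm = sigma3 (sigma1 - sigma2)(sigma2 - sigma3)
  / sigma1^2` with `sigma1 >= sigma2 >= sigma3` the singular values of the
  velocity-gradient tensor (`Dm = 0` when `sigma1 = 0`, the limit value).
  The operator vanishes for two-dimensional or two-component flow, pure
  shear and pure rotation, and decays cubically at walls. A consequence
  worth stating plainly: **in this package's strictly planar velocity
  fields the field-level Sigma closure is identically zero**, so a Sigma
  run coincides with the no-model run on the same grid. That is the
  model's designed nullspace, not an implementation shortcut; the
  pointwise operator `sigma_dm()` retains full 3-D behaviour and is
  verified against an independent eigenvalue route and random rotations.
  In the closure ranking below, Sigma therefore represents the
  "add nothing in resolved planar shear" end of the spectrum.
* **Dynamic Smagorinsky** determines `Cs^2` per cell each step from the
  Germano identity between the grid filter and a discrete top-hat test
  filter (half-weight centre, eighth-weight face neighbours; nominal
  filter ratio 2), in the least-squares form. The numerator
  (`L_ij M_ij`) and denominator (`M_ij M_ij`) are Lagrangian-averaged:
  advected along resolved pathlines with first-order upwinding and relaxed
  over `T = 1.5 Delta (I_LM I_MM)^(-1/8)`, with negative `Cs^2` clipped to
  zero every step. The relaxation constant and exponent are those of the
  original Lagrangian-averaging formulation, the standard choice where no
  application-specific calibration exists. A frozen single-step evaluation
  (no averaging
  history) is tested for exact agreement with a brute-force loop-based
  Germano assembly, and the closure is verified to add `< 1%` of the
  molecular viscosity in laminar Poiseuille flow.

Every closure is clipped non-negative; `model = "none"` returns an exact
zero field and is verified to produce trajectories identical to
Smagorinsky with `Cm = 0`.

# Turbulence analytics

* **Reynolds decomposition** (`reynolds_decompose()`): arithmetic time
  mean over the post-washout window; used for constant-inflow records.
* **High-pass mode filter** (`highpass_modes()`): for pulsatile records a
  time mean is meaningless without phase-averaging tens of cycles, so the
  fluctuation is defined spectrally — DFT of the windowed record, modes
  `0..15` (and conjugate partners) zeroed, inverse transform. The mode
  basis is the *analyzed record*, so with a 4 s window the cutoff sits at
  4 Hz rather than 16 Hz; the cutoff index is configurable, and the
  energy split `sum(u^2) = sum(low^2) + sum(u'^2)` holds to round-off by
  Fourier orthogonality. The "1000 components" sometimes quoted for such
  decompositions is presentational and imposes no resampling.
* **tke** `= 1/2 sum_i mean(u_i'^2)`, with closed-form checks
  (`A^2/4` for a sinusoid, `3 sigma^2 / 2` for three-component white
  noise) and permutation/sign invariance.
* **Welch PSD** (`welch_psd()`): 16 segments at 50% overlap (segment
  length `floor(2N/17)`, the largest allowing exactly 16 such segments),
  Hann window, per-segment mean removal only, window-power normalization,
  one-sided. Input is the fluctuating-velocity *magnitude* signal.
  Verified: peak location, Parseval consistency to 3%, flatness for white
  noise, offset invariance.
* **Q-criterion** `= (|Omega|^2 - |S|^2)/2` (Frobenius norms), pointwise
  and as a field via centred differences to cell centres (one-sided at
  masked boundaries): zero for pure shear, `omega^2` for solid-body
  rotation, frame-rotation invariant to `1e-10`.
* **Field statistics**: `tke_field()` (Reynolds split about the
  snapshot-mean field) and `filtered_tke_field()` (per-point temporal
  mode filtering, bounded above by the unfiltered field pointwise);
  `station_tke()` produces the per-slice profiles the comparison plots
  and discrepancy metric consume.

# Convergence and resolution verification

`observed_order()` solves the generalized order equation
`(f1 - f2)/(f2 - f3) = (dx1^p - dx2^p)/(dx2^p - dx3^p)` by bisection-based
root-finding on `p` in `(0.05, 10]` to `1e-10` — necessary because real
ladders (including the shipped one: `3.04 / 1.92 / 1.44 e-4 m`) do not
halve `dx`. Non-monotone `f` sequences are rejected with the offending
levels named rather than silently extrapolated. `richardson_extrapolate()`
fits the error constant on the two finest levels,
`f_extrapol = f_fine - c dx_fine^p`, and reports per-level percent errors;
`convergence_report()` adds a security factor of 1.5 on the quoted
uncertainties. A planted-ladder round-trip (`f_i = f* + c dx_i^p`)
recovers `p` to `1e-6` and `f*` to `1e-8` relative for `p` in `[0.5, 3]`.

The shipped refinement table's quantity of interest is a space/cycle-
averaged velocity normalized by each mesh's inlet area into a volumetric
flux. The two finest rows are consistent with `f = u_mean * A * 10`
(`normalized_quantity()`'s default rule) but the coarsest row is not
consistent with any single rule — likely a typographical slip in the
source table — so the rule is exposed as configuration and all
table-driven computations consume the printed `f` column directly.

Resolution adequacy uses `eps = 2 nu <s'_ij s'_ij>` from the resolved
fluctuating strain, `mu = (nu^3/eps)^(1/4)`, the per-cell ratio `dx/mu`
(reported as 0 in fully laminar windows rather than dividing by zero), and
the wall-unit surrogate `l+ = dx u_tau / nu`. `workload()` reproduces the
cells-per-core cost accounting of the ladder.

# The comparison experiment

`run_study()` executes the three protocols (spatial refinement, temporal
refinement, LES comparison) over a shared geometry/inlet/station layout,
with per-config provenance (config hash, seed) and per-station analytics;
a failed run marks its column incomplete instead of aborting the study.
`tke_discrepancy()` is the ranking metric: the relative L2 difference of
station tke profiles, model versus reference, with the model profile
interpolated onto the reference's cross-channel coordinates so grids of
different resolution are comparable.

Two operating points carry the study's contrast: a constant peak-systolic
inflow (Re 1380) versus the pulsatile regime with mean Re 980. Because
transition thresholds in a seeded 2-D channel
differ from a 3-D patient geometry, the package maps this to two
constant-inflow Reynolds analogs preserving the 1380:980 ratio. At the
transitional point the post-stenotic jet breaks down: slice-averaged tke
at `+0.6 d` exceeds the upstream `-0.75 d` value by an order of magnitude
or more (~30x at `dx = 1/32`, growing with resolution). At the lower
analog, the closure ranking is evaluated on the *post-stenotic* stations
(`+0.6 d`, `+1.2 d`) only: upstream of the constriction both grids sit at
the seeding-noise floor, so a relative discrepancy there measures noise,
not closure physics. Under that metric static Smagorinsky — which deposits
eddy viscosity in every sheared region, damping the very instabilities
under study — lands farthest from the fine-grid reference, while Sigma
(adding nothing in planar flow) and dynamic Smagorinsky (self-calibrating
toward zero in laminar shear) land closer: the desk-scale analog of the
finding that only the Sigma and dynamic models replicate the reference
flow field at the pulsatile operating point.

## Problem sizes

The shipped tests and study runs use `dx = 1/32` (stations ladder,
transition) to `1/48` (reference run), i.e. 128x32 to 192x48 cells, with
`dt` from the CFL bound (~2900–8600 steps for 5 time units) — sizes chosen
so a full strategy comparison completes in minutes on one core while still
exhibiting transition, closure separation and second-order laminar
convergence.

# What the synthetic generators do and do not emulate

`make_waveform()` produces a deterministic 6-harmonic carotid-like flow
waveform hitting a prescribed mean (exactly) and peak (to 1%), positive
throughout the cycle, with its systolic peak near `t = 0.1 s`; it matches
the published mean/peak/period summary statistics, not any digitized
curve shape. `make_probe_signal()` plants known low-mode content plus
seeded Gaussian broadband of known variance, so the decomposition and tke
estimators are tested against machine-readable ground truth;
`make_refinement_ladder()` and `canonical_gradients()` do the same for the
convergence and closure operators.

What passing these tests shows: the numerical scheme conserves what it
must, the operators compute their defining formulas, the estimators
recover planted truth, and the closure ranking reproduces the expected
qualitative ordering in a seeded planar analog. What it does not show:
fidelity of any 2-D field to 3-D patient-specific flow — a planar channel
has no secondary flow, no curvature-induced upstream instability, no
vortex stretching (the energy cascade is qualitatively different in 2-D),
and its Sigma closure is degenerate by construction. Quantitative
magnitudes of tke, spectra and discrepancies therefore transfer only as
orderings and structural signatures, never as values.

# Known limitations

* 2-D planar domain; no bifurcation, no flow split, rigid walls, no FSI,
  Newtonian fluid only.
* Stair-step immersed walls are first-order accurate locally at the
  constriction boundary; wall-shear-derived quantities (WSS, OSI) are out
  of scope.
* The explicit diffusion treatment caps usable viscosity ratios at
  `dt <= 0.3 h^2 / nu_eff` (never binding at the study's operating
  points, but binding for very viscous configurations).
* The high-pass cutoff interpretation (modes of the analyzed record) is a
  documented choice; a period-based cutoff is available by passing a
  different `cutoff_mode`.
* Phase-averaging over many cardiac cycles, wavelet analysis and HPC
  scheduling are intentionally absent.
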