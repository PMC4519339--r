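---
title: "Methods: shear-gated wall permeability and thrombus formation in a stenosed channel"
author: "stenoclot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shear-gated wall permeability and thrombus formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(stenoclot)
```

## The model

`stenoclot` couples three ingredients on a 2D channel with a Gaussian
stenosis `f(x) = H exp(-x^2/(2 d^2))` on the lower wall:

1. **Hemodynamics.** Incompressible Navier--Stokes with a Darcy sink
   `-alpha_p(M1, M2) nu V` that represents drag of the growing fibrin gel.
   Boundary conditions: parabolic inlet (centerline speed `V0`), zero
   outlet pressure, rigid no-slip walls. The flow is assumed steady at the
   inlet; the Reynolds number is `Re = V0 Ly / nu`.

2. **Wall exchange.** A phenomenological "primary activator" `u` sits in
   the plaque tissue under the stenosed wall at concentration `u0` (window
   `|x| <= 2d`) and leaks into the lumen through a permeable wall,
   `-D_u du/dn = mu(|tau|) (u0 - u)`. The permeability `mu` is a
   continuous piecewise-linear function of the local wall shear stress
   `tau = rho nu dV_t/dn`: `mu1` (essentially sealed) below `tau1 = 10`
   dyn/cm^2, rising to `mu2` at `tau2 = 20` dyn/cm^2. In a healthy flat
   vessel the Poiseuille wall shear `4 rho nu V0/Ly` reaches `tau1` only at
   `Re = 1000`, far above physiological flows considered here -- wall
   activation requires the stenotic shear amplification.

3. **Coagulation cascade and fibrin polymerization.** Six
   reaction--advection--diffusion species: `u` (decaying precursor that
   converts to the cascade activator at rate `k_u`), activator `theta`
   (saturating autocatalysis, linear clearance, bilinear inhibition),
   inhibitor `phi` (theta-driven production with cubic self-acceleration
   and saturation at `c`), fibrinogen `Fg`, and the first two moments
   `M1`, `M2` of the fibrin chain-length distribution. The moment closure
   carries the polymer physics: weight-average length `Nw = M2/M1`,
   reptation-theory transport coefficients `bp = 1/(1 + Nw/Ne)` and
   `Df = D/(Nw (1 + Nw/Ne))`, and the filtration resistance
   `alpha_p = alpha0 M1^2 (1 - bp)` with `alpha0 = l0^4 K^2 Na^2`.
   Gelation is declared where `Nw` reaches the dilute/semidilute crossover
   `Nws = 1/(n0^{2/3} l0^2 K)` (about `1.04e4` at the default constants);
   mature gel is capped at `Nw = 100 Nws` by projecting `M2`.

A run is classified **regime II** (coagulation) if `Nw` reaches `Nws`
anywhere at a finite time `T*` (the nucleation time, reported in seconds
and in units of the kinetic scale `1/(alpha - chi1) ~ 30.8 s`), and
**regime I** otherwise.

## Numerical method

* **Mesh.** Structured body-fitted quadrilaterals through the mapping
  `(x, eta) -> (x, f(x) + eta (Ly - f(x)))`, with tanh clustering of the
  wall-normal coordinate (wall cells about `bl_factor` times the
  mid-channel size) and optional smooth streamwise refinement over the
  stenosis. Face geometry (area vectors, over-relaxed orthogonal
  coefficients, non-orthogonal correction vectors) is precomputed; every
  cell closes to machine precision.

* **Flow.** Collocated finite-volume projection: explicit first-order
  upwind convection and deferred-correction viscous fluxes, implicit Darcy
  drag, and a pressure solve whose compact two-point part is satisfied to
  a configurable tolerance, which makes the face-flux field discretely
  divergence free by construction (default `1e-8 V0/Ly` per cell).
  Non-orthogonality of the mapped mesh enters through one deferred
  correction sweep. Steady states use local pseudo-time stepping;
  transient stepping enforces the advective/viscous stability bound.

* **Scalar transport.** Convection is implicit first-order upwind
  (unconditionally stable M-matrix, Gauss--Seidel with alternating
  sweeps), diffusion explicit (diffusion numbers are ~1e-5 at the default
  step), and the activator's wall influx uses the exact one-sided Robin
  closure, which matters because the diffusive conductance `D_u/dn` of the
  wall-adjacent half cell is comparable to the opened permeability. On top
  of the upwind fluxes the default `"limited"` scheme adds a deferred van
  Leer TVD correction with a donor-cell (FCT-style) clip that caps the
  explicit antidiffusive fluxes at half the donor content per step; the
  clip guarantees positivity at any `dt` and smoothly degrades the scheme
  toward upwind in cells whose Courant number is large, while the slowly
  recirculating region behind the stenosis -- where retention accuracy
  matters -- keeps the second-order behaviour. On rough fields the
  correction can also overshoot the fibrinogen inlet maximum by a fraction
  of a percent; `Fg` is projected back onto its ceiling `Fg0` after each
  transport step (counted like the negativity clips; excursions beyond 2%
  abort).

* **Chemistry.** Cell-local backward Euler solved *exactly* in dependency
  order: `u` in closed form, the `(theta, phi)` block by a damped 2x2
  Newton, `Fg` and `M1` linear given `theta`, and the `M2` balance as a
  scalar quadratic whose continuous root is taken in closed form. A
  negative discriminant signals second-moment blow-up inside the step; the
  step is then subdivided adaptively (halving, linear work) and, below a
  floor, the state is projected onto the mature-gel cap -- which is where
  the model says it must end up. The breakage term `M2^2/M1` uses an `M1`
  floor of `1e-12` nM below which it vanishes (its analytic limit), and a
  vanishing fibrin pool is treated as monomers (`Nw = 1`).

* **Splitting.** Per step: transport of all six species on frozen
  divergence-free fluxes, then chemistry with the gel cap, then the
  closure update. The flow is re-solved quasi-statically whenever the
  saturating resistance metric `alpha_p/(1+alpha_p)` moves by more than
  `0.02` anywhere (clot growth is slow against the flow time scale); a
  fully transient mode exists and is used in verification tests. The
  resistance handed to the flow solver is capped at `1e4` cm^-2: beyond
  that the Darcy screening length (`alpha_p^{-1/2}` = 0.01 cm) is below
  any cell size used here, so the gel is already immobile and larger
  values only degrade the linear solvers' conditioning; the transported
  closure field itself is never capped.

* **A note on discrete fixed points.** The steady solver uses local
  pseudo-time steps while `step_flow()` uses one global `dt`; the
  Rhie--Chow face-flux term of the collocated projection is O(dt), so the
  two discrete steady states differ by a small O(dt) offset (~1e-3
  relative at the test resolutions). Stepping a converged state therefore
  drifts slightly toward the transient scheme's own fixed point rather
  than staying bit-identical; the tests assert contraction toward the
  same attractor.

## Verification

`verify_fixtures()` runs the analytic battery: Poiseuille profile and wall
shear (<= 1% at 32 cells/cm against `tau = 4 rho nu V0/Ly = 1.3` dyn/cm^2
at `Re = 130`), Brinkman plug-flow flattening under a strong uniform sink,
a Gaussian pulse advecting at `b V` with variance growth `2 D t` (<= 3%),
the resting-state fixed point (exact), the precursor's exponential decay
(<= 1e-6 with sub-stepping; backward Euler is first order), the activator
excitation threshold `theta* = chi1 theta0/(alpha - chi1) ~ 0.1283` nM
located by bisection on the integrator's trajectories (<= 1%), the
second-moment blow-up at `t* = 500 s` on the reduced Riccati subsystem
(<= 2%), the closure algebra identities to machine precision, the
permeability law's continuity and monotonicity, and recovery of the
cube-root scaling exponent from constructed nucleation-time data.
Conservation is audited directly: with reactions disabled, the change of
any species' total mass matches the boundary fluxes to 1e-8 relative per
step, because the finite-volume update telescopes exactly and the linear
solves are converged to 1e-12.

## Resolution, retention, and what the scaled-down runs can show

The headline phenomenology hinges on the recirculation eddy behind the
stenosis being *almost closed*: molecular diffusivities are ~3e-7 cm^2/s,
so the physical exchange time between the eddy and the through-flow is of
order 1e5 s, and even the weak activator influx through the
partially-opened wall (the shear peak at the `Re = 130`, `h = 0.5`,
`d/Ly = 0.5` point is only ~10.9 dyn/cm^2, just above `tau1`) can load the
eddy past the excitation threshold within minutes.

On affordable meshes this closure cannot be fully represented: any upwind
or TVD scheme exchanges mass across the separatrix at a rate set by the
grid. We measure this directly by seeding the eddy with a passive scalar
and timing its decay with sealed walls: the confinement time is ~10 s at
24 cells/cm with the limited scheme (about 3x better than pure first-order
upwind, and insensitive to the time step and to streamwise refinement; 32
cells/cm gives ~14.5 s). A box-model estimate then shows gel nucleation
needs confinement of order 1/(k_b + k_r) ~ 50-100 s: below that, the
eddy's artificial washout outcompetes the `4 k_p (M2 + M1)^2`
polymerization growth at any realistic wall permeability. The package's
default resolutions therefore classify the two scenario reference
parameter sets (the solid-thrombus set at `Re = 130`, `h = 0.5`,
`d/Ly = 0.5`, `mu2_tilde = 9.5`, and the floating-structure set at
`Re = 180`, `h = 0.6`, `d/Ly = 0.4`, `mu2_tilde = 12`) as stationary
(regime I), with the activator field reaching
~90% of the excitation threshold at 24 cells/cm -- the regime boundary
exists but sits at stronger forcing than in the fully resolved system.
All regime-II phenomenology (nucleation, the bounded coagulation window in
`Re`, cube-root nucleation-time scaling, the solid vs. floating scenarios)
is exercised in tests and in the acceptance script under conditions chosen
to ignite on coarse meshes; the vignette's point is that the *shift* of
the boundary is a quantified numerical artifact of scalar retention, not a
property of the model equations.

### The severe-stenosis study configuration

The scaled-down regime studies use a severe stenosis, where the shear gate
opens at low Reynolds number and all velocities (hence the artificial
washout) are small:

* geometry `h = 0.8`, `d/Ly = 0.4`, vessel length `Lx = 3` cm;
* mesh 12 cells/cm (12 cells across the narrowest gap via the body-fitted
  mapping), `bl_factor = 0.35`;
* transport step `dt = 2.5` ms -- chosen inside the temporally converged
  range: halving it moves the nucleation time by ~0.1% (43% of the
  `Re = 30` wall shear peak of 10.4 dyn/cm^2 lies above `tau1`, so this
  configuration sits in the partially-opened-wall part of the diagram);
* classification horizon `t_max = 1200` s for clotting candidates, 400-600
  s for washout/closed-wall transect points (reported as censored
  regime I when the stationarity rule has not fired).

Measured behaviour under these conditions (all recomputed by the tests and
the acceptance script, never asserted as constants): the `Re` transect at
`mu2_tilde = 100` is regime I at `Re = 10` (peak shear 3 dyn/cm^2, wall
sealed), regime II at `Re = 30` (nucleation at `T* ~ 195 s ~ 6.3` kinetic
units, first gel ~0.01 cm above the lower wall at `x ~ 0.38` cm, upstream
edge of the recirculation bubble whose reattachment sits at `x ~ 0.89`
cm), and regime I again at `Re = 45` (washout despite a fully-open wall) --
the two hydrodynamic activation thresholds. Along `mu2_tilde` in
{70, 85, 100, 130, 170} the nucleation time falls from ~330 s to ~136 s,
and with the critical value bracketed between 55 and 62 by bisection runs,
the log--log fit of `T*` against `mu2_tilde - mu2_tilde_crit` recovers an
exponent of about -0.38 (cube-root law -1/3), with the cube-law product
constant to ~13% relative spread. Shear rates stay below 10^3 1/s in
every explored run.

## Parameters that matter

| control | meaning | default |
|---|---|---|
| `resolution` | cells per cm (far field) | 24 (12--16 in sweeps) |
| `bl_factor` | wall cell / interior cell thickness | 0.35 |
| `dt` | transport/chemistry step, s | 0.02 |
| `scheme` | scalar convection | `"limited"` |
| `refresh_ds` | quasi-steady flow refresh threshold | 0.02 |
| `t_max` | censoring horizon, s | 5000 |
| `steady_tol` | stationarity (per kinetic window) | 1e-6 |
| `Re_max` | flow stability ceiling | 500 |

The stationarity rule declares regime I when the relative L-infinity
change of all six fields over one kinetic time window `1/(alpha - chi1)`
falls below `steady_tol` *and* `max Nw < Nws/2`; runs that reach `t_max`
without either are reported as regime I with a `censored` flag, which
matters near the boundary where `T*` diverges.

## Known limitations

* Steady inflow only; no pulsatility, no non-Newtonian or
  polymer-dependent viscosity, no platelet phase, 2D geometry.
* The flow's convective fluxes stay first-order upwind (robustness);
  eddy sizes are slightly diffused at the default resolutions.
* The dense-gel regime beyond the `Nw = 100 Nws` cap is not evolved.
* Regime boundaries on coarse meshes are shifted toward stronger wall
  forcing, as quantified above; mesh-converged boundary values require
  resolutions outside this package's intended scale.
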