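---
title: "Modelling pressure-pulse attenuation in viscoelastic conduits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling pressure-pulse attenuation in viscoelastic conduits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viscopulse)
```

## The physical problem

A pressure pulse launched into a fluid-filled, thin-walled tube exchanges
energy with the wall. If the wall is elastic the pulse propagates
essentially undamped (the classical water-hammer picture); if the wall is
viscoelastic, part of each cycle of wall stretching is dissipated and the
pulse decays as it travels. viscopulse models this decay for two classical
differential constitutive laws — the Maxwell model (spring `E1` in series
with a dashpot `eta`, relaxation time `tau = eta/E1`) and the Zener or
standard linear solid (a Maxwell branch in parallel with a spring `E0`) —
in the geometry of a cylindrical vascular prosthesis: inner radius `r`,
wall thickness `e`, length `L`, fluid density `rho`.

The modelling assumptions are those of 1-D linear pulse-wave theory:
incompressible fluid, plug flow, negligible fluid viscosity and convective
acceleration, wall deformation small relative to the radius, and thin-wall
membrane equilibrium `p r = sigma e`. The constructors enforce the last
one: `tube_geometry()` warns when `e/(2r) > 0.2` and refuses ratios above
0.25.

## Decay spectra

For a Maxwell wall the pressure obeys a damped wave equation with wave
speed `c = sqrt(e E1/(2 rho r))`. Separation of variables on `[0, L]`
gives, for mode `n` with `lambda_n = (n pi/L)^2`, the exponents

`mu_{1n,2n} = -1/(2 tau) ± sqrt(Delta_n)`, `Delta_n = 1/(4 tau^2) - lambda_n c^2`.

The sign convention deserves a note: decaying solutions require the
negative offset `-1/(2 tau)`, which is validated against the reproduced
overdamped rate `mu_11 = -0.555 s^-1` of the `tau = 0.2 s`, `c = 5 m/s`,
`L = 10 m` configuration. Low modes with `Delta_n > 0` are overdamped
(up to index `k = floor(L/(2 c pi tau))`), all higher modes underdamped
with the universal envelope `exp(-t/(2 tau))`. Exact critical damping is
classified inside a floating-point window `|Delta_n| < 1e-12/(4 tau^2)`;
it is treated with the overdamped (repeated-root) formulae.

For a Zener wall the pressure satisfies a third-order equation of
Moore–Gibson–Thompson type, and each mode's rate `1/tau_n` is a root of

`x^3 - x^2/tau + lambda_n (c0^2 + c1^2) x - lambda_n c0^2 / tau = 0`.

`zener_mode_roots()` evaluates the closed-form (Cardano) solution and, when
the resolvent discriminant is negative — the casus irreducibilis, where the
literal radical formula needs complex cube roots and cancels
catastrophically — the trigonometric three-real-root form. Every call is
cross-checked against the companion-matrix roots from `polyroot()`; the two
must agree to 1e-9 relative to the spectral radius, otherwise the function
aborts rather than return silently wrong rates. Matching is by nearest
neighbour, not lexicographic sorting, because conjugate pairs differ in
their last bits between the two algorithms. The most cancellation-sensitive
published case (`tau = 0.05 s`, mode 1, decay constant 45.11 s) is part of
the test suite at the ±1 % tolerance appropriate to it.

As `n` grows the slowest root approaches the essential spectrum
`1/tau_inf = min((1/tau) E0/(E0+E1), (1/(2 tau)) E1/(E0+E1))`; its
reciprocal is the equivalent time constant `tau_eq` that turns the modal
picture into a single spatial envelope `exp(-x/(c tau_eq))`. The envelope
description is trusted when `tau^2 c^2 >= 1 m^2`; the raw product is always
reported (`validity_condition()`) so users can apply stricter margins.
One printed annotation of the source formulae deserves correction: on the
`E1 < 2 E0` branch `tau_eq = 2 tau (E0+E1)/E1` always exceeds `3 tau`
(not "between `2 tau` and `3 tau`"); both branches are bounded below by
`3 tau`, attained continuously at `E1 = 2 E0`. The package implements and
tests the correct bound.

## Method-of-lines simulation

`simulate_maxwell()` and `simulate_zener()` discretize space with
second-order centred differences on `N` interior nodes (`h = L/(N+1)`) and
integrate the resulting 2N- or 3N-state systems with the adaptive
Dormand–Prince 4(5) pair (deSolve's `ode45`) at `rtol = 1e-8`,
`atol = 1e-10`. The inlet carries a heartbeat pulse
`f(t) = (p_max/2)(1 - cos(2 pi t/T))` for `t <= T`; its rate enters the
Zener system analytically, never by numerical differentiation. The outlet
is pinned to zero pressure, with the Zener rate state mirrored
(`r_{N+1} = r_{N-1}`). This mirrored closure is unconventional; together
with the formally overdetermined corner condition of the continuous
problem, it is accepted as-is and its effect is confined to the outlet
neighbourhood, which the default time horizon never lets the pulse reach:
`t_end = 0.9 L/c` stops the run before outlet reflections can contaminate
the field.

Defaults: `N = 512`, snapshots every 0.15 s. `measure_decay()` extracts the
travelling peak per snapshot (global maximum restricted to `x > 2h`, with
three-point parabolic refinement of both position and amplitude to remove
grid quantization) and regresses log-amplitude on position; it reports the
decay length, `tau_fit = d/c`, the fit's R², and a low-confidence flag when
R² < 0.9. Problem sizes used by the checks: the convergence study halves
`h` from `N = 800` to `N = 1600` on the 10 m validation tube, where the
measured decay length changes by about 0.2 % (at `N = 512` the residual
discretization error of the measured decay length is itself about 1 %,
which is why the study is run from 800). The simulator-versus-theory
comparisons run at `N = 512`.

## What the simulations show — and where the envelope fails

In the valid regime the measured constants bracket as predicted: the
underdamped Maxwell run (`tau = 2 s`, `c = 5 m/s`) fits
`tau_fit = 4.04 s ≈ 2 tau`, and the Zener run (`tau = 2 s`, `c0 = 4`,
`c1 = 3 m/s`) gives `tau_fit = 11.45 s`, between the essential-spectrum
limit 11.11 s and the first-mode constant 11.59 s. When
`tau^2 c^2 < 1 m^2` (e.g. `tau = 0.05 s`) no single exponential describes
the field: the measured constant (≈ 0.9 s) matches neither the first-mode
(45.11 s) nor the limiting (0.278 s) constant, the decay being a weighted
mixture — the package reproduces this failure mode rather than papering
over it.

Two further limitations, found empirically and retained as documented
boundaries of the method rather than hidden:

* the travelling *peak* decays with the complex-root constant
  `2 tau (E0+E1)/E1` on **both** branches; `tau_eq` describes the peak only
  where `E1 < 2 E0`. On the opposite branch `tau_eq` is the slower,
  real-root (equilibrium) rate, which the peak does not follow within a
  pre-reflection window;
* the envelope describes a pulse of period `T` only while the pulse is
  short relative to the decay time (`tau_eq` of order ten `T` or more; the
  PDMS case has `tau_eq = 8.5 T`). For `tau_eq` comparable to `T`,
  simulated peak attenuation deviates from the envelope prediction by tens
  of percent even where `tau^2 c^2 >= 1 m^2`.

The design-map cross-validation therefore samples the regime where the
theory claims applicability (`E1 < 2 E0`, `tau^2 c^2 >= 2.5 m^2`,
`tau_eq >= 8 T`), where simulated attenuation lands within 10 % of the
target; the boundaries above tell a designer when to distrust the map and
simulate instead.

## Synthetic cyclic testing and parameter identification

The generator emulates a 1 Hz uniaxial sinusoidal protocol on a tensile
strip: strain `eps(t) = offset + amplitude sin(2 pi f t)`. The defaults
cycle one-sidedly from 0 up to 7 % (`offset = amplitude = 0.035`): a
gripped strip cannot sustain negative strain, and the one-sided cycle is
also what makes the Zener model identifiable from a single-frequency test —
the steady cycle determines the complex modulus `E*(omega)` (two numbers)
plus, through the mean stress over mean strain, the equilibrium modulus
`E0`. A zero-mean protocol leaves a one-dimensional parameter ridge that
only the brief start-up transient breaks. Both parameters remain user-set
since real protocols vary; noise is additive Gaussian on the stress, scaled
by the noiseless signal's standard deviation, under a caller-supplied seed
that never touches the global RNG state.

Fitting minimizes the mean orthogonal distance between the experimental and
simulated curves in the z-normalized stress–strain plane (each axis
normalized by the experimental mean and standard deviation, making Pa and
dimensionless strain commensurable; exact point-to-segment projection onto
the simulated polyline). Whether to normalize at all was an open choice;
normalization is scale-free and is recorded in the fit output. The
optimizer is Nelder–Mead over log-parameters (positivity by construction,
`reltol = 1e-8`, up to 2000 iterations, a restart-from-endpoint polish on
non-zero convergence codes, and jittered ±50 % restarts). Initial values
are not guessed: a sine/cosine regression over the second half of the
record yields the storage and loss moduli and the mean-stress estimate of
`E0`, from which `(E0, E1, tau)` follow in closed form — this lands the
simplex in the correct basin, which matters because the nearest-segment
objective is multimodal. The stress response inside the objective uses the
closed-form per-segment solution of the linear constitutive ODE (exact for
piecewise-linear strain, evaluated as a linear recursion), which is both
faster and more accurate than re-running the adaptive integrator thousands
of times; the two paths are cross-checked against each other in the tests.
The initial stress is taken from the first experimental sample.

What the generator does not emulate: instrument drift, grip compliance,
waveform distortion, and the wall-thickness corrections of a flattened-tube
specimen. Passing recovery tests therefore demonstrates correctness of the
estimator under the stated protocol, not robustness to every laboratory
artefact.

## Inverse design

`required_tau()` inverts the attenuation formula: with
`kappa = tau_eq/tau` from the applicable branch
(`2(E0+E1)/E1` if `E1 < 2E0`, else `(E0+E1)/E0`),
`tau = L_device/(c kappa ln(1/(1-a)))`. `build_design_map()` evaluates this
over a log-spaced 100×100 grid spanning 0.01–10 MPa in each modulus
(resolution and spacing are package choices; the range is the studied one)
and masks feasibility by `tau^2 c^2 >= 1 m^2`. The `tau` surface is
non-smooth across `E1 = 2 E0` because the branch formula switches there;
this is a property of the formulae, not an artefact. A useful consequence
of the inversion: along one map, `c tau_eq = L_device/ln(1/(1-a))` is
constant, so feasibility reduces to `kappa <= c tau_eq` — which is why 5 %
in 100 mm is infeasible over the whole grid (it would need
`kappa < 1.95`, while `kappa >= 3` always) and becomes feasible at 200 mm.

## Degenerate inputs and numerical tie-breaks

`E0 = 0` is admitted and reduces every Zener code path to Maxwell exactly
(tested at the constitutive, spectral and field level); `tau_eq` is then
infinite and the predicted attenuation zero, consistent with the envelope
of an undamped equilibrium mode. Repeated cubic roots, exact critical
damping and the `E1 = 2 E0` branch boundary are all handled by explicit
windows or continuity, each with a test. Snapshot times are deduplicated
against floating-point `seq` end effects.

## Known limitations

Single straight segment only: no reflections, bifurcations, curvature or
wave re-superposition; no fluid viscosity or convective terms; linear
small-strain constitutive laws without temperature dependence or fractional
elements; the envelope validity boundaries described above. Mode-amplitude
reconstruction from arbitrary initial conditions is out of scope — the
simulator provides full fields instead.
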