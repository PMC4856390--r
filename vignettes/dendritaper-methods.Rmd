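---
title: "Passive voltage and optimal taper in dendritic cables: models and methods"
author: "dendritaper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Passive voltage and optimal taper in dendritic cables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendritaper)
```

## The model

A passive dendrite of radius $r(x)$ (µm) at arclength $x$ from the soma
obeys the generalised cable equation for the voltage $v(x,t)$ above rest,

$$\tau \frac{\partial v}{\partial t} = -v +
\frac{1}{2 r_a g_l\, r(x)\sqrt{1 + r'(x)^2}}
\frac{\partial}{\partial x}\!\left[r^2(x) \frac{\partial v}{\partial x}\right],$$

with axial resistivity $r_a$ (Ω cm), specific membrane conductance $g_l$
(S/cm²) and membrane time constant $\tau$ (ms).  The
$\sqrt{1 + r'^2}$ factor is the slant correction to the lateral membrane
area of a tapering frustum.  All radii in this package are radii, not
diameters — the classic factor-two error with SWC files is avoided by
construction, since SWC column six is also a radius.

Two length scales govern the solution: the local electrotonic length

$$\lambda(x) = \sqrt{\frac{r(x)}{2 r_a g_l}},$$

over which voltage decays e-fold on a locally uniform cable, and the
taper e-fold length $r/|r'|$.  Their ratio

$$\epsilon(x) = \lambda(x)\,\frac{|r'(x)|}{r(x)}$$

is the package's operational definition of the slow-taper parameter: the
fractional radius change per space constant.  The asymptotic solution
below treats the radius as varying slowly, and is accurate where
$\epsilon$ is small.  (The published account of this method reports
per-class distributions of a small parameter but never prints its
formula; the definition above is a declared convention of this package,
chosen because it is local, dimensionless and exactly zero for
cylinders.)

## First-order multiple-scales solution

Treating the taper as a slow variable, the steady-state voltage at
leading order is a WKB-type two-exponential form in the cumulative
electrotonic coordinate $\Lambda(x) = \int_0^x \mathrm{d}s/\lambda(s)$,
with a $\sqrt{\lambda(x)}$ amplitude prefactor.  For a point current
$I$ at $x'$, with voltage decaying towards the soma on the proximal side
and a sealed distal end at $L$, the coefficients close in terms of
$R_{1/2}(x') = r_a \lambda(x')/(2\pi r^2(x'))$ (half the local
semi-infinite input resistance) and the distal reflection ratio

$$k(x') = \frac{2 - \lambda'(L)}{2 + \lambda'(L)}
          \, e^{-2(\Lambda(L) - \Lambda(x'))},$$

giving the input resistance $R(x') = R_{1/2}(1 + k)$ and the two-sided
voltage reconstruction implemented in `greensCoefficients()` /
`voltageApprox()`.  Two conventions deserve note:

* **Amplitude anchoring.** We write
  $v(x) = \sqrt{\lambda(x)/\lambda(x')}\,[\dots]$, anchoring the
  prefactor at the injection site.  With this choice $B_1$ *is* the
  input resistance times the current, and the solution is exactly the
  classical closed form on cylinders (tested to $10^{-6}$ relative; no
  residual constants need fixing).
* **Degeneracy guard.** The closed form requires
  $|\lambda'(L)| < 2$; steeper distal collapse is outside the validity
  of the first-order solution and is rejected with an error rather than
  silently extrapolated.

The transfer ratio to the soma,
$t(x') = v(0,x')/v(x',x') = \sqrt{\lambda(0)/\lambda(x')}e^{-\Lambda(x')}$,
is implemented in `currentTransfer()`.

## The numerical oracle

`solveSteady()` discretises the steady equation in conservative (flux)
form on a uniform grid: interface fluxes $r^2_{i+1/2}(v_{i+1}-v_i)/dx$,
membrane terms $2 r_a g_l r_i \sqrt{1+r_i'^2}\,w_i$, end cells of width
$dx/2$.  This makes the system matrix symmetric, so reciprocity of the
Green's matrix holds to round-off ($<10^{-14}$ observed), the discrete
divergence theorem gives exact current balance (`currentBalance()`), and
the scheme converges at second order (measured error ratio 4.00 on
halving $dx$).  The $\sqrt{1+r'^2}$ factor is *included* here while the
asymptotic solution drops its $O(\epsilon^2)$ contribution — the
difference is part of what oracle comparisons measure.  The default grid
keeps $dx \le \min_x \lambda(x)/200$.

Boundary conditions: `sealed` (zero flux), `killed` (clamp), and
`matched_infinite` — a Robin load equal to the input conductance of a
semi-infinite uniform collar, emulating decay to zero at $-\infty$ on a
finite grid (validated against an explicit 10$\lambda$ collar to 0.2%).
By default the collar continues the profile's own proximal radius; a
fixed `loadRadius` can be imposed instead, which matters for optimality
comparisons (below).

Units are converted in exactly one place (assembly): µm/nA/mV/MΩ at the
interfaces, cm/A/V/Ω/S internally, so that MΩ × nA = mV.

`solveTransient()` integrates the time-dependent equation with
Crank–Nicolson stepping (unconditionally stable, second order), with a
short backward-Euler startup (four quarter-steps) that damps the
non-physical ringing trapezoidal schemes exhibit after a step turn-on;
by $t = 20\tau$ the transient matches the steady solve to $10^{-8}$.
`solveTreeSteady()` assembles the compartmental analogue on a branched
morphology (axial frustum conductances $\pi r_1 r_2 / r_a l$, slant-area
membrane split half to each end node) and agrees with the cable solver
to 1% on unbranched chains.

## Synthetic cables and trees

`makePeriodicCable()` generates the rough artificial dendrites used to
probe the approximation: a raised-cosine oscillation per period, one
uniform random amplitude per period, alternating sign so the profile is
continuously differentiable and oscillates about its mean.  The
smoothing ladder doubles the period and halves the amplitude per rung.
The package's study conditions — mean radius 1 µm, length 2000 µm, base
period 400 µm, base amplitude 0.5 µm, blowfly passive parameters — were
fixed once so the three rungs span the visibly-rough to nearly-smooth
regime (median $\epsilon$ roughly 0.4 down to 0.05); with them the
maximal relative error of the analytic solution against the oracle falls
strictly along the ladder (about 30% → 4% → 1%) for every seed tried.
What the generator does *not* emulate: measurement noise of real
reconstructions, spines, non-circular cross-sections, and abrupt branch
transitions; passing the ladder therefore shows convergence of the
asymptotics with smoothness, not fidelity to any particular cell class.

`makeRandomTree()` grows strictly binary rooted trees with uniformly
drawn branch lengths and randomly perturbed 3-D directions; radii are a
placeholder for the radius-assignment algorithms.

## Current-transfer functionals and the optimal taper

The variational question is which taper $r(x)$, at fixed length $L$,
distal radius $r_L$ and volume $V$, best conveys current from
distributed sites to the soma.  Two functionals appear:

* the **delivered-voltage functional**
  $J = \int_0^L v(0,x')\,\mathrm{d}x'$, whose leading-order integrand is
  $\lambda^{-7/2}(x') e^{-\Lambda(x')}$ up to a proximal-boundary
  constant.  `transferFunctionalJ()` evaluates it with the boundary
  constant made explicit (`anchor = "proximal"` multiplies by
  $\lambda(0)^{7/2}$), so that profiles with different proximal radii
  are compared as seen by a *common* downstream load;
* the **summed transfer-ratio functional**
  $T = \int_0^L t(x')\,\mathrm{d}x'$ with bounded integrand
  $t \le 1$, `transferRatioFunctional()`.

Setting the first variation of $J$ to zero (neglecting the distal
reflection term) forces the electrotonic slope to a constant,
$\mathrm{d}\lambda/\mathrm{d}x = -2/7$, i.e. a *quadratic* radius
profile $r(x) = \alpha(L - x)^2 + r_L$;
`eulerLagrangeResidual()` reports the pointwise residual
$\lambda'(x) + 2/7$, which is identically $2/7$ for a cylinder and
vanishes in the interior for the stationary quadratic
(`alphaStationary()` gives $\alpha = 8 r_a g_l/49$).  In practice
$\alpha$ is fitted to the volume (`fitAlphaVolume()`, closed form) or to
the proximal radius (`fitAlphaProximal()`).

Stationarity, however, is weaker than optimality, and the package is
explicit about what each functional can support:

* $J$ has **no interior maximum** under the $(V, r_L)$ constraint set.
  Its second variation is indefinite at every constant-slope profile,
  and direct search finds degenerate improvements (a choked proximal
  end decoupling the cable from its load, with surplus volume parked in
  an electrically disconnected distal reservoir).  These improvement
  directions violate the slow-taper assumption under which the
  functional was derived.  Comparisons of *smooth canonical shapes*
  under $J$ are still meaningful and favour the quadratic: at equal
  volume, length and distal radius it beats the cylinder and the linear
  frustum by large margins both at leading order and by the oracle's
  $\int G(0,x')\,\mathrm{d}x'$ under a fixed somatic load.
* $T$ is bounded and has a genuine interior optimum under the volume
  constraint, attained again on a quadratic taper, now with
  electrotonic slope $-2/9$ (the Euler–Lagrange equation of
  $\Lambda'^{1/2}e^{-\Lambda}$ with a volume multiplier;
  `makeStationaryTaper()` constructs it).  Empirically, 2%-amplitude
  smooth volume-preserving perturbations (`perturbVolumePreserving()`,
  which pins both terminal radii — the constraint set of the
  variational problem — and restores the volume in closed form) fail to
  increase $T$ in ≥ 98% of 200 seeded trials, the rare exceptions being
  quadrature-noise ties in the distal region where the neglected
  reflection term lives.

The family is the same in both cases — radius quadratic in distance
from the distal end — which is the substantive claim; the two
functionals simply pin different members of it.

## Non-parametric segment optimisation

`optimizeSegments()` re-implements the classic numerical check: seven
equal segments, derivative-free Nelder–Mead simplex search
(`stats::optim`) over the middle segment radii, the proximal segment
solved from the volume constraint, the distal segment fixed at $r_L$,
objective evaluated with the finite-difference oracle on the
piecewise-constant profile, best of 10 seeded random restarts (each
restart rescaled into the feasible volume region).  The default
objective is the summed transfer ratio; the delivered-voltage objective
is available behind a flag but documented as degenerate.  The proximal
load is fixed at the equal-volume cylinder radius so every candidate
sees the same downstream conductance.

On three geometries spanning total electrotonic lengths of roughly 3.6
to 4.4 (lengths 900–1100 µm, distal radius 0.2 µm, volumes 5–6× the
distal-cylinder floor, blowfly parameters) the optimised radii are
monotone, fitted far better by a quadratic than by a line, and agree
with the volume-fitted quadratic to ~12–13% RMS over the distal six
segments.  Outside this window the agreement degrades for the same
reason noted in the original account of this protocol: electrotonically
short cables gain from the sealed-end rise in distal input resistance
that the reflection-free theory ignores, and very long cables gain from
pinching off their electrically invisible far end.  Runtime is kept to
seconds per geometry with a 288-point oracle grid per evaluation.

## Mapping the optimal taper onto branched trees

`apparentLengths()` implements the post-order pass that collapses a
subtree into an equivalent unbranched length via Rall's rule,
$l_0 = (l_1^{3/2} + l_2^{3/2})^{2/3}$ (extended to higher-order branch
points by the same power sum).  `distributeRadii()` then walks the tree
from the root: the radius tapers quadratically with $L$ set by the local
apparent length, and at every branch point the daughter radii satisfy
$r_0^{3/2} = r_1^{3/2} + r_2^{3/2}$ exactly, with the split between
daughters governed by `ratioRule`:

* `"literal"` (default): $r_1 : r_2 = l_1^{3/2} : l_2^{3/2}$, the
  printed form of the rule this algorithm derives from;
* `"linear"`: $r_1 : r_2 = l_1 : l_2$, the unique rule that makes the
  apparent-length combination an exact conductance continuation.

Both satisfy the Rall invariant to $10^{-15}$; the choice is exposed
because the source formula's exponent placement is ambiguous.  Radii are
floored at $r_L$ (floor events are counted in the provenance).
`matchVolume()` wraps the distribution in a bisection on the proximal
radius (geometric bracket expansion, guaranteed convergence on the
monotone volume map) until the optimal tree's volume matches the
original to 0.1% by default.

`transferMap()` computes per-node transfer ratios to the root from one
dense factorisation of the compartmental matrix, and
`equalisationIndex()` summarises dendritic democracy as the coefficient
of variation of those ratios.  The root is a sealed terminal compartment
by default; a lumped soma conductance is available, and the package's
tree experiments use one (6.3 nS, the leak of a 10 µm-radius somatic
sphere at the blowfly membrane conductance), because on a sealed
soma-less tree the transfer comparison is distorted by the enormous
local input resistance of thin distal branches.  Study conditions for
the seeded-tree experiments: 20 binary trees of 16 tips, branch lengths
150–350 µm, constant 0.5 µm radii as the reference, distal floor 0.1 µm,
blowfly parameters.  Under these conditions the volume-matched optimal
taper raises mean transfer in 20/20 trees and lowers the transfer CV in
20/20 — the ordering constant-vs-optimal seen in cross-class
morphology comparisons.  On electrotonically compact trees (a few
hundred µm of path) the ordering can invert; taper optimality is a
statement about cables long enough for attenuation to matter.

## Numerical choices and degenerate inputs

* Quadrature is cumulative trapezoid and differentiation central
  differences on the same uniform grid everywhere (`pracma`), so
  Euler–Lagrange residuals are not dominated by scheme mismatch;
  $\lambda'(L)$ uses a one-sided second-order stencil.
* Injection sites snap to the nearest grid node; the snapped site is
  reported and shared between analytic and numerical solutions in
  comparisons.
* The point source enters the discrete system as a cell-integrated
  delta, consistent with the weak form of the flux discretisation.
* Zero-length SWC edges are collapsed in `pathToProfile()` (keeping the
  distal radius); trees with cycles, duplicate ids, multiple roots or
  non-positive radii are rejected by class validity.
* Degenerate optimisation inputs (volumes below the $r_L$ floor,
  proximal radius below distal) raise errors rather than clamping.
* All generators and stochastic routines take an explicit seed and
  restore the caller's RNG state.

## Limitations

The package implements the *first-order* steady asymptotics: the
second-order correction, analytic transients and analytic branched-tree
solutions are covered only by the numerical oracle.  Active
conductances and conductance-based synapses are out of scope.  The
optimality results are passive, steady-state statements under fixed
volume and terminal radii; they do not model the cost of building or
maintaining dendrite, nor activity-dependent signalling, and on
electrotonically compact structures the taper advantage vanishes.
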