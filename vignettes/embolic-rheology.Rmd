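---
title: "Modeling the rheology and delivery of non-adhesive embolic agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the rheology and delivery of non-adhesive embolic agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embolrheo)
```

## The problem

Non-adhesive embolic agents (EVOH copolymer in DMSO with suspended tantalum,
marketed as Onyx-18 and Squid-12) occlude the racemose vessel network of an
arteriovenous malformation (AVM). Their clinical behaviour hinges on two
rheological facts. First, they are strongly shear-thinning: viscosity rises
steeply as shear rate falls below ~10 1/s, which is exactly the transition
the agent experiences when it leaves the fast, narrow catheter for the wide,
slow AVM nidus. Second, their viscosity is *thermally activated*: the agent
is drawn up at operating-room temperature (~20 °C) and works at body
temperature (37 °C), between which its viscosity drops by roughly 40 %.
This package models both effects and propagates them through two
reduced-order delivery models: a 1D resistance network of the catheter +
AVM geometry and a lumped warm-up model of the intracorporeal catheter.

## Constitutive models

The workhorse is the Sisko model,

$$\mu_{\mathrm{eff}}(U) = \mu_0 + k\,U^{\,n-1},$$

with $\mu_0$ the limiting (high-shear) viscosity in mPa·s, $k$ the
consistency coefficient and $n$ the dimensionless flow index. Unlike the
bare Ostwald–de Waele power law $\mu = k U^{n-1}$ (also provided), it has a
finite Newtonian plateau at high shear. `embolic_sisko_params()` ships the
published empirical constants for both agents at both anchor temperatures.
Two interpretation choices are deliberate:

* **Units.** The published constants carry no explicit units; we interpret
  $\mu_0$ and $k$ in mPa·s (cP). The 37 °C plateaus then come out at ~18 cP
  for Onyx-18 and ~12 cP for Squid-12, matching the products' nominal
  centipoise designations — a strong consistency check.
* **Negative flow indices.** Two of the four sets have small negative $n$,
  and Squid-12 at 37 °C has $n = -0.5586$. We keep $n$ unconstrained in
  sign, as printed. A consequence discussed under *Numerical choices* is
  that the implied stress–shear-rate law $\tau = \mu(U)\,U$ becomes
  non-monotone below $U^* = (k(1-n)/\mu_0)^{1/(1-n)} \approx 0.15$ 1/s for
  that parameter set, i.e. the extrapolated law is mechanically unstable
  below the measured shear range.

The constants are calibrated on 0.1–10 1/s; above ~10 1/s viscosity is
effectively a temperature-dependent constant, and the Sisko form should not
be trusted much beyond the measured window (0.1–100 1/s).

## Fitting

`fit_sisko()` minimizes least squares in **log viscosity** — residuals on
the natural scale would be dominated by the low-shear decade, where
viscosity is an order of magnitude larger. The optimizer is
Levenberg–Marquardt (`minpack.lm::nls.lm`) with box bounds
$\mu_0, k \ge 0$ and $n$ free. Starting values follow the geometry of the
model: $\mu_0$ from the highest-shear point, $k$ from the low-shear excess
over that plateau, $n = 0$. The residual-function interface is used rather
than a model formula because it stays well-defined for degenerate data
(e.g. an exactly constant curve, which a formula-based fit rejects with a
singular gradient; here it cleanly returns $\mu_0 \approx$ the constant and
$k \approx 0$). The default fitting window is 0.1–10 1/s, the range the
model represents well; windows are configurable. Noiseless round trips
through the synthetic generator recover all four published parameter sets
to ~10⁻¹⁴ relative, and the tests pin this at ≤ 0.1 %.

`fit_piecewise()` provides the representation used to feed flow curves to
CFD codes: a continuous piecewise-linear function of $\log_{10} U$ in
$\log_{10}\mu$ (both axes are logarithmic on the usual flow-curve plots,
and a pure power law is exactly linear there). Continuity is not imposed as
a constraint but built into the basis — intercept, slope, and one hinge
term $\max(x - t_j, 0)$ per breakpoint — so ordinary least squares yields
the optimal continuous fit, and nesting guarantees the residual can only
fall as breakpoints are added. Default breakpoints are {1, 10} 1/s,
separating the pseudoplastic, transition and plateau regimes. Outside the
data range evaluation continues along the end segments.

## Temperature interpolation

Viscosity was measured only at 20 °C and 37 °C. Between (and mildly
beyond) the anchors, `eval_temperature_interpolated()` interpolates
$\log\mu$ linearly in $T$ — an Arrhenius-like form, the simplest strictly
positive interpolant that is exact at both anchors. This is a modeling
choice of the package, not a measured law; it is monotone in $T$ whenever
the warm anchor is thinner than the cold one (true for both agents at all
shear rates of interest). Temperatures in [15, 45] °C outside the anchor
interval are allowed but flagged as extrapolation; beyond that the function
refuses.

## The nonmonotonic zone and its detector

At physiological temperature the measured curves show a localized dip in
viscosity — about 30 % deep — near 1 1/s, which plausibly aids the even
redistribution of the agent from the nidus into small vessels.
`detect_nonmonotonic_zone()` characterizes such a dip as a *shoulder*
(local maximum) followed by a *bottom* (local minimum) with
`relative_drop` $= (\mu_{\max}-\mu_{\min})/\mu_{\max}$.

Two operational definitions deserve explanation:

* **Monotone envelope.** On a shear-thinning baseline, the points before a
  dip are all higher than the dip itself, so "local maximum" is ambiguous
  on the raw curve. The detector therefore compares the (median-smoothed)
  curve with its best monotone-decreasing least-squares approximation
  (antitonic regression, PAVA): the dip bottom is the point furthest below
  that envelope, the recovery peak is the discrete maximum after it, and
  the shoulder is the last pre-dip point still at recovery height. On a
  monotone curve the envelope residual vanishes and the detector returns
  `NULL` — absence of a zone is a result, not an error.
* **Smoothing width 3.** The moving median is there to reject single-point
  instrument spikes. At the typical ~10 points/decade sampling, a 5-point
  median spans half a decade and measurably erodes a ±0.3-decade dip
  (biasing the measured depth from ~0.30 to ~0.24 and displacing the
  minimum); a 3-point median is the narrowest robust choice and preserves
  both depth and location. A detection floor `min_drop = 0.05` keeps
  ordinary 5 % multiplicative noise on a monotone curve from being reported
  as a zone.

## The synthetic generator

`generate_curve()` emulates a cone-plate viscosity-curve test:
$$\mu(U) = S(U)\,\bigl(1 - A\,e^{-(\log_{10}U - \log_{10}c)^2/2\sigma^2}\bigr)\,\varepsilon,$$
a Sisko base $S$, an optional Gaussian-in-log-shear dip (amplitude $A$,
center $c = 1$ 1/s, width $\sigma = 0.15$ decades by default — a localized
feature spanning ~±0.3 decades), and multiplicative lognormal noise with
median 1 (viscosity is positive and spans decades, so scatter is naturally
relative; the default $\sigma_{\mathrm{noise}} = 0.05$ is a stand-in for
unpublished replicate variance, not a measured value). The default grid is
30 log-spaced points over 0.1–100 1/s, the plotted range of typical flow
curves. Generation is deterministic per seed and leaves the caller's RNG
stream untouched.

What the generator does *not* emulate: rheometer hardware artifacts
(inertia, secondary flows, evaporation), thixotropy, yield stress, and the
true replicate covariance structure. Passing tests therefore demonstrate
the estimators' correctness under the assumed noise model, not robustness
to every failure mode of real instruments.

The unmixed-tantalum variant (`unmixed_tantalum_params()`) keeps $\mu_0$
and halves $k$: the clear copolymer solution left when the contrast powder
has settled agrees with the suspension near the high-shear plateau and
diverges from it increasingly below 1 1/s.

## The 1D network model

`solve_network()` replaces 3D CFD with a Poiseuille resistance network —
appropriate because every default scenario is deeply laminar (Re ≲ 1 in
the catheter, smaller in the nidus) and the aim is trends, not fields. The
geometry is catheter → feeder → {racemose bundle ∥ optional 4 mm fistula}
→ drainer. Per tube, $\delta p = 32\mu l c/d^2$ with the viscosity
evaluated at the tube's own Poiseuille wall shear rate $8c/d$ (the exact
shear-dependent velocity profile is deliberately not resolved). Segment
lengths and the 10-tube racemose count are plausible AVM-scale defaults
(feeder/drainer 20 mm × 3 mm, racemose tubes 10 mm each, catheter
1 m × 2 mm) and are fully configurable; delivery defaults are 0.6 mL/min
and density 1100 kg/m³.

Numerical choices:

* **Shear-rate clamp.** Network viscosities are evaluated with the shear
  rate clamped to the measured window 0.1–100 1/s (constant extrapolation
  beyond). Without the clamp, Squid-12's $n < 0$ law makes a branch's
  pressure–flow relation $\delta p \propto \mu_0 q + \mathrm{const}\,q^n$
  *diverge* as $q \to 0$: a 4 mm fistula would then appear infinitely
  resistive at small flows and the solver could equilibrate in an
  unphysical state with the whole flow squeezed through 0.5 mm vessels.
  The clamp restores a monotone closure at small flows and confines the
  constitutive law to where it was calibrated.
* **Exact parallel split.** The racemose/fistula split is found by scalar
  root finding (`uniroot`, bracket $(0, Q/N)$, tolerance $10^{-14} Q/N$)
  on the pressure-equality residual with the shear-consistent viscosities
  evaluated inside the residual. The outer viscosity fixed point
  (viscosity → flows → shear → viscosity, tolerance $10^{-8}$, cap 200)
  then converges in at most two iterations — one for a Newtonian fluid,
  whose viscosity update is exactly zero. A naive conductance-split fixed
  point was tried first and crawls ($O(1/k)$) near the constitutive fold
  described above. Mass conservation holds to rounding by construction
  ($q_f = Q - N q_r$); parallel pressure balance is limited only by the
  root-finder tolerance (observed ~10⁻¹⁵ relative).
* **Failure semantics.** Non-convergence returns a flagged solution with
  the last iterate and defect norms rather than throwing; diameter sweeps
  flag failed rows and continue.

`sweep_diameters()` re-solves over racemose diameters 0.5–2 mm, with and
without fistula, and reproduces the qualitative trends of the full 3D
computations this model abstracts: racemose pressure drop falling steeply
(~$d^{-4}$) with diameter, the fistula short-circuiting the nidus at every
diameter, and the more viscous Onyx-18 requiring more driving pressure than
Squid-12 on identical geometry at 37 °C. Exact 3D values (which include
vortex and entrance effects) are out of scope for a 1D model and are not
targeted.

## Catheter warm-up

The intracorporeal catheter segment is modeled as a lumped plug-flow heat
exchanger at constant wall temperature:

$$T(x) = T_{\mathrm{body}} - (T_{\mathrm{body}} - T_{\mathrm{in}})\,
e^{-x/x^*}, \qquad x^* = \frac{\rho\,c_p\,Q}{h\,\pi d}, \qquad
h = \frac{\mathrm{Nu}\,k}{d}.$$

Defaults: 1 mm lumen, 0.6 mL/min, DMSO constants ($k = 0.2$ W/m/K,
$c_p = 0.47$ cal/g/°C $= 1966.5$ J/kg/K with 1 cal $= 4.184$ J), density
1100 kg/m³ (DMSO-dominated; tantalum loading raises it, hence
configurable), and the laminar fully-developed constant-wall-temperature
Nusselt number 3.66. These give $x^* \approx 9.4$ mm and a 95 % warm-up
length of ~28 mm: a 1 m neurosurgical catheter warms the agent completely,
a centimeters-long pediatric access does not. An optional cylindrical wall
conduction resistance (0.2 mm wall) can be composed in series with the
film. Axial conduction is neglected (the Péclet number over the decay
length is large) and the exponential is evaluated in closed form — the
test suite checks it against brute-force axial integration at 0.1 mm
steps. `viscosity_profile()` composes $T(x)$ with the temperature law at
the catheter wall shear rate and integrates $32\mu(x)c/d^2$ by the
trapezoidal rule; the heated pressure drop always lies strictly between
the two isothermal bounds. In plug flow the temperature equation decouples
from viscosity, so this model cannot distinguish Newtonian from
non-Newtonian thermal fields — a known limitation of the lumped approach.

## Problem sizes used in the tests

Unit and property tests run on 20–60-point synthetic curves; the
Monte-Carlo parameter-recovery study uses 200 seeded replicates per
parameter set at 5 % noise (median relative error of $\mu_0$ stays below
5 %); the network acceptance checks solve the full 9-diameter × 2-fistula
× 2-polymer factorial. The whole suite runs in a few seconds.

## Known limitations

* The constitutive constants are used outside 0.1–10 1/s only under the
  plateau/clamp conventions described above; behaviour below 0.1 1/s is
  unmeasured, and for Squid-12 at 37 °C the raw law is unstable there.
* The 20 °C catheter Reynolds number cannot be pinned down consistently
  with the 20 °C constitutive constants under the same density, velocity
  and length used at 37 °C; the package computes it from its own
  ingredients and anchors no expectation to any particular value.
* The catheter is described as 2 mm lumen (6 Fr) where delivery velocity
  and Reynolds numbers are quoted, and 1 mm where the warm-up model is
  quoted; both configurations ship, but they are not interchangeable —
  velocities differ fourfold.
* No two-phase blood/polymer displacement, no precipitation kinetics, no
  transient start-up, no 3D flow structures.
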