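---
title: "Tension-coupled calcium binding in the cardiac sarcomere: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tension-coupled calcium binding in the cardiac sarcomere: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mechchem)
```

## The model

Steady-state active tension in striated muscle comes from cross-bridges that
can only form where thick and thin filaments singly overlap. We track one
representative thin filament, with a coordinate `x` running from the
mid-line end of the single-overlap region (`x = 0`) toward the Z-disk
(`x = x_max`). Each attached cross-bridge adds its force to the tension
`S(x)` carried by the filament at positions distal to it, so `S` is a
non-decreasing staircase that, averaged over the many cross-bridges of
living muscle, becomes a smooth function.

Chemistry enters through the troponin switch. Calcium binding to an
in-register pair of troponin complexes — treated as one binding unit with an
intrinsic cooperativity coefficient `n` — moves tropomyosin and unblocks
nearby cross-bridge binding sites. In this model unblocking is taken to
imply cross-bridge formation, so the local force density is proportional to
the activated fraction `P(x)`:

$$\frac{dS}{dx} = C_f\,P(x), \qquad
P(x) = \frac{1}{1 + \exp\!\big(n\,(-C_s S(x) - \ln([\mathrm{Ca}^{2+}]/K_{TnCa0}))\big)},
\qquad S(0)=0.$$

The mechanochemical hypothesis sits in the `C_s S(x)` term: the energy
needed to pull calcium off troponin grows linearly with the tension the
filament already carries, which multiplies the dissociation constant by
`exp(-C_s S)`. Tension begets activation begets more tension — a long-range
cooperative feedback that needs no direct communication between troponins.
Its measurable consequence is that calcium–tension curves simulated with
`n = 3` fit best with apparent Hill coefficients near 7.

Assumptions worth keeping in mind: all chemical reactions are in
equilibrium (static, isometric conditions only); every attached cross-bridge
exerts the same force; unblocked sites are always occupied; passive tension
from titin or extracellular matrix is excluded — outputs are active tension
only, in the dimensionless tension unit `S` of the skinned-muscle data the
model was calibrated against.

## Parameters and units

| Parameter | Unit | Meaning | Typical fitted range |
|---|---|---|---|
| `c_f` | S·µm⁻¹ | force density at full activation | 1.85–1.97 |
| `c_s` | S⁻¹ | tension sensitivity of the calcium–troponin equilibrium | 2.7–9.3 |
| `k_tnca0` | µM | dissociation constant at zero tension | 5.7–10.1 |
| `n` | — | intrinsic cooperativity (fixed, not fitted) | 3 |

Published tables quote `c_f` in 10⁶ m⁻¹S; numerically this equals S·µm⁻¹,
which is what the package stores, so no conversion factor ever appears.
`n = 3` follows measurements of calcium–troponin binding in tension-free
preparations; `reference_params()` exposes the fitted values per sarcomere
length (per-curve, shared, and Hill comparator blocks).

The overlap geometry defaults to a 1.65 µm thick filament with a 0.1 µm bare
zone and 1.2 µm thin filaments — the standard myofilament geometry of the
Rice et al. (2008) model family. The single-overlap length is

$$x_{max} = \min(\mathrm{thick}/2,\ SL/2) -
  \max(\mathrm{thin} - SL/2,\ \mathrm{bare}/2),$$

which grows from 0.550 to 0.750 µm as SL rises from 1.85 to 2.25 µm (the
supported SL range, matching the available measurements). The second term is
the double-overlap edge: opposing thin filaments exclude cross-bridges near
the mid-line at short SL. These three lengths are arguments everywhere a
geometry is built, so alternative filament measurements can be substituted.

## Numerical choices

**Integrator.** The right-hand side is smooth, bounded by `c_f` and
stiffness-free, so an adaptive Dormand–Prince 4(5) pair (deSolve's `ode45`)
with `rtol = 1e-8`, `atol = 1e-12` is comfortable. Profiles are sampled on a
uniform 512-point `x`-grid via dense output; calcium–tension curves solve
one vector ODE with one state component per calcium level, which shares step
-size control across the curve and keeps a 200-point curve under 100 ms. The
test suite checks the solver against an independent fixed-step classical RK4
at `dx = 1e-4` µm to a relative 1e-5 over the whole reference parameter
range, and against the model's own discrete cross-bridge ladder.

**The ladder.** `discrete_ladder()` realises the staircase picture directly:
sites at spacing `dx = x_max/n_sites`, each adding
`c_f · dx · P(S_before)` with `P` evaluated at the tension accumulated
*strictly before* the site (left-Riemann convention — the natural reading of
discrete cross-bridges pulling on everything distal to them). It is the
forward-Euler discretisation of the ODE, so its error is first order in
`dx`; tests verify the error roughly halves per doubling of `n_sites` from
32 to 4096.

**Stable logistic.** `P(x)` is evaluated with `plogis`, never by
exponentiating the raw argument, so calcium levels many decades from
`k_tnca0` cannot overflow.

**Calcium grid.** `default_ca_grid()` is 200 log-spaced points over
[0.001, 10] µM, the range of the simulation protocol the model was developed
under.

**Peak and EC50 conventions.** The "peak" of a curve is its tension at the
top of the grid (10 µM), matching how a bounded experimental protocol
reports maximal tension — not the `c_f·x_max` asymptote, which the curves
approach only logarithmically. EC50 is the calcium level where the curve
crosses half that peak, located by monotone piecewise-cubic (Hyman-filtered)
interpolation in (log Ca, tension) plus root bracketing; for noisy,
non-monotone measured curves the interpolant falls back to isotonic
regression with linear interpolation. Under this convention the EC50 of an
exactly-Hill curve sits slightly below its `ec50` parameter, by the
closed-form factor `(1 + 2(ec50/10)^{n_H})^{-1/n_H}`; for the steep curves
of interest (`n_H ≈ 7`) the deflection is below 0.2%, and the tests assert
the closed form rather than pretending the conventions coincide.

**Zero-tension clipping.** The solver's `atol`-scale negative wobble at
near-zero tension is clipped to 0 so profile invariants (`S ≥ 0`,
monotonicity) hold exactly.

## Fitting

Both the Hill comparator and the mechanochemical model are fitted by bounded
Levenberg–Marquardt least squares on tensions in linear space — the same
unweighted RMSE criterion used to report fit quality, `sqrt(mean((model -
data)^2))`. Bounds are `c_f ∈ [0.5, 5]` S·µm⁻¹, `c_s ∈ [0, 200]` S⁻¹,
`k_tnca0 ∈ [0.5, 1000]` µM — wide enough that low-cooperativity variants
(`n = 1` pushes `k_tnca0` into the hundreds of µM) stay interior.

Steep sigmoids make narrow curved valleys, so every fit runs from five
deterministic starting points derived from the data (peak tension over
`x_max` for `c_f`; the half-peak calcium for the concentration scale; a
spread of coupling strengths) and keeps the best optimum. Determinism was
chosen over random restarts so that identical inputs always give identical
fits without touching the RNG.

The shared-parameter mode mirrors the two-step procedure used for the
published table: fit each sarcomere-length curve independently, seed a joint
fit with the mean `(c_f, c_s)` and the per-curve `k_tnca0` values, then
re-optimise everything jointly (plus two perturbed restarts). A returned
fit's objective can never beat the sum of the per-curve optima it nests in;
the tests assert exactly that inequality.

**Identifiability.** `k_tnca0` and `c_s` compensate each other strongly:
scaling `k_tnca0` by a factor `a` can be absorbed almost entirely by
re-tuning `c_s`, with curve-space RMSE changes of a few percent of peak
tension. `ridge_scan()` maps this ridge empirically — for each `a` it finds
the distance-minimising `c_s` and reports the implied power-law exponent
`log(c_s'/c_s)/log(a)` — rather than asserting any particular algebraic
form, whose printed versions in the literature are dimensionally ambiguous.
Practical consequence: judge fits in curve space (the tests require refitted
curves within 0.05 S of the generating ones everywhere) and treat individual
`(c_s, k_tnca0)` values with caution; `c_f`, by contrast, is identified to
better than a percent at realistic noise.

## The synthetic data generator

`generate_dataset()` emulates steady-state skinned-fibre protocols: for each
sarcomere length in {1.85, 1.95, 2.05, 2.15, 2.25} µm it evaluates a
noiseless model curve (mechanochemical or Hill) on a design of 18 log-spaced
calcium levels across the 1–10 µM transition plus three sub-threshold
anchors (0.05, 0.16, 0.5 µM), adds homoscedastic Gaussian tension noise, and
clips at zero (a skinned preparation cannot report negative active tension).
The default `σ = 0.02` S was fixed to make fitted RMSEs land in the
0.01–0.05 S range reported for fits to the real measurements; the true
measurement error of those experiments is unknown, and no claim of fidelity
is made. Homoscedastic noise is the neutral choice given that the reported
fit criterion is unweighted.

What the generator does *not* emulate: run-down and drift over a protocol,
sarcomere-length dispersion within a preparation (which smears the sharp
low-calcium bend of real curves), calcium buffering errors, and
between-preparation variability. Tests passing on synthetic data therefore
demonstrate correctness of the algorithms and internal consistency of the
fitting machinery — not that the model is right about muscle; that case
rests on the published comparisons to measured data.

## Problem sizes

The test-suite and acceptance computations use the 200-point calcium grid,
512-point profiles, RK4 oracle steps of 1e-4 µm, ladders up to 4096 sites,
21-point × 5-length synthetic datasets, and 40 noise replicates for the
Hill-bias check — sizes chosen to make every check decisive for a model
whose single-curve simulation costs tens of milliseconds.

## Known limitations

* Statics only: no cross-bridge cycle kinetics, no twitch or relaxation
  dynamics. The equilibrium assumption is appropriate for steady-state
  skinned-fibre data and nothing else.
* Activation is equated with force generation; partial occupancy of
  unblocked sites is absorbed into `c_f`.
* Mean-field in space: no individual binding sites, no discreteness noise.
* Passive tension is out of scope; measured total tensions must have their
  passive component removed before fitting.
* Published prose summaries of this model family quote zero-tension
  equilibrium constants (16.6 falling to 11.8 µM) that are inconsistent
  with the fitted parameter tables those same sources print; the package
  carries the table values in `reference_params()` and makes no attempt to
  reconcile the two.
* The apparent Hill coefficient of simulated curves falls with sarcomere
  length (from ≈7.4 at 1.85 µm to ≈6.0 at 2.25 µm with the per-curve
  parameters) because the fitted coupling `c_s` itself falls with length;
  the "boost from 3 to about 7" headline is a statement about the curve
  family, not each individual length.
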