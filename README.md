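# mechchem

Cardiac muscle develops tension far more steeply with calcium than simple
calcium–troponin chemistry allows: skinned-fibre force–pCa curves show Hill
coefficients near 7, while calcium binding to troponin in the absence of
tension is only about as cooperative as n = 3. **mechchem** implements a
mechanochemical explanation of the gap: the mechanical tension S(x) carried
by the thin filament raises the energy needed to detach calcium from
troponin, scaling the dissociation constant as

```
K_TnCa(x) = K_TnCa0 · exp(−C_s · S(x))
```

so that the fraction of activated troponin at position x along the
single-overlap region is

```
P(x) = 1 / (1 + exp(n · (−C_s·S(x) − ln([Ca²⁺]/K_TnCa0))))
```

and tension accumulates toward the Z-disk according to the ODE

```
dS/dx = C_f · P(S(x)),   S(0) = 0,   0 ≤ x ≤ x_max(SL),
```

with `x_max` the single-overlap length set by the sarcomere length SL and
the filament geometry. Total filament tension is S(x_max). Three constants —
the force density `C_f` (S·µm⁻¹), the tension coupling `C_s` (S⁻¹) and the
zero-tension equilibrium constant `K_TnCa0` (µM), with the intrinsic
cooperativity fixed at n = 3 — are enough to reproduce measured
calcium–tension relations, including their characteristic asymmetry that the
symmetric Hill equation

```
S_H = S_max · [Ca²⁺]^nH / (EC50^nH + [Ca²⁺]^nH)
```

misses. The package is for muscle biophysicists and cardiac modellers who
want to simulate these curves, fit the model to skinned-muscle-style data,
and compare it against Hill fits.

## What's in the box

* `sarcomere_geometry()`, `single_overlap_length()` — overlap geometry.
* `integrate_tension()`, `ca_tension_curve()`, `total_tension()`,
  `discrete_ladder()` — spatial tension/activation profiles and steady-state
  calcium–tension curves (adaptive Runge–Kutta; the discrete cross-bridge
  ladder is the model's native staircase picture and doubles as an
  integrator check).
* `mechchem()` — fit the model to grouped data (`tension ~ ca | sl` formula
  interface; per-curve or shared-parameter mode), with `print`, `summary`,
  `coef`, `predict`, `residuals`, `plot` and `simulate` methods.
* `fit_hill()`, `hill_tension()` — the three-parameter Hill comparator.
* `ec50()`, `apparent_hill_coefficient()`, `peak_tension_change()`,
  `param_variation()`, `curve_summary()` — curve metrics.
* `generate_dataset()`, `read_dataset()`, `write_dataset()` — synthetic
  skinned-muscle datasets and CSV I/O; `reference_params()` — the published
  parameter table.
* `mechchem_cli()` / `exec/mechchem` — shell subcommands
  (`simulate`, `profile`, `generate`, `fit`, `fit-hill`, `summarize`,
  `ridge`).

## Worked example

Simulate the calcium–tension curve at SL = 1.85 µm with the published
per-curve parameters, then fit the model to a synthetic five-length dataset:

```r
library(mechchem)

geom <- sarcomere_geometry(1.85)
geom
#> Sarcomere geometry: SL 1.85 um (thick 1.65 | thin 1.2 | bare zone 0.1 um)
#>   single-overlap length x_max: 0.55 um

p <- mechchem_params(c_f = 1.85, c_s = 9.27, k_tnca0 = 10.09)
curve <- ca_tension_curve(p, geom)
curve_summary(curve)
#>     sl   ec50 peak_tension apparent_n_h
#> 1 1.85 4.1225    0.9805621     7.315725
```

Half-maximal tension needs 4.12 µM calcium, the peak tension at 10 µM is
0.98 S, and although the chemistry's intrinsic cooperativity is only n = 3,
the best-fitting Hill coefficient of the simulated curve is 7.3 — the
tension feedback supplies the missing cooperativity.

```r
ds <- generate_dataset("mechchem", reference_params("shared"),
                       noise_sigma = 0.02, seed = 42)
fit <- mechchem(tension_S ~ calcium_uM | sarcomere_length_um,
                data = ds, mode = "shared")
fit
#> Mechanochemical model fit (mode: shared , n = 3 )
#>    sl   c_f  c_s k_tnca0 n    rmse n_points
#>  1.85 1.928 5.42   8.774 3 0.02447       21
#>  1.95 1.928 5.42   8.115 3 0.01706       21
#>  2.05 1.928 5.42   7.689 3 0.01715       21
#>  2.15 1.928 5.42   7.450 3 0.01739       21
#>  2.25 1.928 5.42   7.103 3 0.01739       21
#> Total SSQ 0.03756 S^2 over 105 points; converged: TRUE
```

The shared fit pins one `(C_f, C_s)` pair across sarcomere lengths and lets
only the zero-tension calcium affinity vary: `k_tnca0` falls monotonically
with SL (increasing calcium sensitivity at longer lengths), per-group RMSEs
sit at the 0.02 S noise floor, and `C_f ≈ 1.93` S/µm is recovered to a
fraction of a percent. `C_s` and `K_TnCa0` compensate each other along a
ridge (see `ridge_scan()`), so their individual values wander more than the
curves they produce.

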