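---
title: "Methods: a two-airway nasal air-conditioning and ASL hydration model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-airway nasal air-conditioning and ASL hydration model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nasalcycle)
```

## The problem

The nose conditions every breath — warming it toward core temperature and
saturating it with water vapour — and simultaneously clears trapped
particles by mucociliary transport. Both jobs are done by the same thin
liquid film, the airway surface liquid (ASL): evaporation into the
inhaled airstream dries it, while ciliary clearance requires it to stay
hydrated. The two nasal passages share the tidal flow unevenly (the nasal
cycle alternates which side is patent and which is congested), and this
package models why that asymmetry matters: the patent side does most of
the conditioning work and pays for it in ASL dehydration, while the
congested side rests.

The model is a one-dimensional lumped-parameter transient simulator, not a
CFD code: each passage is a chain of coronal slabs exchanging heat and
vapour with a prescribed wall, which makes whole-breath, multi-cycle
simulations cheap enough for parameter exploration.

## State variables and geometry

Per slice `k` (anterior → posterior): air temperature `T_a(k, t)`, vapour
concentration `C_a(k, t)` (kg/m³ of air volume) and the ASL
water-equivalent height `H_e(k, t)` (µm). Geometry enters through the
slab-averaged cross-sectional area `A(k)`, perimeter `P(k)` and slice
thickness `l`; the hydraulic diameter `Dh = 4A/P` is the characteristic
length of all duct correlations (this convention is what makes the
composed friction-factor route agree with the closed-form slice
resistance, a tested identity). Positions are reported as `X/L`, the
fractional distance from the anterior nasal valve (0) to the choanae (1);
when a CSV geometry has sides of unequal slice count or length, both are
linearly resampled onto a common `X/L` grid so slice `k` faces slice `k`.

### The synthetic geometry

Real profiles come from segmented coronal MRI; none are distributed, so
`synthesize_geometry()` builds a smooth stand-in: each cross-section is a
folded slit of developed width `w` (narrow at the nasal valve, widest over
the turbinates at `X/L ≈ 0.35`, tapering to the choanae) and gap `b`
(2.5–2.8 mm), with `A = w·b`, `P = 2(w + b)`. Defaults were chosen once,
a priori, to match the field's standard figures: passage length ≈ 9.4 cm
(120 slices at the typical 0.78 mm MRI slice thickness), one-side mucosal
surface area ≈ 100 cm², effective gap ≤ 3 mm everywhere (the narrow-slit
bound that justifies parallel-plate correlations), and a one-side cavity
volume of ~11 mL. Congestion `c ∈ [0, 1)` models turbinate engorgement as
gap narrowing: areas scale by `(1 − c)` with perimeter held, because the
engorged mucosa closes the air gap rather than shortening the wall. What
the generator does **not** emulate: septal deviations, sinus ostia,
slice-to-slice roughness of real anatomy, and the cross-sectional shape
detail that drives secondary flows — so a green test establishes the
transport/ledger mechanics, not subject-specific prediction.

## Airflow partitioning

At-rest nasal airflow is laminar (peak slice Reynolds numbers stay below
~2000; the solver logs the maximum as a diagnostic). Per slice, the
parallel-plate friction factor `f = 24/Re` composed with Darcy–Weisbach
head loss `h_f = f l V² / (2 g Dh)` gives the flow-independent specific
resistance

```
R(k) = 3 µ P(k)² l / (4 ρ² A(k)³ g)   [m head per kg/s]
```

Sides sum in series, combine in parallel, and each side's partitioning
ratio is `PR = R_total / ΣR_side`; `PR_left + PR_right = 1` is an
algebraic identity, asserted as a property test. Because laminar
resistance is flow-independent, `PR` is constant over the breath at fixed
congestion: the whole tidal trace is apportioned by two numbers. The
`A⁻³` scaling means modest congestion swings the share strongly: the
default pair `(0, 0.2)` gives a ~1.95:1 resistance ratio and a patent
share of ~0.66, the apportionment magnitude reported for mid-cycle
subjects. Head (metres) is the working unit to keep the slice formula
exact; multiply by `ρg` for Pa.

The default breath is a 500 mL, 5 s (12 breaths/min) sinusoid,
`ṁ(t) = (π V_t ρ / T_p) sin(2π t / T_p)`, whose inhaled-phase volume
integral equals the tidal volume exactly; measured traces can be
substituted as CSV tables (rejected if inhaled and exhaled volumes differ
by more than 1%).

## Heat and vapour exchange

The wall (mucosal surface) temperature is prescribed, not solved: linear
in `X/L` from 32 °C at the nasal valve to 37 °C at the choanae, constant
in time. This stands in for the mucosal blood-temperature distribution
used by earlier airway models; the anterior value is the least-certain
parameter and is configurable (`wall_model()`), so its sensitivity can be
explored rather than asserted. The ASL surface is assumed saturated at
the local wall temperature, with evaporative enthalpy drawn from the
mucosal reservoir — the standard prescribed-wall simplification.

Transfer coefficients: the fully developed laminar constant-wall-
temperature limit for parallel plates is `Nu = 7.54`, `h = Nu k / Dh`.
The original design called for this constant value alone, but it made the
*congested* side dry faster anteriorly (narrowing the gap raises `h`
while costing no flow dependence), inverting the physics the model
exists to show. The nasal thermal entrance length `~0.05 Re Pr Dh` is
comparable to the passage length, so the flow is thermally developing
nearly everywhere and a local Lévêque/Graetz term is blended in:

```
Nu_x = (7.54³ + (1.233 Gz^(1/3))³)^(1/3),   Gz = Re Pr Dh / x
```

with `x` measured from the current flow inlet (nares on inhalation,
choanae on exhalation). This restores the correct ordering — in the
entrance-dominated anterior region the per-area flux ratio between patent
and congested walls scales as `(1 − c)^(−1/3) > 1` — and reduces to the
constant-Nu limit at zero flow. Mass transfer follows the Chilton–Colburn
analogy, `h_m = h / (ρ c_p Le^(2/3))`, `Le = α/D_v`.

Psychrometrics use the Arden Buck saturation-pressure fit with ideal-gas
conversion (`R_v = 461.5` J/(kg·K)), valid over −20…50 °C; at 23 °C / 45%
RH the inlet absolute humidity is 9.25 g/m³, within the ±0.1 g/m³
correlation slack of the conventional 9.2 figure. Concentrations are per
m³ of (moist) air volume; at nasal humidity levels the distinction from a
dry-air basis is below 2% and is ignored.

## The ASL hydration ledger

`H_e` is the removable water volume per unit area of the two-layer ASL,
expressed as a height. The endpoints come from layer physiology: over full
dehydration the periciliary layer (PCL) collapses by 4 µm; with the PCL
osmotic bulk modulus twice the mucus value, the mucus blanket gives up
twice the height (8 µm), totalling 12 µm; at 85% water volume fraction
the removable water is 10 µm (`derive_spans()`). `H_e = 10` µm is fully
hydrated; `H_e = 0` marks severe dehydration, where PCL collapse stops
mucociliary transport. Between the endpoints the layer heights map
linearly (only the endpoints are constrained by the physiology). The
hydrated PCL height defaults to 7.5 µm — the value consistent with a
"53% or 4 µm" collapse and inside the observed 7–10 µm range.

Per step the ledger applies, in order: demand-led mucosal supply (active
only when there is evaporative demand or a hydration deficit, capped at
the supply maximum), the exchange flux (dry-surface capped: a bare wall
can evaporate no faster than supply delivers; the event is flagged),
epithelial reabsorption of any excess above `H_e,max` up to its own cap,
and a hard clamp with the residual logged as an over-hydration overflow
diagnostic. The audit identity
`delivered + Δstore/dt − supply + reabsorption + overflow = 0`
holds to rounding and is asserted per cycle of every simulation.

### The supply-cap unit question

The literature supply estimate is printed as 7.9 g/cm²·hr with a 3.5
supply:reabsorption ratio (2.26 ≈ the quoted 2.2 g/cm²·hr). Taken at face
value this refills the entire 10 µm ledger in ~0.5 s — roughly an order
of magnitude above any evaporative flux this model (or any nose) can
produce, so no dehydration could ever occur; yet the same literature
reports severe anterior dehydration, and its own derivation sketch (fully
humidifying 500 mL per breath from 100 cm² of mucosa) gives
~0.1–0.8 g/cm²·hr. The printed value is therefore carried verbatim as the
default, but as a `(value, unit)` pair: substituting
`supply_unit = "mg/cm2/hr"` — the package's *demonstration world* — puts
supply (2.2 × 10⁻⁵ kg/m²/s) below peak evaporation (~1.5 × 10⁻³ kg/m²/s)
and the documented dehydration/rehydration dynamics appear. All
dehydration-dependent acceptance properties run in the demonstration
world; the printed-default world is used for the periodic-steady-state
check (its ledger is pinned at `H_e,max`, by construction). Reabsorption
is applied only above `H_e,max` (whether it runs concurrently with supply
is unstated in the physiology; concurrent operation would only add a
constant offset both caps absorb).

## Numerics

Explicit first-order upwind advection in space, forward Euler in time,
with automatic sub-stepping so the advective Courant number and exchange
rates stay ≤ 1 (default outer `dt` = 1 ms; error if more than 500
sub-steps would be needed). The wall-exchange relaxations are integrated
*exactly* within each sub-step (exponential integrator toward `T_w` and
`C_sat(T_w)`), with the resulting sub-step-average vapour flux routed
through the ledger caps; this removes the forward-Euler rate error that
otherwise dominates at the anterior slices, where the entrance-region
coefficient is largest. Vapour advection is written in conservative flux
form with a constant volumetric flow per passage (mass flow over inlet
density), which is what lets the water audit close to ~1e−13 per cycle.
Supersaturated air (`C_a > C_sat(T_a)`, produced when warm saturated
exhaled air is cooled) is clipped to saturation and the excess condensed
onto the local ASL. Zero-flow instants keep wall exchange and drop
advection. Runs discard 3 spin-up cycles by default.

Self-convergence is tested, not assumed: at the default resolution
(120 slices, dt = 1 ms) halving dt or the slice thickness changes the
final-cycle `T`, `C` and `H_e` fields by well under 1% (acceptance test).
At strongly reduced slice counts the discrete sub-step count makes the
effective Courant number — and hence the upwind numerical diffusion —
jump with dt, so the hydration front can wobble by ~1–2%; the scaled unit
tests document this with a wider tolerance.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| ambient T, RH | 23, 0.45 | °C, – | standard room-air reference (AH 9.2 g/m³) |
| tidal volume, period | 500, 5 | mL, s | adult at rest, 12 breaths/min |
| congestion (L, R) | 0, 0.2 | – | ~2:1 resistance ratio, patent share ~2/3 |
| wall T (ant., post.) | 32, 37 | °C | anterior value uncertain; tunable |
| `pcl_span`, ratio, water fraction | 4, 2, 0.85 | µm, –, – | layer physiology; gives 8/12/10 µm |
| hydrated PCL height | 7.5 | µm | 4 µm ≈ 53% collapse; in 7–10 µm range |
| supply cap | 7.9 (unit-carried) | g/cm²·hr | printed estimate; see unit question |
| reabsorption ratio | 3.5 | – | supply/reabsorption; cap 2.26 g/cm²·hr |
| laminar threshold | 2000 | – | warn when `f = 24/Re` leaves its regime |
| dt, cycles, spin-up | 1 ms, 8, 3 | s, –, – | converged at default grid; periodic after spin-up |

## Known limitations

- The wall temperature is prescribed, so mucosal cooling by evaporation
  feeds back only through the configured profile, not dynamically.
- Congestion is an exogenous per-run parameter; the nasal cycle is
  modelled as discrete state swaps (`nasal_cycle_experiment()`), not
  continuous vascular dynamics.
- Transfer correlations are laminar narrow-slit idealisations; sniffing,
  exercise hyperpnea and entrance/exit minor losses are out of scope.
- The anterior dehydrated fraction depends on subject geometry, the
  breath trace and the supply-cap interpretation; the package reproduces
  the patent/congested *contrast* (dominance at every `X/L`, rehydration
  on exhalation, role swap under mirroring), not any particular printed
  percentage.
- In the demonstration world the slow net drift of mid-passage slices
  means cycle-to-cycle `H_e` changes can remain above 0.1% for many more
  cycles than a default run simulates; strict periodicity is asserted
  only where the stated parameters actually produce it.
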