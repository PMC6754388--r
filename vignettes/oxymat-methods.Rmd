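---
title: "Modelling oxygen dynamics in subaerial microbial mats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling oxygen dynamics in subaerial microbial mats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxymat)
```

## The system

A subaerial photosynthetic microbial mat is a centimetre-scale, layered
community growing on rock in contact with the atmosphere. Cyanobacteria in
the illuminated top millimetres produce oxygen; heterotrophs throughout the
mat consume it; molecular diffusion through the porewater connects the two
and exchanges O~2~ with the atmosphere above and the rock below. `oxymat`
packages four quantitative layers of this picture:

1. a one-dimensional oxygen reaction–transport model of the mat,
2. flux and volumetric-rate estimation from measured O~2~ microprofiles,
3. an oxygen-equivalent box model balancing organic-carbon accretion,
   methane loss and O~2~ fluxes, and
4. calculators that scale areal rates to global fluxes under land-coverage
   scenarios.

A seeded synthetic-data module emulates the field measurements so that every
stage is testable end to end without any external data.

## The reaction–transport model

Oxygen in the porewater obeys

$$\frac{\partial C}{\partial t} \;=\; D'\,\frac{\partial^2 C}{\partial z^2}
  \;+\; P(z) \;-\; R(C),$$

with depth $z$ positive downward from the mat–atmosphere interface.
Production is Michaelis–Menten in light,
$P = \mathrm{PAR}(z)\,V_{\max,P}/(K_{m,P} + \mathrm{PAR}(z))$, with the
light field attenuating by a fixed fraction per depth step
($\mathrm{PAR}(z) = \mathrm{PAR}_0 (1-f)^{z/\Delta z_f}$, taken as a
continuous exponent so any grid is accepted). Respiration is
Michaelis–Menten in oxygen, $R = C\,V_{\max,R}/(K_{m,R} + C)$.

Defaults (all configurable through `kinetic_parameters()` and
`transport_parameters()`):

| parameter | default | units | meaning |
|---|---|---|---|
| $V_{\max,P}$ | 2.1 | nmol L^-1^ s^-1^ | maximal volumetric O~2~ production |
| $K_{m,P}$ | 1000 | µE m^-2^ s^-1^ | light half-saturation |
| $V_{\max,R}$ | 1.75 | nmol L^-1^ s^-1^ | maximal volumetric respiration |
| $K_{m,R}$ | 250 | nmol L^-1^ | O~2~ half-saturation |
| $\mathrm{PAR}_0$ | 1500 | µE m^-2^ s^-1^ | surface irradiance |
| $f$ per $\Delta z_f$ | 1% per 0.071 mm | — | light attenuation |
| $\varphi$ | 0.97 | — | porosity |
| $D'$ | 1 × 10^-5^ | cm^2^ s^-1^ | tortuosity-corrected diffusivity |

### Discretization and stability

The solver is the explicit forward-time centred-space (FTCS) scheme on a
uniform grid, with the diffusion term
$D'(C_{x-1} - 2C_x + C_{x+1})/\Delta x^2$. A literal per-step update that
subtracts a Fickian *flux* from a *concentration* is dimensionally
inconsistent, so the standard concentration-update form is used; porosity
cancels for internal porewater diffusion and enters only when converting
gradients to areal fluxes (Fick's first law, $J = -\varphi D'\,dC/dz$) and
volumetric rates to areal rates ($\varphi \int (P-R)\,dz$).

The scheme is stable for $D'\Delta t/\Delta x^2 < 0.5$; configurations at or
beyond the bound are rejected with an error naming the offending number. The
defaults ($\Delta t = 1$ s, $\Delta x = 0.071$ mm) give 0.198. A transient
check against the analytic error-function solution of the diffusion
equation, and the exact discrete balance between boundary fluxes and
depth-integrated net rates at steady state, are both part of the test suite.

### Two steady-state modes

`run_to_steady_state()` offers `fixed_1200` — exactly 1200 iterations
of 1 s, the fixed greenhouse-calibration procedure — and `converge`, which
iterates until the largest concentration change per second falls below a
tolerance (default 10^-4^ nmol L^-1^ s^-1^). The two differ in practice: the
diffusive relaxation time over a 20 mm domain is $L^2/D' \approx 4\times
10^5$ s, so 1200 s equilibrates only the top millimetres. Property tests
(conservation, boundary monotonicity, inversion round trips) therefore use
converge mode; `fixed_1200` reproduces the fixed procedure.

Boundary conditions: the top node is always held at a fixed concentration
(default 230 µmol L^-1^, an air-equilibrated value for warm fresh water; 0
for anoxic-atmosphere scenarios). The bottom is a zero-flux closure by
default, with an optional fixed concentration to emulate drawdown by the
rock. The domain depth defaults to 20 mm, the scale of the sampled mat
sections.

Negative concentrations cannot arise from the reaction term because
respiration at a node is capped at $C/\Delta t$; any residual negatives from
the explicit update are clipped to zero and counted in a warning.

### The direct steady-state solve

`steady_state_direct()` solves the same discrete equations the FTCS scheme
relaxes to (Newton iteration with a tridiagonal solve). It lands on the FTCS
fixed point to within the convergence tolerance — the agreement is itself a
test — and makes fits that need hundreds of steady states cheap. It is the
default forward engine inside `calibrate_vmax()`.

### Calibration

`calibrate_vmax()` minimizes the sum of squared concentration residuals over
$(V_{\max,P}, V_{\max,R})$ with non-negativity bounds, using damped
Gauss–Newton steps with finite-difference sensitivities. Over the oxic part
of the profile the steady state is nearly linear in both parameters (the
respiration term is O~2~-saturated when $C \gg K_{m,R}$), so the iteration
converges in a handful of forward solves. The packaged recovery experiment
generates a steady profile on the sensor-resolution grid (0.071 mm, 283
nodes, 20 mm), adds 2 µmol L^-1^ Gaussian sensor noise, and refits from a
deliberately wrong start; across 20 seeded replicates both maxima come back
within 10%. Identifiability depends on the domain: on shallow (< ~15 mm)
domains the two parameters are strongly collinear (production and
respiration shapes differ only through light attenuation) and recovery from
noisy single profiles degrades accordingly — a caution that applies equally
to fitting real microprofiles.

## Profile inversion

`fick_flux()` applies Fick's first law at either interface with a
least-squares gradient over a configurable window (default two points).
Fluxes are reported positive out of the mat. `invert_net_rates()` uses the
steady-state identity $P - R = -\varphi D'\, d^2C/dz^2$ (bulk-volume basis):
net production is positive where the profile is concave-down. Centred second
differences are used rather than piecewise zonation fitting — reproducible
and directly testable; the areal integral extends the first and last
interior rates to the profile ends, where curvature is undefined. Double
differentiation amplifies sensor noise roughly as
$\sigma/\Delta x^2$, so noisy profiles should be smoothed (a 3-point moving
average is built in, off by default) or fitted with the forward model
instead; both routes exist and their areal integrals are cross-checked in
the tests. `day_night_gross()` records the standard bookkeeping: gross
production = daytime net production + night respiration, a lower limit
because respiration can slow at night when O~2~ is low.

## The oxygen-equivalent balance

All sources and sinks are normalized to 4-electron transfers: oxidizing
CH~2~O to CO~2~ and reducing O~2~ to water are both 4-electron steps
(factor 1), while CH~4~ carries 8 electrons (factor 2). The factors are
fixed constants; the ledger rejects unknown species.

`om_accretion_rate()` converts a wt%C depth profile to an areal carbon
accretion rate for a mat of given thickness (default 6 cm), age (default 9
yr), porosity (0.97) and particle density (2.65 g cm^-3^), using trapezoids
with constant extension below the profile support, a 365-day year and
12.011 g mol^-1^ carbon. `ch4_areal_flux()` halves a dark-incubation
methane rate by default, representing inhibition of methanogenesis under
daytime oxic conditions.

With the measured component rates — 20 mmol C m^-2^ d^-1^ of organic-matter
accretion and 4.1 mmol m^-2^ d^-1^ of dark methane production, halved —
the combined source row is 24.1 ≈ 24 mmol O~2~-eq m^-2^ d^-1^.

A note on magnitudes: the default kinetic constants integrate to a
depth-integrated net production of order 1 mmol m^-2^ d^-1^ over any
plausible mat depth, far below the tens of mmol m^-2^ d^-1^ that productive
mats sustain; matching such areal rates requires proportionally larger
maximal rates (the profile *shapes* are what the default constants
reproduce). The balance and extrapolation layers therefore take areal rates
as explicit inputs rather than deriving them from the default kinetics, and
the model-side guarantees are conservation and monotonicity properties
rather than specific areal values.

## Global extrapolation

The calculators are deliberately plain arithmetic, kept exactly linear in
rate, area and coverage: annualization (×365, ×10^6^ m^2^ km^-2^), global
production in Tmol yr^-1^, cellular-carbon stocks (cells cm^-3^ × fg C
cell^-1^), biomass as a fraction of TOC, division budgets, turnover times,
ocean area (Earth surface 5.10 × 10^8^ km^2^; 95% ocean gives
4.845 × 10^8^ ≈ 485 × 10^6^ km^2^), nitrate export via a molar C:N ratio,
and break-even coverage against user-supplied reference fluxes. Reference
fluxes are configuration inputs, not bundled facts. Rounding to reported
precision happens only at report time; internal values stay at full
precision.

With the default cell budget (10^8^–10^9^ cells cm^-3^, 1–150 fg C
cell^-1^, 1–12 wt% TOC) the cellular carbon density spans 10^-7^ to
1.5 × 10^-4^ g C cm^-3^ and cellular biomass spans ~0.001% to ~19% of TOC.
Note the lower TOC density bound is 7.95 × 10^-4^ g C cm^-3^
(= 0.01 × 0.03 × 2.65), which is what the ~19% upper biomass fraction
requires.

## Synthetic data

The generators are pure functions of their parameters and a seed:

* `gen_o2_profile()` — forward model steady state plus homoscedastic
  Gaussian sensor noise, clipped at zero; generating parameters are embedded
  in the profile metadata as ground truth for recovery tests.
* `gen_diel_profiles()` — one steady state per entry of a 24-h light
  schedule (night entries have PAR 0).
* `gen_wtc_profile()` — exponential decline between two anchors, 12 wt% at
  the surface to 1 wt% at depth, e-folding depth 5 mm.
* `gen_cell_counts()` — log-uniform draws in 10^8^–10^9^ cells cm^-3^,
  sorted non-increasing with depth.

What they deliberately do not emulate: lateral heterogeneity, diel
hysteresis (each schedule entry is an independent steady state, whereas a
real mat carries its history), depth-dependent porosity, temperature
effects, and non-Gaussian sensor artefacts (drift, stirring sensitivity).
Tests that pass on synthetic data therefore validate the numerics and the
estimators' self-consistency, not the field fidelity of the kinetic law.

## Problem sizes used in the packaged checks

Converge-mode property tests run on coarsened grids (0.142–0.284 mm spacing
with the time step rescaled to keep the stability number at ~0.4) because
the explicit scheme's cost scales as $L^2/\Delta x^2 \cdot 1/\Delta t$;
grid-refinement tests pin the discretization error of the coarsened runs at
under 2%. The calibration-recovery experiment uses the sensor-resolution
grid with the direct solver. The packaged default pipeline
(`run_pipeline(default_pipeline_config())`) runs the three scenarios on the
full sensor-resolution grid in well under a minute.

## Known limitations

* One spatial dimension, constant porosity and diffusivity, no temperature
  dependence, no multi-wavelength light field, no microbial growth/death
  dynamics, no internal methane cycling.
* The explicit scheme needs small time steps; use `steady_state_direct()`
  when only the steady state matters.
* Curvature inversion assumes an approximately steady profile; applying it
  to transient (e.g. early-morning) profiles folds storage changes into the
  apparent rates.
* The global calculators compute the arithmetic consequences of user-stated
  scenarios; they make no claim about actual Precambrian land areas or
  atmospheric chemistry.
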