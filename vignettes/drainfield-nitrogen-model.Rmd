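---
title: "Modeling water flow and nitrogen fate in drainfield mesocosms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling water flow and nitrogen fate in drainfield mesocosms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drainfieldN)
```

## The system being modeled

Onsite wastewater treatment systems discharge septic tank effluent (STE) or
advanced-treated effluent (ATE) to a soil treatment area (drainfield), where
microbial nitrification (NH4+ to NO3-, oxic) and denitrification (NO3- to
N2, anoxic, carbon-requiring) control how much nitrogen reaches
groundwater. `drainfieldN` simulates bench-scale drainfield mesocosms —
intact 15-cm-ID, 1.37-m soil columns dosed on realistic schedules — for
three system types:

* **PSND** — pressurized shallow narrow drainfield: ATE sprayed uniformly
  across an infiltrative surface (IS) 20 cm below grade, 2 L/d in 42-mL
  doses every 30 min.
* **GEO** — a PSND variant with a 1-cm entangled-filament distribution
  layer and a 2.54-cm pressure pipe; IS at 25 cm.
* **P&S** — conventional pipe-and-stone trench: STE at 400 mL/d in two
  200-mL doses, released at a pipe 60 cm deep inside a 30-cm crushed-stone
  layer over native soil at 84 cm.

The native profile is a silt loam A horizon over gravelly-coarse sand; the
package ships the mean calibrated van Genuchten parameter sets of the three
replicate mesocosms per system (`drainfield_hydraulics()`), the reported
layer water-filled pore space (WFPS, theta/theta_s) values
(`wfps_reference()`) and the effective zero-order transformation rates per
material (`zero_order_rates()`).

## Water flow

Flow follows the Richards equation for variably saturated media in a 2D
vertical plane, with van Genuchten-Mualem constitutive relations
(`water_content()`, `conductivity()`; the Mualem constraint `m = 1 - 1/n`
and pore connectivity `l = 0.5` throughout, which is never calibrated).
The numerical scheme is a cell-centered finite volume on a structured
quadrilateral mesh (about 580-620 cells per mesocosm, refined to 0.44 cm or
less near pipes and the dosing cover, comparable to the reference
discretizations), with:

* mixed-form backward Euler and modified-Picard iteration — the update is
  written against the water-content residual, so the global water balance
  closes to round-off regardless of time step (closure is reported on every
  run and asserted below 0.5% in the tests; in practice it is ~1e-10%);
* geometric-mean internodal conductivity (arithmetic and upstream
  weighting available as options);
* adaptive time stepping: steps shrink threefold on non-convergence and
  grow when the iteration converges comfortably, clipped to the dosing
  on/off edges so every pulse is resolved;
* a single **seepage-face node** at the domain bottom: no-flux while
  unsaturated, a Dirichlet `h = 0` outlet once locally saturated,
  deactivated again if it would draw water in; the switching is
  re-evaluated every iteration. This produces the hanging saturated zone
  above the column outlet seen in the mesocosms;
* an atmospheric top boundary that degenerates to no-flux because no
  precipitation, evapotranspiration or root uptake is simulated, and a
  minimum permissible pressure of -1000 cm;
* effluent doses enter as a variable-flux segment: the full IS width for
  PSND, a one-pipe-diameter (2.54 cm) segment below the pipe for GEO and
  P&S. Column dose rates are converted to the plane by the ratio of plane
  width to the 15-cm-ID circular cross-section.

Initial pressure head is -50 cm everywhere (near saturation, so steady
flow is reached quickly); runs last 90 days and summary fields are
averaged over the final 30 days.

### Numerical tolerances

Picard convergence uses 1e-3 cm on pressure head or 1e-6 on total water
content, whichever is met first. These are three orders of magnitude
tighter than the 1-cm head tolerance customary for this problem class;
tightening them a further thousandfold changes the 90-day layer-mean WFPS
only in the sixth decimal while tripling run time, which is why the
tighter setting is available in `flow_config()` but not the default.
Saturated cells carry a small specific storage (1e-5 cm^-1) so that
ponding inside the highly conductive stone/filament layers is represented
as transient positive pressure rather than a failure mode.

### What the layer WFPS means

`wfps_by_layer()` reports the time-averaged theta/theta_s per native
material. The default (`method = "nodes"`) evaluates the observation
nodes 15 and 30 cm below the infiltrative surface — the moisture-probe
depths against which the mesocosm models were calibrated and reported.
A `method = "volume"` alternative averages all cells of a layer below the
IS outside the seepage-controlled saturated bottom. The two differ
materially for the deep sand: its low air-entry parameter
(alpha ~ 0.02 cm^-1) produces a capillary fringe several decimeters thick
above the outlet, which dominates any volume average but not the probe
nodes. The probe-based definition is the one that corresponds to the
reported layer values, and the unit-gradient analysis
(`unit_gradient_state()`) reproduces it in closed form: at the PSND
loading of 11.3 cm/d the silt loam sits at WFPS 0.654 and the sand at
0.44.

A structural observation, documented rather than hidden: a
mass-conservative unsaturated column dosed at 2.26 cm/d (the P&S loading)
through material with Ks = 4.513 cm/d must, at quasi-steady state, run at
effective saturation near 0.88. The simulation does exactly that, so the
much drier reported P&S sand value (0.27) cannot be recovered under the
reported parameter set; the acceptance test asserts the reported value
and is expected to fail, with the reasoning above.

## Nitrogen transport and transformation

NH4-N and NO3-N are transported by upwind-weighted implicit
advection-dispersion over the stored flow fields (interval-averaged face
fluxes and water contents, 0.05-day intervals by default, sub-stepped to
the local Courant number for accuracy; the implicit scheme is
unconditionally stable). The dispersion tensor uses longitudinal
dispersivity set to one tenth of the soil profile depth below the IS,
transverse dispersivity one tenth of that (a standard ratio; the source
material is silent), free-water diffusion of 0.067/0.061 cm^2/h for
NH4/NO3, and Millington-Quirk tortuosity (theta^(7/3)/theta_s^2). NH4
sorption is off by default (`Kd = 0`; the soils have negligible exchange
capacity), with linear retardation available.

Reactions follow the sequential chain NH4 -> NO3 -> N2 with
Michaelis-Menten kinetics modulated by three dimensionless factors:

* `fsw_nitrification()` — a three-branch water-content response rising
  from the wilting point, optimal between saturations 0.665 and 0.809,
  and falling to zero at saturation (oxygen limitation); fitted
  breakpoints `swp = 0.154`, `e1 = 2.267`, `e2 = 1.104`, `fwp = fs = 0`.
* `fsw_denitrification()` — `S^2.86` (threshold `sdn = 0`), so
  denitrification needs wet, poorly aerated soil.
* `f_temperature()` — a bell curve with maximum 1 at `Topt`;
  `f_carbon_depth()` — `exp(-alpha_c z)`, organic carbon declining below
  the infiltrative surface.

Transport and reaction are operator-split, with the reaction sub-stepped
whenever a step would consume more than 10% of a pool, and concentrations
floored at zero with the consumed mass truncated — this keeps the chain
exactly conservative: NH4 consumed equals NO3 produced, NO3 consumed
equals N2 produced. N2 is tracked as a cumulative loss per cell, not
transported (it leaves the system as gas). `nitrogen_mass_balance()`
partitions the cumulative N input into effluent NO3, effluent NH4, N2
loss and storage change; the four fractions close to 100% to round-off.

### Parameters that are not printed anywhere

Four kinetic constants are exposed but have no published values, so the
package fixes defaults once and treats them as calibration targets:

| parameter | default | rationale |
|---|---|---|
| `Km` (both pools) | 5 mg N/L | small against influent concentrations, so the intended zero-order regime holds |
| `Topt` | 22.5 C | midpoint of the 20-25 C range typical for nitrifiers |
| `beta` | 0.177 | places f_t(20 C) near 0.9 for Topt = 25, a mild sensitivity |
| `alpha_c` | 0.02 cm^-1 | halves the carbon supply every ~35 cm of depth |

Maximum rates are never printed either; only layer-average effective
zero-order rates are. `mu_max_from_rate()` inverts the dependency
functions at a layer's reference state (its reported WFPS, 20 C, the
layer mid-depth), and `drainfield_kinetics()` applies this to every
material. The engineered layers (filament, stone) have no reported WFPS
and use a nominal reference saturation of 0.30.

### Influent

Influent total N enters with the dose water and is speciated by effluent
type under the convention that influent organic N is fully mineralized to
NH4 before entering the soil: STE is dosed entirely as NH4-N; ATE (18%
organic N, 26% NH4, 56% NO3) as 44% NH4-N and 56% NO3-N
(`speciate_influent()`; a configurable recalcitrant fraction can pass
organic N through untransformed). The influent chemistry tables of the
companion mesocosm study are not available in numeric form, so the
synthetic generator defaults to field-typical weekly statistics — STE TN
60 ± 9 mg/L, ATE TN 26 ± 5 mg/L — chosen once from the onsite-wastewater
literature and not adjusted thereafter.

## Calibration machinery

`gauss_newton_fit()` minimizes a weighted least-squares objective with a
damped (Marquardt) Gauss-Newton iteration: forward finite-difference
sensitivities at 1% relative perturbation, step acceptance only on
objective decrease, box constraints by projection, convergence on
relative parameter change below 1e-3. With `lambda0 = 0` a linear model
is solved in one accepted step. `composite_scaled_sensitivity()`
implements CSS — the aggregate information the observations carry about
each parameter — and flags parameters whose CSS ratio falls below 0.01
for exclusion from the regression; attempting to fit a structurally
insensitive parameter raises a rank-deficiency error naming it. Weights
default to 1/sigma^2 with sigma per observation group (0.005 cm^3/cm^3
for moisture, 10% of the mean for concentrations) since the original
weighting scheme is unpublished.

The synthetic-data module closes the loop: `synthetic_truth()` fixes a
known parameterization (defaults are the calibrated means, so synthetic
experiments sit in the real systems' regime),
`generate_mesocosm_observations()` runs the forward model and samples it
the way the mesocosms were instrumented (sub-daily moisture at the probe
depths, weekly effluent chemistry), adding Gaussian noise to moisture and
multiplicative lognormal noise to concentrations (non-negative by
construction; no noise model is published). Zero-noise observations equal
the forward output exactly, and an end-to-end fit on them recovers the
truth to 0.1%. What passing these tests does **not** show: real probes
drift, biomats develop over months, and replicate columns differ
structurally — none of which the generator emulates.

## Climate scenarios

`scenario()` encodes the two projected stressors: soil warming (23 C vs
20 C; temperature is spatially uniform and constant per run — no heat
equation, matching the scenario design) and a water table raised by 30 cm.
The rise is implemented by `raise_water_table()`: the seepage outlet moves
up to the new water-table level and everything below starts (and stays)
saturated, thinning the unsaturated zone from 112 to 82 cm in the GEO
geometry. The reported account of below-water-table behavior is
internally tense — complete NO3 conversion in the saturated zone on one
hand, carbon-limited denitrification at depth on the other — so both
controls are exposed (`alpha_c`, and the saturation response itself)
rather than hard-coding either reading. `compare_runs()` reports the N2
and effluent-concentration deltas. The direction checks in the test suite
use `Topt = 25` so that warming from 20 to 23 C moves towards the optimum,
and they assert directions, not magnitudes, because the temperature-shape
parameter is unpublished.

## Problem sizes and run times

The mesocosm meshes are 7-8 columns by 73-83 rows. A 90-day PSND flow
simulation takes on the order of a minute on one core (GEO, with its
localized dosing through the filament, several minutes; P&S, with its
12-hour cycles, well under a minute), and a 90-day transport run tens of
seconds on the stored flux replay. Verification tests run on reduced
columns (1D, a few hundred cells, days-long horizons) so the full suite
stays within minutes.

## Known limitations

* The physical mesocosm is a cylinder; the model domain is the 2D
  vertical plane the mesocosm modeling convention uses. An axisymmetric weighting
  flag exists (`overrides$axisym`) but the plane is the default and the
  tested configuration.
* One seepage node fixes the outlet; the water table is an emergent
  hanging zone, not a controlled boundary, so experimental water-table
  elevations are only approximately honoured.
* NO2- and N2O intermediates, microbial biomass dynamics, gas-phase O2
  transport, pH effects and dynamic biomat growth are out of scope; the
  biomat appears only through the calibrated low saturated conductivity
  of the P&S native sand.
* Temperature enters kinetics only; there is no coupled heat transport.
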