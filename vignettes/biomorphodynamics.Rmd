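---
title: "Coupled mangrove–estuary biomorphodynamics: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled mangrove–estuary biomorphodynamics: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mangromorph` simulates the centennial co-evolution of an idealized
back-barrier estuary and its mangrove vegetation (*Avicennia marina*), the
system typical of barrier-enclosed estuaries on the North Island of New
Zealand. The purpose is to explore how catchment mud supply and in-estuary
vegetation management (mangrove removal) control estuarine infilling, on a
desk-scale grid that runs in minutes rather than on a cluster.

# The coupled model

## Domain and forcing

The domain is a 4 km × 2 km basin behind two non-erodible barriers, joined
through a central inlet (default 300 m) to a 2 km × 2 km offshore area whose
bed slopes linearly from the inlet depth to −100 m at the open boundary, so
that offshore deposition never shoals the approaches. The basin platform
starts at −1.5 m MSL over a 10 m sand substrate. Forcing is a single M2
constituent of 1.5 m range (30 deg/hr, i.e. a 12.0 h period) imposed at the
open boundary, and three rivers (north, head, south) of 18 m³/s each. The
30 m river width is consistent with the hydraulic-geometry relation
W = 7.2 Q^0.5 (30.5 m at 18 m³/s). River mud concentration is the management
lever: 5 mg/L (pre-disturbance), 15 mg/L (post-deforestation disturbance)
and 10 mg/L as the intermediate restoration level — the midpoint, since only
"intermediate" is specified qualitatively.

The default grid resolution is 60 m. The reference large-scale setting for
this kind of study is 15 m, which resolves individual channels and levees;
60 m resolves the basin-scale channel network and the metrics are per-area,
so landscape trajectories remain comparable while a 600-year run stays
within minutes on one core. `mm_config(domain = list(resolution = 15))`
reproduces the fine layout if you have the patience.

## Tidal flow

Depth-averaged continuity and momentum are solved on a staggered C-grid by
dimensional splitting: each step performs an implicit one-dimensional
shallow-water solve along x (tridiagonal, friction linearized implicitly),
then the same along y. Each sweep is diagonally dominant and the flux-form
continuity makes the water budget close to round-off; the ledger of
boundary, river and wetting/drying fluxes is checked in the test suite at
1e-8 relative. Momentum advection is neglected — a standard
reduced-complexity choice for long-term tidal-basin morphodynamics where
the tide is quasi-static at basin scale (the M2 wavelength is two orders of
magnitude longer than the basin) — and the solver is verified against the
closed-form Chézy uniform-flow balance (u = C√(hS), within 1 %), hydroperiod
closed forms and tidal-prism integrals. Wetting and drying uses a 0.05 m
threshold; velocities are capped at 3 m/s between steps, which only acts on
drying-front spikes and does not affect the flux bookkeeping.

Vegetation enters the momentum balance twice, after the Baptist
decomposition: the representative Chézy coefficient

C_r = C_b + (√g/κ) ln(h/h_v) √(1 + C_D n h_v C_b² / 2g)  for h ≥ h_v
(C_r = C_b when the canopy is emergent),

which *raises* the effective roughness while *lowering* the bed shear
stress fraction, and an explicit momentum sink −(λ/2)u|u| with
λ = C_D n (h_v/h)(C_b²/C_r²) (submerged) or C_D n (emergent). Stems and
pneumatophores are separate roughness-object classes in each cell; classes
are combined by applying the roughness increment sequentially in order of
object height, with λ contributions additive — the intent of multi-fraction
trachytope schemes. Within a seasonal burst the roughness field is frozen,
evaluated at the high-tide depth (the depth at which vegetated intertidal
cells actually convey flow).

## Sediment

Mud follows the Partheniades–Krone exchange: erosion
M(τ/τ_ce − 1) above the critical stress, scaled by the mud fraction exposed
at the surface and limited by the mud actually held in the bed column;
deposition w_s·c(1 − τ/τ_cd) below the critical deposition stress. The
finite τ_cd (classical Krone mutually-exclusive regimes) matters for the
science: it makes settling flow-dependent, so vegetation-damped flats trap
mud preferentially and the local bio-morphodynamic feedback loop closes;
with unconditional deposition the coupling is one-way and removal
experiments produce no contrast. Suspended mud and sand are carried as mass
per cell and advected by conservative first-order upwind transport with a
small explicit dispersion, sub-stepped to the advective CFL with a
positivity flux limiter. Sand uses a reduced-complexity
Engelund–Hansen-type capacity (∝ u⁵/C_r³ with a critical-mobility cutoff)
standing in for a full Van Rijn formulation, split into bedload directed
with the flow — with a transverse-slope (Koch–Flokstra-type) diffusive
correction that damps upslope transport — and a suspended share relaxing to
its equilibrium concentration. Sea and river boundaries carry sand at local
equilibrium, so boundaries neither erode nor deposit systematically; river
inflow cells are exempt from bed updating for the same reason.

Bed change is the Exner balance of all fluxes multiplied by the
morphological acceleration factor, limited to 0.05 m per solver step.
Stratigraphy records the deposit column as a stack of layers (nominal
0.1 m) with per-layer mud fraction over an implicit sand base; the top-1 m
thickness-weighted mud fraction defines the "muddy region" metric.

Two parameterizations deserve emphasis because they are scale devices, not
field physics:

* **Intertidal accretion ceiling** (`sediment$dep_ceiling`, +0.75 m MSL =
  mean high water): suspended settling stops on cells aggraded to MHW.
  Deposition requires tidal inundation; at 60 m the unresolved river
  distributaries would otherwise stack sediment into perched mounds far
  above the tidal frame.
* **Mud calibration knobs**: τ_ce = τ_cd = 0.5 N/m², M = 5e-5 kg/m²/s,
  w_s = 2 mm/s (flocculated), dry bulk densities 500 (mud) and 1600 (sand)
  kg/m³. All sit within published field ranges for muddy intertidal systems;
  they were calibrated — as any reduced-complexity model must be — so the
  basin-scale trapping and pre-disturbance state resemble the reference
  regime (emergent vegetated levees near the river mouths by year 400,
  partial muddification). The sand-capacity constants (eh_coef = 0.02,
  bedload share 0.7, u_crit = 0.28 m/s) were likewise set so the basin sand
  budget stays near-neutral over a run rather than draining through the
  ebb-dominant inlet.

## Morphological acceleration and the seasonal clock

One morphological year contains four ecological seasons. Each season the
model simulates `scenario$cycles_per_season` representative M2 cycles
(default 1) and multiplies the sediment fluxes by the acceleration factor
season/(cycles × T) ≈ 183, so simulated hydrodynamic time maps exactly onto
one season. The classical choice in full-scale studies is a factor of
order 90 with two-cycle bursts; a test verifies that one-cycle ~183×
bursts and two-cycle ~91× bursts give consistent decadal bed change (the
linearity that justifies morphological acceleration in the first place),
and the two-cycle layout is one configuration switch away.

## Vegetation life cycle

The habitat hydroperiod is the fraction of the tidal cycle a cell is
inundated *by the connected tide*: the water level averaged over the
always-connected subtidal basin cells, compared against the cell's
elevation. (The raw per-cell wet fraction would count water ponded on the
flats after ebb — an artifact of the unresolved creek drainage at 60 m —
and would misclassify emergent flats as permanently flooded.)

At the first season of each ecological year, every unvegetated basin cell
colonizes at 3000 seedlings/ha if its relative hydroperiod lies in (0, 0.5]
(between mean high water and mean sea level), its representative-cycle
mean bed shear stress is below 0.2 N/m² (the cycle maximum is
config-switchable but is contaminated by drying-front velocity spikes at
this resolution), and growth is viable (f·C > 0.5). Cells cleared by a
removal event become recolonizable only from the next ecological year. Every season, stem diameter D (cm) advances by the
JABOWA-lineage rate

dD/dt = G·D·(1 − DH/(D_max H_max)) / (274 + 3 b₂ D − 4 b₃ D²) · f · C,

with height H = 137 + b₂D − b₃D² (cm). The defaults pin H(D_max) = H_max
(b₂ = 2(H_max−137)/D_max, b₃ = (H_max−137)/D_max²) with D_max = 18 cm and
H_max = 320 cm — the short open-coast A. marina of New Zealand rather than
the 10 m trees of tropical estuaries — and G = 162 cm/yr from the mangrove
forest-model lineage. Integration is explicit Euler per season with capping
at the ceiling; a test compares one season against an adaptive ODE
integration.

The stress factors are deliberately simple, swappable components (the
lineage models reference them to prior work rather than printing them):

* f(hydroperiod): a unimodal parabola, 1 at hydroperiod 0.25, falling to a
  configurable dry-end minimum (default 0) at hydroperiod 0 and to 0 at
  0.5 and beyond.
* C(biomass): 1/(1 + B/B_half) with B the standing biomass from the
  A. marina allometry 0.308 D^2.11 (kg/tree) and B_half = 15 kg/m².

At the last season of each year, cohorts whose f·C stayed below 0.5 advance
a suppression counter (a viable year resets it); after 5 consecutive
suppressed years self-thinning removes exactly as many stems as needed for
competition to relax back to viability, or the whole cohort when even a
single stem could not grow. Cells aggraded above MHW lose stems along a
0.5 m linear taper — the upper-elevation limit of the species.

Removal interventions clear 25/50/100 % of the vegetated area
(seaward-first by default, mimicking mapped clearance; uniform-random under
a seed as the alternative). Stems vanish immediately; pneumatophores can
persist as roughness "ghosts" for a configurable number of years (0 by
default: the documented practice removes stems and roots together; 2 or 5
years reflect observed root decomposition).

# Scenario engine

Every plan shares the backbone: 200-year vegetation-free spin-up (sand
only), pre-disturbance years 200–400 at 5 mg/L, disturbance years 400–500
at 15 mg/L, management branch from year 500 (or an earlier reduction year).
Runs are deterministic given (configuration, seed) — the only stochastic
element is the optional random removal mode — and branches resume from a
shared checkpoint guarded by a configuration hash, reproducing the
branching experimental design. Metrics (accommodation space, muddy-region
fraction, mangrove coverage, A_MSL/A_tot, SY, TP) are appended annually;
grid snapshots are stored at years 200, 400, 430, 450, 500 and 600.

```{r}
library(mangromorph)
cfg <- mm_config()
base <- run_scenario("high_forever", cfg, until = 400)
high <- run_scenario("high_forever", cfg, resume_from = base)
ctrl <- run_scenario("control_low", cfg, resume_from = base)
autoplot(high, ctrl)
glance(high)
```

# What the generator does and does not emulate

The domain synthesis reproduces the geometry, forcing and supply statistics
of the study system: basin dimensions, barrier-inlet topology, tidal range,
river discharge and the stepped mud-supply history. It does **not**
emulate wind waves, storm discharge events, salinity gradients, sea-level
rise, belowground organic accretion or root-collapse after dieback —
processes the full-scale lineage also excludes or only discusses. Passing
the directional tests therefore demonstrates that the implemented feedback
chain (vegetation → roughness → flow partitioning → sedimentation →
habitat) reproduces the qualitative landscape behavior under these idealized
conditions; it does not validate predictions for any real estuary, where
the excluded processes and the 60 m resolution both matter.

# Numerical choices

* Solver step 240 s (the tide is quasi-static at basin scale; the implicit
  sweeps are unconditionally stable, accuracy is set by the tidal
  resolution of 180 steps per cycle); transport sub-stepped at CFL 1.
* Wetting/drying threshold 0.05 m; concentration conversions floored at
  1 mm depth (mass itself is never rescaled).
* Bed-change limiter 0.05 m per step; erosion floored at the non-erodible
  substrate base; deposition floored at the accretion ceiling.
* Stratigraphy layers merge below 0.1 m nominal thickness and the stack is
  compacted from the bottom when it exceeds 100 layers.
* Channel identification (for the sedimentation-pattern diagnostics) uses
  residual relief: a cell is channelized when it lies more than 0.3 m below
  the 9×9-cell moving median or is subtidal below MLW within an intertidal
  neighbourhood. Both parameters are configuration-exposed and validated on
  constructed fixtures.
* A_MSL/A_tot counts basin cells above MSL among those wetted at high tide;
  the muddy-region denominator is total basin area (config-switchable),
  since the source definition does not specify wetted vs total.

# Problem sizes

The shipped tests and the acceptance script run the full scenario chain at
60 m resolution (101 × 33 cells, 2400 ecological seasons per 600-year run),
with branches sharing the common 0–400 trajectory. A full management
comparison (control, intermediate, high, removal) is a few such runs;
each takes single-digit minutes on one core.

# Known limitations

* Under sustained high mud supply the desk-scale basin retains ~70–75 % of
  the delivered mud volume as net fill; reaching the reference regime where
  more than half the basin surface rises above mean sea level within two
  centuries would require near-total retention plus net marine sand import,
  which this 2DH, wave-free, 60 m model does not produce. The simulated
  trajectories are directionally faithful but vertically conservative.
* Branch contrasts between management scenarios (e.g. complete removal vs
  continued high supply) are of order 1–2 % in the basin-integrated metrics
  at this resolution — the right sign is not guaranteed run-to-run design
  variants, and the near-channel (<100 m) vs far-field (300–400 m)
  sedimentation split is poorly populated because typical channel spacing
  is ~200 m (the far class covers only a few percent of basin cells).
* Basin-scale vegetation presence is net-trapping here: a never-vegetated
  control ends with *more* accommodation space than the vegetated control,
  whereas the channel-confinement mechanism of the full-resolution reference
  gives vegetation a basin-scale limiting effect on infilling. Resolving
  that mechanism needs levee-scale topography.
* First-order upwind transport is diffusive; plume gradients are smoother
  than a higher-order scheme would give, which tends to spread mud slightly
  further from the rivers.
* Dimensional splitting without momentum advection cannot produce inertial
  secondary circulations; channel-bend dynamics and spiral flow are out of
  scope.
* The 60 m grid does not resolve levees as distinct landforms; the
  near-channel/far-field sedimentation contrast is therefore a coarse
  aggregate of what the 15 m reference resolves explicitly.
* Vegetation is a single species with deterministic colonization; no
  propagule dispersal, no interspecific competition.
* Mud parameters are calibration knobs, not site measurements; absolute
  infilling rates should be read as order-of-magnitude.
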