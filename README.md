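# mangromorph

Reduced-complexity bio-morphodynamic simulation of mangrove estuaries.

## The problem

Barrier-enclosed estuaries on the North Island of New Zealand have been
filling with mud since catchment deforestation raised river sediment loads
by an order of magnitude, and the expanding mangrove forests (*Avicennia
marina*) are widely blamed. Management has responded with local mangrove
clearance, on the local-scale logic that vegetation traps sediment, so
removing it should slow the muddying. Whether that logic survives the jump
from a vegetated flat to a whole estuary — an interconnected landscape of
channels, flats and forest — is a bio-morphodynamic question: vegetation
changes the flow field, the flow field redistributes sediment, and sediment
builds or destroys vegetation habitat.

`mangromorph` is a desk-scale simulator for exactly this question: an
idealized 4 km x 2 km back-barrier basin (initial bed −1.5 m MSL) behind
two non-erodible barriers, an inlet to a 2 km offshore strip sloping to
−100 m, an M2 tide of 1.5 m range, and three rivers of 18 m³/s whose mud
concentration is stepped through pre-disturbance (5 mg/L), disturbance
(15 mg/L) and management phases. It couples, century over century:

* **Tidal flow** — depth-averaged continuity/momentum on a staggered grid
  (implicit dimensional splitting, wetting/drying), with vegetation entering
  through the Baptist roughness decomposition
  `C_r = C_b + (sqrt(g)/kappa) ln(h/h_v) sqrt(1 + C_D n h_v C_b^2/(2g))`
  and the momentum sink `-(lambda/2) u|u|`,
  `lambda = C_D n (h_v/h)(C_b/C_r)^2`.
* **Sediment** — Partheniades–Krone mud exchange
  (`E = M max(tau/tau_ce - 1, 0)`, `D = w_s c max(1 - tau/tau_cd, 0)`),
  capacity-based sand transport with a transverse-slope correction,
  conservative upwind advection of suspended mass, Exner bed updating with
  morphological acceleration, and a layered stratigraphy recording the mud
  fraction of the substrate.
* **Mangroves** — seasonal colonization (3000 seedlings/ha where the
  relative hydroperiod is in (0, 0.5] and bed shear stress is below
  0.2 N/m²), JABOWA-type diameter growth
  `dD/dt = G D (1 - DH/(D_max H_max)) / (274 + 3 b2 D - 4 b3 D^2) * f * C`,
  hydroperiod fitness `f`, biomass competition `C`, five-year suppression
  self-thinning, and removal interventions with optional root persistence.

Landscape metrics follow the scenario year by year: accommodation space
(basin volume below high tide), muddy-region fraction (top-1 m mud fraction
above 30 %), mangrove coverage, the relative basin area above mean sea
level (A_MSL/A_tot), and the annual sediment yield over tidal prism (SY/TP).

## A worked example

```r
library(mangromorph)

cfg <- mm_config()                                   # 60 m desk-scale grid
base <- run_scenario("high_forever", cfg, until = 400) # spin-up + pre-disturbance
high <- run_scenario("high_forever", cfg, resume_from = base)
ctrl <- run_scenario("control_low",  cfg, resume_from = base)

glance(high)
```

```
# A tibble: 1 x 10
  scenario     years accommodation_m3 muddy_fraction coverage  amsl   SY_TP
  <chr>        <int>            <dbl>          <dbl>    <dbl> <dbl>   <dbl>
1 high_forever   600         9524550.          0.634    0.131 0.381 0.00770
```

```r
glance(ctrl)
```

```
# A tibble: 1 x 10
  scenario    years accommodation_m3 muddy_fraction coverage  amsl   SY_TP
  <chr>       <int>            <dbl>          <dbl>    <dbl> <dbl>   <dbl>
1 control_low   600        13651061.          0.433    0.111 0.188 0.00180
```

Two centuries of elevated mud supply (15 mg/L vs 5 mg/L) roughly halve the
remaining accommodation space (9.5 vs 13.7 million m³ of the initial
~17.9 million), push the muddy share of the basin substrate from 43 % to
63 %, and double the potential mangrove habitat (the basin fraction above
mean sea level, `amsl`: 0.38 vs 0.19). `autoplot(high, ctrl)` draws the four
trajectories; `tidy(run)` returns the annual metrics table;
`run_scenario("remove_100", cfg, resume_from = ...)` plays the
100 %-clearance management branch, and `scenario_catalogue()` lists all
built-in experiments. A 600-year run at 60 m takes a few minutes on one
core; each management branch reuses the shared spin-up/disturbance
checkpoint.

A thin command-line front end is included for shell use:

```sh
Rscript inst/cli/mangromorph.R run --scenario high_forever --seed 1 --out out/
```

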