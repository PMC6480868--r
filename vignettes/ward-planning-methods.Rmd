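---
title: "Planning paediatric and obstetric wards: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning paediatric and obstetric wards: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wardplan)
```

## The planning problem

Rural regions face a structural conflict in hospital planning: paediatric
and obstetric wards have high fixed and step-fixed costs (round-the-clock
staffing minima, bed stocks, department overheads), while a shrinking and
aging population delivers fewer cases every year. Fewer, larger wards are
cheaper per case; more, smaller wards are closer to patients. `wardplan`
quantifies the economic half of this trade-off from the perspective of the
providers: given a regional case load, which hospitals should run which
wards, and what does every configuration earn or lose?

The model covers two aggregate case classes, a paediatric case and a
birth, each remunerated by a DRG-style lump sum (rebate) per case. Only
operating economics are modelled: under dual hospital financing, capital
costs (buildings, equipment) are state-funded and excluded.

## The contribution-margin ladder

For a ward treating $x$ cases a year the package books, in order:

* revenue $x \cdot d$ (rebate $d$ per case),
* variable (direct) costs $x \cdot a$ — drugs, food, implants,
* **contribution I** $= x(d-a)$,
* DRG-specific fixed costs (default 0 in the applied model),
* **contribution II**,
* the department-level block: department fixed cost $FA$, bed costs
  $b \cdot bA$, and step-fixed staff costs $\sum_i K_i w_i$,
* **contribution III**, the ward's margin,
* hospital fixed costs $FK$ (default 0) below the per-ward ladders.

Staff units $K_i$ and beds $b$ are integers. For an open ward,

$$K_i = \max\left(K_i^{\min},\ \left\lceil \frac{x \, c_i}{k_i} \right\rceil\right),
\qquad
b = \max\left(b^{\min},\ \left\lceil \frac{x \, v}{365} \right\rceil\right),$$

with $c_i$ the care hours of category $i$ per case, $k_i$ the annual
productive hours of one unit, and $v$ the length of stay in days. A
365-day year is used — the "full capacity utilization" framing — with no
occupancy-rate discount. The margin is therefore piecewise linear in $x$:
between steps it grows by exactly $d-a$ per case
(`ward_contribution()` documents and tests this).

## Parameters and their provenance

All constants derive from primitive assumptions via exported functions,
so every number in a report can be traced:

| quantity | value | derivation |
|---|---|---|
| annual staff capacity | 1760 h | 40 h/week × (52 − 8) weeks |
| nurse/midwife unit cost | 56,700 EUR | 42,000 × 1.35 employer share |
| physician unit cost | 101,250 EUR | 75,000 × 1.35 |
| paediatric rebate | 1505.68488 EUR | 3117.36 base value × CMI 0.483 |
| obstetric rebate | 3135.11 EUR | canonical constant (below) |
| mixed obstetric stay | 4.9172 d | 0.356 × 7.3 + 0.644 × 3.6 |
| paediatric nursing | 16.12 h/case | 5.2 h/day × 3.1 days |
| obstetric nursing | 22.62 h/birth | (2.8 + 1.8) h/day × 4.9172 days |
| midwife time | 14.5 h/birth | average delivery duration |
| staffing minima | 9 nurses, 5 physicians, 5 midwives | coverage rules |

Three derivations deserve comment, because the published constants are
not mutually consistent and a choice had to be made:

* **The paediatric rebate is used unrounded.** Rounding 1505.68488 to
  cents before multiplying by ~1800 annual cases shifts ward margins by
  several euros; the reference results only reconcile with the unrounded
  product.
* **The obstetric rebate is stored as the canonical 3135.11.** The base
  value times the obstetric case-mix index (1.006) gives 3136.06, while
  3135.10 is the figure usually quoted; the scenario margins, however,
  reconcile to the euro only with ≈3135.109. We store 3135.11 as the
  default and leave it configurable — `derive_rebate()` remains available
  for users who prefer the strict product.
* **Minimum midwives default to 5.** The coverage rule (one midwife
  around the clock, 40-hour weeks, 8 absence weeks) gives 5; a head
  midwife who also attends births could reduce it to 4, but the scenario
  accounts reconcile only with 5. Configurable via
  `default_parameters(min_midwives = )`.

The caesarean theatre-nursing time (300 min per section) is recorded on
the primitives but deliberately not folded into the ward nursing
coefficient, which represents ward care for mother and newborn; folding
it in would overstate the coefficient relative to the applied model.
The obstetric physician coefficient (≈2.42 h/birth) never binds: the
five-physician minimum dominates at every regionally plausible volume.

## The optimisation model

`plan_region()` maximises the regional total contribution margin over

* binary ward-open flags per (ward type, hospital),
* an integer case allocation $x_{jk}$ with $\sum_k x_{jk} = B_j$
  (all regional patients are treated),
* integer staff units and beds per open ward, bounded below by the
  open-ward minima,

with big-M links tying activity to the open flags. Opening a ward —
not treating its first case — triggers the fixed block, so an open ward
with zero allocated cases still pays department fixed costs, minimum
staffing and minimum beds. Hospitals are cost-identical (the location
does not change the cost structure), and economies of scale are excluded
by construction: all gains come from spreading fixed blocks over more
cases.

Because the instance is small (two ward types, a handful of sites) the
program is solved exactly rather than through an external MILP library:
the solver enumerates all admissible open/close configurations and, for
each, allocates every ward type's demand by dynamic programming — a
min-plus convolution of the integer-case step-cost vectors, memoised
across configurations. Every configuration is visited and each
allocation subproblem is solved exactly, so the optimum is proven, not
approximate (optimality gap 0). Ties between symmetric optima go to the
configuration with fewest open wards and lowest hospital indices, making
reports reproducible. `enumerate_plans()` provides an independent
brute-force check: it walks the same configurations and a full integer
grid of case splits, pricing each cell through `ward_contribution()`
alone, and must agree with the solver at grid step 1 (it refuses grids
beyond ~2×10⁴ cells; the test suite runs it on two-hospital instances
with a few dozen cases).

Scenario constraints supported: an exact number of open hospitals, an
exact number of open wards per type (1 concentrates each ward type), a
flag tying ward openings to hospital openings (the two-hospital scenario
needs both wards at both open sites), and fully fixed allocations/bed
stocks (the status-quo scenarios).

## Break-even volumes

Because the margin has downward jumps at every staff or bed step, it can
touch zero and fall back below it: the obstetric curve first reaches a
non-negative value at 848 births, only to turn negative again two births
later when the next midwife unit is due. `break_even()` therefore uses a
suffix definition — the smallest volume at and *above* which the margin
stays non-negative up to the scan cap (default 5000) — which is the
planning-relevant notion of durable viability. With default parameters
this yields 1587 paediatric cases (14 beds) and 894 births (13 beds).

## Classical formulas

Two textbook formulas frame the analysis. `hill_burton_beds()` computes
the classical bed demand $B = P h V / (a \cdot 1000 \cdot 365)$.
`hexagon_cost_per_capita()` computes annual hospital cost per inhabitant
when catchments tile the region as regular hexagons of maximal travel
distance $r$: $K/P = \frac{AT}{P \cdot 3 r^2 \sin 60^\circ} F + h v$,
with $\sin 60^\circ = \sqrt{3}/2$ (degrees; hexagon geometry) and $h$
documented as admissions per inhabitant and year — callers using rates
per 1000 must scale. No published numeric targets exist for these
curves, so they are verified by properties: strict decrease in $r$ and
population, the $1/r^2$ scaling of the fixed component, and the $h v$
floor as $F \to 0$.

## Catchments and accessibility

`assign_catchments()` assigns each municipality, by its centre point, to
the nearest open hospital by travel time (ties to the lower hospital
id), and aggregates case counts to catchment totals. Real road-network
routing is out of scope: the module consumes precomputed travel-time
matrices from CSV or from the synthetic generator, so the published
empirical accessibility percentages of the study region are not
reproduced here. Competitor hospitals in neighbouring regions can be
included as extra matrix columns; they capture municipalities but
contribute nothing to the economics. Properties guaranteed and tested:
closing a hospital never shortens any travel time and never shrinks the
population share beyond any threshold; catchment case totals always sum
to the regional totals.

## The synthetic region generator

`simulate_region()` emulates the data structure the analysis needs,
without external geodata: municipality centres uniform on a 2:1
rectangle, lognormal municipality sizes (few towns, many villages;
log-sd 1.1) normalised to the regional population, fixed at-risk strata
fractions, Poisson case counts with stratum-proportional means,
hospitals at the most populous places, and travel times as Euclidean
distance × 1.1 min/km (detour factor and rural speed folded together).
Defaults are fixed once at study-region scale: 3,930 km², 240,000
inhabitants, 10.7% children under 18 and 14.6% women aged 15–50, and
admission/birth rates (0.117, 0.029 per person at risk and year) chosen
so the expected regional case load matches the observed ≈3,000
paediatric cases and ≈1,000 births. Hospital demand exceeds regional
demand by the external inflow fractions 0.12 (paediatrics) and 0.42
(births), matching the observed hospital/catchment case ratios.

What the generator does *not* emulate: road networks (straight-line
travel only), demand elasticity with distance, cross-border patient
choice, seasonal and stochastic occupancy peaks, and demographic change
over time. Passing tests on synthetic regions therefore demonstrate the
*mechanics* of the pipeline — conservation, monotonicity,
optimality — not the empirical accessibility of any real region.

`study_region()` returns the observed 2014 fixture (per-hospital case
loads, catchment totals, bed stocks) used by the scenario presets.

## Numerical choices

* Euro amounts are kept in full double precision internally; report
  tables round half-up to whole euros, utilization to whole percent.
* Ceiling operations are applied to values pre-rounded at 9 decimals to
  keep binary floating-point noise from flipping a step at an exact
  boundary.
* The solver treats objective ties within 10⁻⁹ EUR as equal and keeps
  the earlier (sparser, lower-index) configuration.
* Problem sizes: the scenario suite and tests solve instances up to
  ~3,400 cases over three hospitals; a full solve including the
  two-hospital dynamic program completes in about a second on one core.

## Known limitations

* Provider perspective only: patient travel costs, financer and societal
  perspectives are outside the objective.
* Constant case load: demand does not react to distance or quality.
* The published department fixed costs (576,500 / 679,000 EUR) are used
  as given; they cannot be decomposed into their stated components from
  the available figures.
* Printed reference tables carry internal inconsistencies (a paediatric
  column subtotal off by exactly 3,000 EUR from its own cells; aggregate
  utilization percentages); the package reproduces cells and grand
  totals and reports internally consistent totals.
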