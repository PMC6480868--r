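# wardplan

Economic planning of paediatric and obstetric hospital wards in rural
regions, where small case volumes meet large fixed costs. The package is
written for health-systems analysts and hospital planners who need to
answer, with transparent arithmetic: *which hospitals in a region should
run which wards, what does every configuration earn or lose, and what
case volume makes a ward viable at all?*

## The model in brief

Each ward type (a paediatric case, a birth) is remunerated by a DRG lump
sum $d$ per case against variable cost $a$. A ward treating $x$ cases a
year earns the contribution margin

$$\text{CM}_{III}(x) = x\,(d-a) \;-\; FA \;-\; b\cdot bA \;-\; \sum_i K_i\, w_i,$$

where the department fixed cost $FA$, the integer bed stock
$b = \max(b^{\min}, \lceil x v / 365\rceil)$ at $bA$ EUR per bed, and
integer staff units
$K_i = \max(K_i^{\min}, \lceil x c_i / k_i \rceil)$ at $w_i$ EUR per
unit are *step-fixed*: constant over ranges of $x$, jumping when the
next nurse, midwife, physician or bed is due. Open wards pay
round-the-clock staffing minima (9 nurses, 5 physicians, 5 midwives)
whether or not the cases fill them.

On top of the ladder sits an exact location-allocation optimiser: over
binary ward-open flags, an integer case allocation $x_{jk}$ covering the
whole regional demand ($\sum_k x_{jk} = B_j$), and the integer staffing
and bed variables, `plan_region()` maximises the regional total margin.
The solve enumerates every admissible open/close configuration and
allocates cases by exact dynamic programming, so the returned plan is
provably optimal; `enumerate_plans()` is an independent brute-force
cross-check. `break_even()` scans for the smallest durably viable ward
volume, `hill_burton_beds()` and `hexagon_cost_per_capita()` implement
the classical planning formulas, `assign_catchments()` and
`travel_band_table()` handle nearest-hospital travel-time analysis, and
`simulate_region()` generates synthetic regions so the whole pipeline
runs without external geodata.

## Worked example

The built-in scenarios analyse a three-hospital region (university
hospital plus two primary-care hospitals) at its observed case loads:

```r
library(wardplan)

rep <- run_scenario(scenario_config("three-fixed-beds"))
print(rep)
#> Scenario 'three-fixed-beds': objective -4,449,209 EUR
#>    hospital        ward beds cases utilization_pct contribution
#>  Greifswald paediatrics   24  1820              64      49899.4
#>  Greifswald  obstetrics   24   800              45    -378567.8
#>     Wolgast paediatrics   18  1057              50    -494091.2
#>     Wolgast  obstetrics   11   357              44   -1169486.9
#>      Anklam paediatrics   16   496              26   -1165970.5
#>      Anklam  obstetrics    6   280              63   -1290991.8
```

At historical bed stocks every ward except Greifswald paediatrics loses
money; the region as a whole is 4.45 million EUR short per year. Shrinking
bed stocks to full utilization (`"three-optimized-beds"`) narrows the gap
to −3.6 million EUR, still far from viability. Concentration turns the
sign around:

```r
one <- run_scenario(scenario_config("one-hospital"))
one$objective
#> one-hospital objective: 2,087,599
```

A single site treating all 3,373 paediatric cases (29 beds) and 1,437
births (20 beds) earns a 2.1 million EUR margin; the best two-hospital
configuration (`"two-hospitals"`) still loses about 237,000 EUR. The
break-even search explains why — the region simply cannot feed two of
either ward:

```r
p <- default_parameters()
break_even(p$wards$obstetrics, p)
#> Break-even at 894 cases/year (13 beds); margin there 2,071 EUR
break_even(p$wards$paediatrics, p)
#> Break-even at 1587 cases/year (14 beds); margin there 563 EUR
```

The accessibility side of the trade-off is quantified with
`travel_band_table()` on a travel-time matrix (from CSV or
`simulate_region()`): closing sites never shortens anyone's trip, and
the band table shows who ends up beyond 20, 30 or 40 minutes.

See the vignette (`vignettes/ward-planning-methods.Rmd`) for the model's
assumptions, parameter provenance and design decisions.

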