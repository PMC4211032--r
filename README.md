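# ambucea

Societal-perspective cost-effectiveness analysis of mobile-app home
monitoring versus in-person clinic visits for the first postoperative
month after ambulatory breast reconstruction. The package is aimed at
health-economics analysts and methodologists who want the full decision
model — micro-costing ledger, incremental analysis, deterministic and
probabilistic sensitivity analyses, and a synthetic patient cohort — as
tested, configurable, seeded code rather than a spreadsheet.

## The model

Two follow-up strategies are compared pairwise over a 30-day horizon.
Costs are micro-costed per patient and tagged by payer stratum
(health system, patient/caregiver, external), so results are available
from both the societal and the narrower health-system perspective.
Effectiveness *E* is the probability of a successful 30-day surgical
outcome; the base case models equal effectiveness (ΔE = 0), under which
the incremental cost-effectiveness ratio ΔC/ΔE is undefined and flagged
**not reportable**. Decisions then rest on the incremental net benefit

INB(λ) = λ·ΔE + ΔC,

with ΔC oriented as the cost saving of the mobile arm and
λ = $109,970 CAD/QALY × 0.04 QALY = **$4398.80 CAD per successful
outcome**. Uncertainty is handled three ways: a scenario analysis over
visit counts and mobile-to-clinic crossover, a two-way grid over
patient leisure cost × mobile effectiveness, and a 10,000-draw Monte
Carlo PSA (uniform ±20% clinic cost, uniform ±2 pp effects, gamma
patient wage) summarised as an ICER plane and a cost-effectiveness
acceptability curve.

## Worked example

```r
library(ambucea)

base_case()
#> # A tibble: 2 × 10
#>   perspective   cost_mobile cost_in_person delta_cost_cad delta_cost_usd
#>   <chr>               <dbl>          <dbl>          <dbl>          <dbl>
#> 1 societal             136.           381.          245.           223.
#> 2 health_system        136.           174.           38.4           35.0
#> # ℹ 5 more variables: delta_effect <dbl>, icer_reportable <lgl>,
#> #   quadrant <chr>, lambda <dbl>, inb <dbl>
```

Mobile follow-up costs $136 per patient against $381 for in-person
care (1.64 visits): a societal saving of $245 CAD ($223 USD), of which
only $38 accrues to the health system — the patient keeps most of the
saving (travel, leisure, caregiver time, parking). `icer_reportable` is
`FALSE` in both rows because ΔE = 0; the INB column equals the cost
saving at any willingness to pay.

```r
psa <- run_psa(psa_spec(n_draws = 10000, seed = 20140922))
psa
#> <cea_psa> 10000 draws (seed 20140922)
#>   mobile cost:    mean $135.77 (sd 0.00)
#>   in-person cost: mean $381.15 (sd 46.56)
#>   preferred at lambda $4398.80: 100.0% of draws
```

No mobile-arm parameter is varied, so its mean is exactly the
deterministic ledger sum; the in-person mean reflects clinic-cost and
wage uncertainty, and the mobile arm is preferred in essentially all
draws at the base-case threshold. Downstream: `ceac(psa)` for the
acceptability curve, `icer_plane(psa)` for per-draw (ΔE, ΔC) points and
quadrant counts, `autoplot()` on any of these, `two_way()` for the
leisure-cost × effectiveness INB grid, `scenario_visits()` for visit
and crossover scenarios, `generate_cohort()` + `cohort_costs()` for
patient-level simulation, and `render_report()` to write the CSV/JSON
report. Model parameters live in a YAML configuration
(`load_config()`; the packaged default is
`inst/extdata/config.yaml`).

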