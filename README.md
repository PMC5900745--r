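# oppcost

Opportunity-cost valuation of hospital bed-days.

Hospital beds rarely carry a market price, yet every admission displaces the
next-best use of the same beds. Health-economic evaluations conventionally
price bed-days with reference costs — the expenditure of the *chosen* stay —
which is only adequate under perfect competition, where a pound spent buys a
pound of benefit. `oppcost` is a costing engine for analysts and health
technology assessment practitioners that makes the choice explicit: it values
a bed-day consumption against the second-best patient group forgone, under
the decision maker's actual objective (health, revenue, throughput, ...).

## The model

A case mix is a set of patient groups competing for the same beds, each with
per-patient length of stay `LOS_j`, expenditure `C_j`, and optionally revenue
`R_j` and health gain `B_j` (QALYs). A chosen consumption of `LOS_i` bed-days
at expenditure `C_i` is valued by one of four methodologies:

* **A — units forgone.** Patient-equivalents `LOS_i / LOS_j · E` or
  treatment-equivalents `C_i / C_j`, where `E` is the effective occupancy
  factor (1 under excess demand).
* **B — net benefit of the second-best alternative forgone.** Monetary or
  health valuations of the displaced patient-equivalents, including the
  net-monetary-benefit form
  `OC_i = LOS_i · (B_j·λ − C_j) / LOS_j · E`,
  with `λ` the local cost-effectiveness threshold (money per QALY) and
  `NMB = B·λ − C`.
* **C — expenditure of the chosen option.** `C_i`, or its variable-cost share
  reported separately alongside the bed-days.
* **D — economic cost.** `C_i` plus the highest net benefit forgone, for
  consumptions that were not the optimal use of the beds.

Fourteen estimators (approaches 1–9 and New1–New5; approach 3 has three
variants, approach 8 returns a pair) cover the taxonomy; `assess_optimality()`
determines whether the chosen option maximised total NMB and therefore
whether Methodology B or D yields the true opportunity cost.

## Worked example

The built-in fixture is a ward with three patient groups at `λ` = £20,000/QALY
and full occupancy: P1 (10 bed-days, £7,000, 1.3 QALYs, chosen), P2 (5
bed-days, £5,000, 0.6 QALYs, second-best), P3 (5 bed-days, £5,000, 0.4 QALYs).

```r
library(oppcost)

fx <- worked_example()
results <- evaluate_all(fx$case_mix, fx$context)
tidy(results)[, c("approach_id", "unit", "value")]
#> # A tibble: 16 × 3
#>    approach_id unit                    value
#>    <chr>       <chr>                   <dbl>
#>  1 1           patient_equivalents      2
#>  2 2           treatment_equivalents    1.4
#>  3 3a          money                10000
#>  4 3b          money                12000
#>  5 3c          money                 2000
#>  6 5           money                24000
#>  7 New1        money                14000
#>  8 New2        money                 9800
#>  9 4           QALYs                    1.2
#> 10 6           QALYs                    0.35
#> 11 New3        QALYs                    0.7
#> 12 New4        QALYs                    0.49
#> 13 7           money                 7000
#> 14 8           money                 3500
#> 15 9           money                 9000
#> 16 New5        money                21000
```

P1's 10 bed-days could have treated 2 patient-equivalents of P2 (approach 1),
worth £24,000 gross (approach 5) and £14,000 net of P2's expenditure
(approach New1) — against the £7,000 a reference-cost valuation (approach 7)
would report. The estimates span £2,000–£24,000 because each answers a
different agent's question.

```r
assess_optimality(fx$case_mix, fx$context)
#> <optimality assessment>
#> # A tibble: 3 × 7
#>   id    chosen n_forgone expenditure_total gross_benefit_total nmb_total
#>   <chr> <lgl>      <dbl>             <dbl>               <dbl>     <dbl>
#> 1 P1    TRUE           1              7000               26000     19000
#> 2 P2    FALSE          2             10000               24000     14000
#> 3 P3    FALSE          2             10000               16000      6000
#> # i 1 more variable: expenditure_plus_highest_forgone_nmb <dbl>
#> optimal option:       P1
#> chosen (P1) optimal:  TRUE
#> methodology:          B
#> true opportunity cost: £14,000
```

P1 maximises total NMB, so Methodology B applies and the true opportunity
cost of the 10 bed-days is the forgone second-best net benefit of £14,000.
Had P1 been suboptimal, Methodology D would add P1's expenditure on top.

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/oppcost.R demo
Rscript inst/cli/oppcost.R evaluate --case-mix inst/extdata/worked-example.csv --approach New1
Rscript inst/cli/oppcost.R sweep --param ocr --grid 0.75:1.0:0.25 --approach 1
```

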