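---
title: "Valuing the opportunity cost of hospital bed-days"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing the opportunity cost of hospital bed-days}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oppcost)
```

## The problem

Bed-days are a major cost driver in every analysis involving inpatient
stays, but they have no market price. The economic value of occupying a bed
is what the next-best use of that bed would have produced — a second-best
patient group that was not admitted. Pragmatic costing conventions
(reference costs, tariffs, accounting averages) price the *chosen* stay
instead, which implicitly assumes perfectly competitive prices: a pound of
expenditure buys exactly a pound of forgone benefit. Hospital care violates
essentially every condition of that model, so the conventional number and
the opportunity cost can differ several-fold.

`oppcost` organises bed-day valuation into four methodologies and fourteen
estimators, and automates the choice logic between them.

## Data model

* A **patient group** is one alternative use of the beds, described per
  patient: length of stay `los_per_patient` (bed-days, strictly positive),
  `expenditure_per_patient`, and optionally `revenue_per_patient`,
  `qaly_gain_per_patient` and a variable-cost share. QALY gains must be
  *marginal* gains from treatment relative to no treatment — otherwise a
  perfectly healthy person would appear to benefit most from a bed.
* The **chosen option** is the consumption being valued: total bed-days
  `los_total` (possibly only the excess part of a stay, e.g. during an
  outbreak), total expenditure, and optionally its variable-cost share and
  own benefit/revenue for optimality checks. It is usually one of the groups
  (`case_mix(options, chosen = "P1")`) but can be external, e.g. beds lost
  to a ward closure.
* The **economic context** carries the cost-effectiveness threshold `λ`
  (money per QALY; no default — it is a local policy quantity), the
  occupancy rate, the excess-demand flag, the ranking objective and an
  informational perspective label.

## The estimators

With `LOS_i`, `C_i`, `VC_i` for the chosen option, `LOS_j`, `C_j`, `R_j`,
`B_j` for the forgone group, `λ` the threshold and `E` the effective
occupancy factor:

| Approach | Formula | Unit |
|---|---|---|
| 1 | `LOS_i / LOS_j · E` | patient-equivalents |
| 2 | `C_i / C_j` | treatment-equivalents |
| 3a | `LOS_i · C_j / LOS_j` | money |
| 3b | `LOS_i · (R_j / LOS_j) · E` | money |
| 3c | `LOS_i · (R_j − C_j) / LOS_j` | money |
| 5 | `LOS_i · B_j · λ / LOS_j` | money |
| New1 | `LOS_i · (B_j λ − C_j) / LOS_j · E` | money |
| New2 | `C_i · (B_j λ − C_j) / C_j` | money |
| 4 | `LOS_i · B_j / LOS_j` | QALYs |
| 6 | `C_i / λ` | QALYs |
| New3 | `LOS_i · (B_j − C_j/λ) / LOS_j · E` | QALYs |
| New4 | `C_i · (B_j − C_j/λ) / C_j` | QALYs |
| 7 | `C_i` | money |
| 8 | `(VC_i, LOS_i)`, reported separately | money & bed-days |
| 9 | `C_i + LOS_i (R_j − C_j) / LOS_j` | money |
| New5 | `C_i + LOS_i (B_j λ − C_j) / LOS_j · E` | money |

Useful algebra, exercised as property tests: `NMB = λ · NHB` bridges the
monetary and health rows (New1 = λ·New3, New2 = λ·New4, 5 = λ·4); the
Methodology D rows decompose exactly as C plus B (9 = 7 + 3c,
New5 = 7 + New1); and under perfect competition (`R_j = C_j`, or
`B_j λ = C_j`) every net term vanishes and all methodologies collapse onto
the chosen expenditure — which is precisely the assumption the conventional
approach makes tacitly.

## Occupancy and excess demand

Freed beds only produce forgone value if they are refilled. The occupancy
rate enters as a multiplicative factor `E ≤ 1` on the patient-equivalent
flows — approaches 1, 3b, New1 and New3, and through New1 the forgone term
of New5. Treatment-equivalent bases (2, New2, New4) carry no occupancy term:
money, unlike a freed bed, is assumed spendable elsewhere. Under excess
demand (waiting lists, patients awaiting admission — the default) `E = 1`
and the adjustment is omitted entirely; empty beds then carry no forgone
health value. This multiplicative-trailing-factor reading is one of two ways
the printed formulas can be parsed; we chose it because it matches both
published uses of the adjustment (a 0.75 occupancy scaling of
patient-equivalents, and a 0–25% revenue haircut), and we expose the choice
through the `excess_demand` flag rather than hard-coding either reading.

For exogenous shocks (outbreaks, closures), `effective_bed_days()` composes
the consumption to value: observed case bed-days are scaled by a scalar
`excess_attribution_fraction` (length-of-stay during epidemics is subject to
time-dependent bias, so only part of a stay is excess; full multistate
modelling is out of scope), plus all beds lost unoccupied to isolation or
closure.

## Ranking, second-best and the decision layer

`rank_case_mix()` orders groups by a per-patient score under an explicit
objective — throughput (`1/LOS`), expenditure, revenue, net revenue, health,
or NMB. The engine never guesses the objective: different maximands can pick
different second-bests, and that choice belongs to the analyst. Scores are
per patient; totals over displaced equivalents appear only in the optimality
assessment. Under `objective = "expenditure"` larger spend ranks higher (a
cost-recovery agent); this is a documented convention, as no rule is
standard. Ties (relative tolerance 1e-9) keep input order, set a flag and
warn — determinism without asserting an unstated preference.

`assess_optimality()` compares the chosen option's realized totals (its own
single stay, not equivalents) against each alternative's totals over the
fractional patient-equivalents `LOS_i / LOS_j · E` the bed-days would have
displaced. Fractional equivalents are kept in all computations —
`floor_patient_equivalents()` exists for presentation only, since flooring
would break the decomposition identities. Two equivalent characterisations
of optimality are implemented and cross-checked: the chosen option maximises
total NMB, and its expenditure plus the highest NMB forgone is smaller than
its own gross benefit. An exact tie counts as optimal (weak optimality): an
equilibrium choice should not be declared suboptimal. The recommended
methodology is B when the chosen option is optimal (true opportunity cost =
highest forgone NMB) and D otherwise (chosen expenditure added on top).
Displacement is evaluated one group at a time; mixtures of groups filling
the freed bed-days form a packing problem we note as an extension.

## Numerical conventions

Monetary values are plain doubles; comparisons use a relative tolerance of
1e-9 and rounding to two decimals happens only at presentation. Negative
forgone net benefits are returned unclamped with a warning — clamping would
break `New5 = 7 + New1`. A zero expenditure denominator in the
treatment-equivalent bases is a hard error rather than infinity. In batch
evaluation (`evaluate_all()`) approaches whose inputs are missing are
skipped with a logged notice so partially specified case mixes remain
usable; single-approach calls (`evaluate_approach()`) error instead.

## The synthetic generator

`generate_case_mix()` emulates a ward-level case mix: log-normal lengths of
stay with a 5-bed-day median (sdlog 0.5, a realistic acute-care spread),
per-day costs uniform on 500–1,500, revenue as a −10% to +30% markup on
cost, and uniform QALY gains on [0, 1.5] — non-negative by default because
benefits are marginal gains from treatment; a negative lower bound is
available for stress tests. The chosen option is NMB-optimal with
probability 0.8 and uniformly random otherwise, so roughly 10–20% of
generated mixes have a suboptimal chosen option and exercise the
Methodology D path that the built-in worked example cannot reach. The
generator is fully deterministic under its seed and restores the caller's
RNG state.

What generated data do not emulate: correlation between severity, cost and
benefit; within-group heterogeneity; capacity dynamics and waiting-list
feedback; and real tariff structures. Passing property tests therefore
certify the algebra and the decision logic, not the empirical realism of any
particular valuation.

The property suite checks the decomposition, threshold-bridge, degeneracy
and optimality-agreement identities on 10,000 generated mixes of 2–5 groups
(seeds 1–10,000), plus 200-mix versions in the regular unit tests; the whole
suite runs in well under a minute on one CPU.

## Limitations

The engine takes `λ`, lengths of stay, expenditures and QALY gains as given:
threshold estimation, disease natural-history modelling, willingness-to-pay
elicitation, equity weighting and multi-criteria analysis are out of scope.
Whether `C_i` is provider expenditure or a reimbursement payment under a
payer perspective is encoded by the analyst in the inputs; the `perspective`
field documents the choice but changes no computation.
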