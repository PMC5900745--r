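# The fourteen opportunity-cost estimators, each a pure function of
# (chosen consumption, forgone alternative group, economic context).
#
# Methodology letters:
#   A - units of the second-best alternative forgone
#   B - net benefit of the second-best alternative forgone
#   C - expenditure of the alternative chosen
#   D - chosen expenditure plus the highest net benefit forgone
#
# The effective occupancy factor E multiplies only the patient-equivalent
# flows (approaches 1, 3b, New1, New3); treatment-equivalent bases carry no
# occupancy term, and E = 1 under excess demand.

# pull a per-patient field off a group (list or one-row data frame), or error
need_j <- function(group, field, approach) {
  if (is.data.frame(group)) group <- as_group(group)
  val <- group[[field]]
  if (is.null(val) || is.na(val)) {
    abort_missing_input(field, sprintf("for the forgone alternative (approach %s)", approach))
  }
  val
}

need_i <- function(chosen, field, approach) {
  val <- chosen[[field]]
  if (is.null(val) || is.na(val)) {
    abort_missing_input(field, sprintf("for the chosen option (approach %s)", approach))
  }
  val
}

#' Approach 1: patient-equivalents forgone
#'
#' The number of second-best patients that could have been treated with the
#' chosen option's bed-days: \eqn{LOS_i \cdot (1/LOS_j) \cdot E}, where E is
#' the effective occupancy factor ([effective_occupancy()]). Fractional
#' values are returned as-is; see [floor_patient_equivalents()] for a
#' whole-patient presentation.
#'
#' @param chosen A [chosen_option()].
#' @param second_best A forgone patient group (one row of a case-mix options
#'   table, or the list returned by [second_best()]).
#' @param context An [economic_context()].
#' @return Patient-equivalents (dimensionless).
#' @examples
#' fx <- worked_example()
#' patient_equivalents(resolve_chosen(fx$case_mix),
#'                     second_best(fx$case_mix, fx$context), fx$context) # 2
#' @export
patient_equivalents <- function(chosen, second_best, context) {
  los_i <- need_i(chosen, "los_total", "1")
  los_j <- need_j(second_best, "los_per_patient", "1")
  los_i / los_j * effective_occupancy(context)
}

#' Present patient-equivalents as whole displaced patients
#'
#' Floors a fractional patient-equivalent count for reporting and returns the
#' remainder; the fractional value remains the computational quantity.
#'
#' @param pe Patient-equivalents, possibly fractional.
#' @return A tibble with columns `whole_patients` and `remainder`.
#' @export
floor_patient_equivalents <- function(pe) {
  tibble(whole_patients = floor(pe), remainder = pe - floor(pe))
}

#' Approach 2: treatment-equivalents forgone
#'
#' The number of second-best treatments purchasable with the chosen option's
#' expenditure: \eqn{C_i / C_j}.
#'
#' @inheritParams patient_equivalents
#' @return Treatment-equivalents (dimensionless).
#' @export
treatment_equivalents <- function(chosen, second_best) {
  c_i <- need_i(chosen, "expenditure_total", "2")
  c_j <- need_j(second_best, "expenditure_per_patient", "2")
  if (c_j == 0) {
    oc_abort("Approach 2 is undefined when the alternative's expenditure is zero.",
             class = "oppcost_degenerate_denominator")
  }
  c_i / c_j
}

#' Approaches 3a-3c: money forgone on the second-best patient-equivalents
#'
#' Values the displaced patient-equivalents monetarily:
#' * `expenditure` (3a): \eqn{LOS_i \cdot C_j / LOS_j}
#' * `revenue` (3b): \eqn{LOS_i \cdot (R_j / LOS_j) \cdot E}
#' * `net_revenue` (3c): \eqn{LOS_i \cdot (R_j - C_j) / LOS_j}
#'
#' @inheritParams patient_equivalents
#' @param mode `"expenditure"`, `"revenue"` or `"net_revenue"`.
#' @return Money.
#' @export
monetary_forgone <- function(chosen, second_best, context,
                             mode = c("expenditure", "revenue", "net_revenue")) {
  mode <- mode[1]
  if (!mode %in% c("expenditure", "revenue", "net_revenue")) {
    abort_validation(sprintf("Unknown mode '%s'.", mode))
  }
  los_i <- need_i(chosen, "los_total", paste0("3", c(expenditure = "a", revenue = "b", net_revenue = "c")[mode]))
  los_j <- need_j(second_best, "los_per_patient", "3")
  switch(mode,
    expenditure = los_i * need_j(second_best, "expenditure_per_patient", "3a") / los_j,
    revenue = los_i * (need_j(second_best, "revenue_per_patient", "3b") / los_j) *
      effective_occupancy(context),
    net_revenue = los_i * (need_j(second_best, "revenue_per_patient", "3c") -
                             need_j(second_best, "expenditure_per_patient", "3c")) / los_j
  )
}

#' Approach 4: gross health benefit forgone
#'
#' QALYs the displaced patient-equivalents would have gained:
#' \eqn{LOS_i \cdot B_j / LOS_j}.
#'
#' @inheritParams patient_equivalents
#' @return QALYs.
#' @export
health_forgone_gross <- function(chosen, second_best) {
  need_i(chosen, "los_total", "4") *
    need_j(second_best, "qaly_gain_per_patient", "4") /
    need_j(second_best, "los_per_patient", "4")
}

#' Approach 5: gross monetary benefit forgone
#'
#' The gross health benefit forgone valued at the threshold:
#' \eqn{LOS_i \cdot B_j \cdot \lambda / LOS_j}.
#'
#' @inheritParams patient_equivalents
#' @return Money.
#' @export
monetary_benefit_forgone_gross <- function(chosen, second_best, context) {
  health_forgone_gross(chosen, second_best) * context$threshold
}

#' Approach 6: health benefit forgone for expected second-best use
#'
#' Converts the expenditure incurred into QALYs at the local
#' cost-effectiveness threshold: \eqn{C_i / \lambda}. The only Methodology B
#' approach that needs no explicit alternative: the threshold stands in for
#' the marginal intervention displaced elsewhere in the budget.
#'
#' @inheritParams patient_equivalents
#' @return QALYs.
#' @export
threshold_conversion <- function(chosen, context) {
  stopifnot(inherits(context, "oc_context"))
  need_i(chosen, "expenditure_total", "6") / context$threshold
}

#' Approach 7: expenditure for the resource consumption incurred
#'
#' The conventional reference-cost valuation: the chosen option's own
#' expenditure \eqn{C_i}, with no reference to any alternative. Adequate only
#' under perfect competition, where prices equal forgone benefits.
#'
#' @inheritParams patient_equivalents
#' @return Money.
#' @export
expenditure_incurred <- function(chosen) {
  need_i(chosen, "expenditure_total", "7")
}

#' Approach 8: variable expenditure and bed-days, separately
#'
#' Splits the valuation into the variable-cost share (the part realisable as
#' cash savings in the short run) and the non-monetary bed-day consumption,
#' reported side by side and never summed.
#'
#' @inheritParams patient_equivalents
#' @return A tibble with columns `variable_cost` (money) and `bed_days`.
#' @export
variable_cost_split <- function(chosen) {
  tibble(
    variable_cost = need_i(chosen, "variable_cost_total", "8"),
    bed_days = need_i(chosen, "los_total", "8")
  )
}

#' New1/New2: net monetary benefit forgone
#'
#' The net monetary benefit of the forgone alternative, per displaced unit:
#' * `patient_equiv` (New1): \eqn{LOS_i (B_j \lambda - C_j) / LOS_j \cdot E}
#' * `treatment_equiv` (New2): \eqn{C_i (B_j \lambda - C_j) / C_j} (no
#'   occupancy term on the expenditure basis)
#'
#' A negative value (the alternative's expenditure exceeds the monetary value
#' of its health gain) is returned unchanged, with a warning; clamping would
#' break the decomposition with Methodology D.
#'
#' @inheritParams patient_equivalents
#' @param basis `"patient_equiv"` or `"treatment_equiv"`.
#' @return Money.
#' @examples
#' fx <- worked_example()
#' nmb_forgone(resolve_chosen(fx$case_mix),
#'             second_best(fx$case_mix, fx$context), fx$context) # 14000
#' @export
nmb_forgone <- function(chosen, second_best, context,
                        basis = c("patient_equiv", "treatment_equiv")) {
  basis <- basis[1]
  if (!basis %in% c("patient_equiv", "treatment_equiv")) {
    abort_validation(sprintf("Unknown basis '%s'.", basis))
  }
  id <- if (basis == "patient_equiv") "New1" else "New2"
  b_j <- need_j(second_best, "qaly_gain_per_patient", id)
  c_j <- need_j(second_best, "expenditure_per_patient", id)
  net_j <- net_monetary_benefit(b_j, context$threshold, c_j)
  out <- if (basis == "patient_equiv") {
    need_i(chosen, "los_total", id) * net_j /
      need_j(second_best, "los_per_patient", id) *
      effective_occupancy(context)
  } else {
    if (c_j == 0) {
      oc_abort("Treatment-equivalent basis is undefined when the alternative's expenditure is zero.",
               class = "oppcost_degenerate_denominator")
    }
    need_i(chosen, "expenditure_total", id) * net_j / c_j
  }
  if (out < 0 && !oc_near(out, 0)) {
    warn("Forgone net benefit is negative: the second-best alternative has negative net monetary benefit.",
         class = "oppcost_negative_nmb")
  }
  out
}

#' New3/New4: net health benefit forgone
#'
#' As [nmb_forgone()] but expressed in QALYs:
#' `patient_equiv` (New3) gives \eqn{LOS_i (B_j - C_j/\lambda) / LOS_j \cdot E},
#' `treatment_equiv` (New4) gives \eqn{C_i (B_j - C_j/\lambda) / C_j}.
#' Identically equal to `nmb_forgone() / threshold`.
#'
#' @inheritParams nmb_forgone
#' @return QALYs.
#' @export
nhb_forgone <- function(chosen, second_best, context,
                        basis = c("patient_equiv", "treatment_equiv")) {
  nmb_forgone(chosen, second_best, context, basis) / context$threshold
}

#' Approach 9 / New5: economic cost of the chosen option (Methodology D)
#'
#' For a chosen option that is not (known to be) optimal, the opportunity
#' cost is the expenditure incurred plus the highest net benefit forgone:
#' * `net_revenue` (9): \eqn{C_i + LOS_i (R_j - C_j) / LOS_j}
#' * `nmb` (New5): \eqn{C_i + LOS_i (B_j \lambda - C_j) / LOS_j}
#'
#' `best_forgone` must be the forgone alternative with the greatest net value
#' under the relevant maximand — not necessarily the global second-best.
#'
#' @inheritParams patient_equivalents
#' @param best_forgone The greatest-net-value forgone group.
#' @param mode `"net_revenue"` (Approach 9) or `"nmb"` (New5).
#' @return Money.
#' @export
economic_cost <- function(chosen, best_forgone, context,
                          mode = c("net_revenue", "nmb")) {
  mode <- mode[1]
  if (!mode %in% c("net_revenue", "nmb")) {
    abort_validation(sprintf("Unknown mode '%s'.", mode))
  }
  expenditure_incurred(chosen) +
    if (mode == "net_revenue") {
      monetary_forgone(chosen, best_forgone, context, "net_revenue")
    } else {
      nmb_forgone(chosen, best_forgone, context, "patient_equiv")
    }
}
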