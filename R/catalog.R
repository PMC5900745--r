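#' Catalog of bed-day opportunity-cost approaches
#'
#' One row per approach variant, in report order: the two unit-based
#' approaches (Methodology A), the ten net-benefit valuations (Methodology B,
#' monetary then health units), the two chosen-expenditure approaches
#' (Methodology C), and the two economic-cost approaches (Methodology D).
#'
#' @return A 16-row tibble with columns `approach_id`, `methodology`, `unit`,
#'   `description`, `required_fields` (list-column of the input fields each
#'   approach needs).
#' @examples
#' approach_catalog()
#' @export
approach_catalog <- function() {
  tibble(
    approach_id = c("1", "2", "3a", "3b", "3c", "5", "New1", "New2",
                    "4", "6", "New3", "New4", "7", "8", "9", "New5"),
    methodology = c("A", "A", rep("B", 10), "C", "C", "D", "D"),
    unit = c("patient_equivalents", "treatment_equivalents",
             "money", "money", "money", "money", "money", "money",
             "QALYs", "QALYs", "QALYs", "QALYs",
             "money", "money", "money", "money"),
    description = c(
      "Patient-equivalents (of second-best patients) forgone",
      "Treatment-equivalents forgone for the second-best patients",
      "Expenditure forgone on the second-best patient-equivalents",
      "Revenue forgone from the second-best patient-equivalents",
      "Net revenue forgone from the second-best patient-equivalents",
      "Gross monetary benefit forgone for the second-best patient-equivalents",
      "Net monetary benefit forgone for the second-best patient-equivalents",
      "Net monetary benefit forgone for the second-best treatment-equivalents",
      "Gross health benefit forgone for second-best patient-equivalents",
      "Health benefit forgone for expected second-best use",
      "Net health benefit forgone for the second-best patient-equivalents",
      "Net health benefit forgone for the second-best treatment-equivalents",
      "Expenditure for the resource consumption incurred",
      "Separating variable expenditure and non-monetary resource consumption",
      "Expenditure incurred + highest net revenue forgone",
      "Expenditure incurred + highest net monetary benefit forgone"
    ),
    required_fields = list(
      c("los_total", "los_per_patient"),
      c("expenditure_total", "expenditure_per_patient"),
      c("los_total", "los_per_patient", "expenditure_per_patient"),
      c("los_total", "los_per_patient", "revenue_per_patient"),
      c("los_total", "los_per_patient", "revenue_per_patient", "expenditure_per_patient"),
      c("los_total", "los_per_patient", "qaly_gain_per_patient"),
      c("los_total", "los_per_patient", "qaly_gain_per_patient", "expenditure_per_patient"),
      c("expenditure_total", "expenditure_per_patient", "qaly_gain_per_patient"),
      c("los_total", "los_per_patient", "qaly_gain_per_patient"),
      c("expenditure_total"),
      c("los_total", "los_per_patient", "qaly_gain_per_patient", "expenditure_per_patient"),
      c("expenditure_total", "expenditure_per_patient", "qaly_gain_per_patient"),
      c("expenditure_total"),
      c("variable_cost_total", "los_total"),
      c("expenditure_total", "los_total", "los_per_patient",
        "revenue_per_patient", "expenditure_per_patient"),
      c("expenditure_total", "los_total", "los_per_patient",
        "qaly_gain_per_patient", "expenditure_per_patient")
    )
  )
}

# which fields of an approach refer to the chosen option
.oc_chosen_fields <- c("los_total", "expenditure_total", "variable_cost_total")

# does the group/chosen pair carry every field the approach needs?
has_fields <- function(fields, chosen, group) {
  for (f in fields) {
    src <- if (f %in% .oc_chosen_fields) chosen else group
    v <- src[[f]]
    if (is.null(v) || is.na(v)) return(FALSE)
  }
  TRUE
}

# For Methodology D the comparator is the forgone alternative with the
# greatest net value under the relevant maximand (net revenue for 9, NMB for
# New5) per displaced patient-equivalent cohort, not necessarily the global
# second-best. Returns a group list or NULL.
best_forgone_group <- function(cm, chosen, context, mode) {
  alts <- forgone_options(cm)
  if (nrow(alts) == 0) return(NULL)
  col_needed <- if (mode == "net_revenue") "revenue_per_patient" else "qaly_gain_per_patient"
  if (!col_needed %in% names(alts) || anyNA(alts[[col_needed]])) return(NULL)
  net_per_patient <- if (mode == "net_revenue") {
    alts$revenue_per_patient - alts$expenditure_per_patient
  } else {
    net_monetary_benefit(alts$qaly_gain_per_patient, context$threshold,
                         alts$expenditure_per_patient)
  }
  # total net value over the patient-equivalents the chosen bed-days displace
  total <- chosen$los_total * net_per_patient / alts$los_per_patient
  as_group(alts[which.max(total), ])
}

compute_approach <- function(id, chosen, sb, bf_nr, bf_nmb, context) {
  switch(
    id,
    "1" = patient_equivalents(chosen, sb, context),
    "2" = treatment_equivalents(chosen, sb),
    "3a" = monetary_forgone(chosen, sb, context, "expenditure"),
    "3b" = monetary_forgone(chosen, sb, context, "revenue"),
    "3c" = monetary_forgone(chosen, sb, context, "net_revenue"),
    "4" = health_forgone_gross(chosen, sb),
    "5" = monetary_benefit_forgone_gross(chosen, sb, context),
    "6" = threshold_conversion(chosen, context),
    "7" = expenditure_incurred(chosen),
    "8" = variable_cost_split(chosen)$variable_cost,
    "9" = economic_cost(chosen, bf_nr, context, "net_revenue"),
    "New1" = nmb_forgone(chosen, sb, context, "patient_equiv"),
    "New2" = nmb_forgone(chosen, sb, context, "treatment_equiv"),
    "New3" = nhb_forgone(chosen, sb, context, "patient_equiv"),
    "New4" = nhb_forgone(chosen, sb, context, "treatment_equiv"),
    "New5" = economic_cost(chosen, bf_nmb, context, "nmb")
  )
}

#' Evaluate every applicable opportunity-cost approach on a case mix
#'
#' Resolves the chosen consumption and the second-best alternative, then
#' computes each approach in the [approach_catalog()] whose required inputs
#' are present. In this batch form, approaches with missing inputs are
#' skipped with a logged notice rather than an error; use
#' [evaluate_approach()] for a strict single-approach call. Approach 8's pair
#' is carried as `value` (variable cost) plus `secondary_value` (bed-days).
#'
#' @param cm A [case_mix()].
#' @param context An [economic_context()].
#' @param quiet Suppress skip notices.
#' @return An `oc_results` tibble with one row per computed approach:
#'   `approach_id`, `methodology`, `unit`, `value`, `secondary_value`,
#'   `description`, plus attributes `context`, `chosen_id`, `second_best`,
#'   `skipped`.
#' @examples
#' fx <- worked_example()
#' evaluate_all(fx$case_mix, fx$context)
#' @export
evaluate_all <- function(cm, context, quiet = FALSE) {
  stopifnot(inherits(cm, "oc_case_mix"), inherits(context, "oc_context"))
  chosen <- resolve_chosen(cm)
  sb <- second_best_for_evaluation(cm, context)
  bf_nr <- best_forgone_group(cm, chosen, context, "net_revenue")
  bf_nmb <- best_forgone_group(cm, chosen, context, "nmb")
  cat <- approach_catalog()

  # Methodology C needs no alternative; everything else (including the
  # threshold conversion, whose alternative is implicit) is only reported
  # when a forgone alternative exists.
  comparator <- function(id) {
    switch(id, "9" = bf_nr, "New5" = bf_nmb, "7" = , "8" = chosen, sb)
  }
  value <- rep(NA_real_, nrow(cat))
  secondary <- rep(NA_real_, nrow(cat))
  keep <- logical(nrow(cat))
  for (k in seq_len(nrow(cat))) {
    id <- cat$approach_id[k]
    comp <- comparator(id)
    if (is.null(comp) || !has_fields(cat$required_fields[[k]], chosen, comp)) {
      if (!quiet) {
        inform(sprintf("Skipping approach %s: required inputs not available.", id))
      }
      next
    }
    value[k] <- compute_approach(id, chosen, sb, bf_nr, bf_nmb, context)
    if (id == "8") secondary[k] <- chosen$los_total
    keep[k] <- TRUE
  }
  out <- cat[keep, c("approach_id", "methodology", "unit", "description")]
  out$value <- value[keep]
  out$secondary_value <- secondary[keep]
  out <- out[, c("approach_id", "methodology", "unit", "value",
                 "secondary_value", "description")]
  structure(
    out,
    class = c("oc_results", class(out)),
    context = context,
    chosen_id = chosen$id,
    second_best = if (is.null(sb)) NA_character_ else sb$id,
    skipped = cat$approach_id[!keep]
  )
}

# second-best used for Methodology A/B; NULL when no alternative or when the
# objective's fields are missing (fall back to any available alternative by
# trying simpler objectives).
second_best_for_evaluation <- function(cm, context) {
  alts <- forgone_options(cm)
  if (nrow(alts) == 0) return(NULL)
  sb <- tryCatch(second_best(cm, context), oppcost_missing_input = function(e) NULL)
  if (!is.null(sb)) return(sb)
  # objective fields absent on some group: rank by throughput, always possible
  ctx2 <- context
  ctx2$objective <- "throughput"
  second_best(cm, ctx2)
}

#' Evaluate a single approach, strictly
#'
#' Unlike [evaluate_all()], a missing required input or an unresolvable
#' alternative is an error here.
#'
#' @inheritParams evaluate_all
#' @param approach_id One id from [approach_catalog()].
#' @return A one-row `oc_results` tibble (two values for Approach 8).
#' @export
evaluate_approach <- function(cm, context, approach_id) {
  cat <- approach_catalog()
  if (!approach_id %in% cat$approach_id) {
    abort_validation(sprintf(
      "Unknown approach '%s'. Known approaches: %s.",
      approach_id, paste(cat$approach_id, collapse = ", ")))
  }
  chosen <- resolve_chosen(cm)
  row <- cat[cat$approach_id == approach_id, ]
  needs_alternative <- row$methodology %in% c("A", "B", "D")
  sb <- second_best_for_evaluation(cm, context)
  bf_nr <- best_forgone_group(cm, chosen, context, "net_revenue")
  bf_nmb <- best_forgone_group(cm, chosen, context, "nmb")
  comp <- switch(approach_id, "9" = bf_nr, "New5" = bf_nmb, sb)
  if (needs_alternative && is.null(comp)) {
    oc_abort(sprintf(
      "Approach %s needs a forgone alternative, but the case mix has none (or it lacks the needed fields).",
      approach_id), class = "oppcost_missing_alternative")
  }
  value <- compute_approach(approach_id, chosen, sb, bf_nr, bf_nmb, context)
  out <- row[, c("approach_id", "methodology", "unit", "description")]
  out$value <- value
  out$secondary_value <- if (approach_id == "8") chosen$los_total else NA_real_
  out <- out[, c("approach_id", "methodology", "unit", "value",
                 "secondary_value", "description")]
  structure(out, class = c("oc_results", class(out)),
            context = context, chosen_id = chosen$id,
            second_best = if (is.null(sb)) NA_character_ else sb$id,
            skipped = character(0))
}
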