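#' Describe the resource consumption being valued
#'
#' A chosen option is the bed-day consumption whose opportunity cost is to be
#' estimated: total bed-days consumed (possibly only the *excess* consumption,
#' not the whole length of stay), the expenditure incurred, and optionally its
#' variable-cost share, revenue and QALY gain (the latter two are needed only
#' for optimality checks).
#'
#' @param id Label for the chosen option.
#' @param los_total Bed-days consumed (\eqn{LOS_i}), non-negative.
#' @param expenditure_total Expenditure incurred (\eqn{C_i}), non-negative.
#' @param variable_cost_total Optional variable-cost share of the expenditure
#'   (\eqn{VC_i}); must not exceed `expenditure_total`.
#' @param revenue_total Optional revenue of the chosen option.
#' @param qaly_gain_total Optional QALY gain of the chosen option.
#' @return An object of class `oc_chosen`.
#' @examples
#' chosen_option("P1", los_total = 10, expenditure_total = 7000,
#'               variable_cost_total = 3500)
#' @export
chosen_option <- function(id, los_total, expenditure_total,
                          variable_cost_total = NULL,
                          revenue_total = NULL,
                          qaly_gain_total = NULL) {
  if (!is.numeric(los_total) || los_total < 0) {
    abort_validation("`los_total` must be a non-negative number of bed-days.")
  }
  if (!is.numeric(expenditure_total) || expenditure_total < 0) {
    abort_validation("`expenditure_total` must be non-negative.")
  }
  if (!is.null(variable_cost_total)) {
    if (!is.numeric(variable_cost_total) || variable_cost_total < 0) {
      abort_validation("`variable_cost_total` must be non-negative.")
    }
    if (variable_cost_total > expenditure_total + .oc_tol * expenditure_total) {
      abort_validation("`variable_cost_total` must not exceed `expenditure_total`.")
    }
  }
  structure(
    list(
      id = as.character(id),
      los_total = as.numeric(los_total),
      expenditure_total = as.numeric(expenditure_total),
      variable_cost_total = if (is.null(variable_cost_total)) NULL else as.numeric(variable_cost_total),
      revenue_total = if (is.null(revenue_total)) NULL else as.numeric(revenue_total),
      qaly_gain_total = if (is.null(qaly_gain_total)) NULL else as.numeric(qaly_gain_total)
    ),
    class = "oc_chosen"
  )
}

# columns a case-mix options table may carry, beyond `id`
.oc_group_cols <- c("los_per_patient", "expenditure_per_patient",
                    "variable_cost_per_patient", "revenue_per_patient",
                    "qaly_gain_per_patient", "n_available")

#' Build a case mix of competing patient groups
#'
#' A case mix is the set of alternative uses of the same beds: one row per
#' patient group with its per-patient bed-days (length of stay), expenditure,
#' and optionally revenue and QALY gain, plus a designation of which option's
#' consumption is being valued (the "chosen" option).
#'
#' @param options A data frame with columns `id`, `los_per_patient` (> 0),
#'   `expenditure_per_patient` (>= 0), and optionally
#'   `variable_cost_per_patient`, `revenue_per_patient`,
#'   `qaly_gain_per_patient`, `n_available`. Unknown columns are kept as
#'   annotations.
#' @param chosen Either the `id` of one option, or a [chosen_option()] object
#'   describing an external consumption. When an id is given, the chosen
#'   consumption is that group's single-stay values (one patient's bed-days
#'   and expenditure).
#' @return An object of class `oc_case_mix`: a list with the validated
#'   `options` tibble and the `chosen` designation.
#' @examples
#' opts <- tibble::tibble(
#'   id = c("P1", "P2"),
#'   los_per_patient = c(10, 5),
#'   expenditure_per_patient = c(7000, 5000),
#'   qaly_gain_per_patient = c(1.3, 0.6)
#' )
#' case_mix(opts, chosen = "P1")
#' @export
case_mix <- function(options, chosen) {
  if (!is.data.frame(options) || nrow(options) < 1) {
    oc_abort("A case mix needs at least one patient group.",
             class = "oppcost_empty_input")
  }
  options <- as_tibble(options)
  for (col in c("id", "los_per_patient", "expenditure_per_patient")) {
    if (!col %in% names(options)) {
      abort_missing_input(col, "in the case-mix options table")
    }
  }
  options$id <- as.character(options$id)
  if (anyDuplicated(options$id)) {
    abort_validation("Patient-group ids must be unique.")
  }
  if (any(!is.finite(options$los_per_patient)) ||
      any(options$los_per_patient <= 0)) {
    abort_validation("`los_per_patient` must be strictly positive for every group.")
  }
  for (col in intersect(.oc_group_cols[-1], names(options))) {
    bad <- !is.na(options[[col]]) & options[[col]] < 0
    if (any(bad)) {
      abort_validation(sprintf("`%s` must be non-negative (group %s).",
                               col, options$id[which(bad)[1]]))
    }
  }
  if (all(c("variable_cost_per_patient", "expenditure_per_patient") %in% names(options))) {
    bad <- !is.na(options$variable_cost_per_patient) &
      options$variable_cost_per_patient > options$expenditure_per_patient
    if (any(bad)) {
      abort_validation(sprintf(
        "Variable cost exceeds expenditure for group %s.",
        options$id[which(bad)[1]]))
    }
  }
  if (inherits(chosen, "oc_chosen")) {
    chosen_id <- chosen$id
  } else if (is.character(chosen) && length(chosen) == 1) {
    if (!chosen %in% options$id) {
      abort_validation(sprintf("Chosen id '%s' is not in the options table.", chosen))
    }
    chosen_id <- chosen
  } else {
    abort_validation("`chosen` must be an option id or a chosen_option().")
  }
  structure(
    list(options = options, chosen = chosen, chosen_id = chosen_id),
    class = "oc_case_mix"
  )
}

#' Resolve the chosen consumption of a case mix
#'
#' Returns the [chosen_option()] being valued. When the case mix designates a
#' group by id, the chosen consumption is that group's single-stay values.
#'
#' @param cm An [case_mix()] object.
#' @return An `oc_chosen` object.
#' @export
resolve_chosen <- function(cm) {
  stopifnot(inherits(cm, "oc_case_mix"))
  if (inherits(cm$chosen, "oc_chosen")) return(cm$chosen)
  row <- cm$options[cm$options$id == cm$chosen_id, ]
  get0 <- function(col) {
    if (col %in% names(row) && !is.na(row[[col]][1])) row[[col]][1] else NULL
  }
  chosen_option(
    id = row$id[1],
    los_total = row$los_per_patient[1],
    expenditure_total = row$expenditure_per_patient[1],
    variable_cost_total = get0("variable_cost_per_patient"),
    revenue_total = get0("revenue_per_patient"),
    qaly_gain_total = get0("qaly_gain_per_patient")
  )
}

# single-row tibble -> list of per-patient fields used by the estimators
as_group <- function(row) {
  g <- list(
    id = row$id[1],
    los_per_patient = row$los_per_patient[1],
    expenditure_per_patient = row$expenditure_per_patient[1]
  )
  for (col in c("revenue_per_patient", "qaly_gain_per_patient",
                "variable_cost_per_patient", "n_available")) {
    if (col %in% names(row) && !is.na(row[[col]][1])) g[[col]] <- row[[col]][1]
  }
  g
}

# alternatives to the chosen option, as a tibble (possibly 0 rows)
forgone_options <- function(cm) {
  cm$options[cm$options$id != cm$chosen_id, , drop = FALSE]
}

#' @export
print.oc_case_mix <- function(x, ...) {
  cat(sprintf("<case mix: %d patient group%s, chosen = %s>\n",
              nrow(x$options), if (nrow(x$options) == 1) "" else "s",
              x$chosen_id))
  print(x$options)
  invisible(x)
}
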