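#' Assess whether the chosen option was optimal, and value its bed-days
#'
#' For a health-maximising decision maker, compares the chosen option's
#' realized totals against the totals each alternative group would have
#' produced with the same bed-days: the displaceable patient-equivalents
#' `n_forgone` (\eqn{LOS_i / LOS_j}, scaled by the effective occupancy
#' factor, fractional by design), total expenditure, total gross monetary
#' benefit (\eqn{B \lambda n}) and total net monetary benefit. The chosen
#' option's own row uses its realized single-stay values.
#'
#' The chosen option is optimal when its total NMB is at least that of every
#' alternative — equivalently, when its expenditure plus the highest NMB
#' forgone is smaller than its own gross benefit (exact ties count as
#' optimal). When optimal, Methodology B applies and the true opportunity
#' cost of the bed-days is the highest forgone net monetary benefit; when
#' suboptimal, Methodology D applies and the chosen expenditure is added on
#' top.
#'
#' @param cm A [case_mix()]; every option needs `los_per_patient`,
#'   `expenditure_per_patient` and `qaly_gain_per_patient`.
#' @param context An [economic_context()].
#' @return An `oc_optimality` object: a list with `assessments` (one tibble
#'   row per option: `id`, `chosen`, `n_forgone`, `expenditure_total`,
#'   `gross_benefit_total`, `nmb_total`,
#'   `expenditure_plus_highest_forgone_nmb`), `optimal_id`,
#'   `chosen_is_optimal`, `recommended_methodology` (`"B"` or `"D"`),
#'   `true_opportunity_cost` (`NA` when the case mix has no alternative) and
#'   `tie_flag`.
#' @examples
#' fx <- worked_example()
#' assess_optimality(fx$case_mix, fx$context)
#' @export
assess_optimality <- function(cm, context) {
  stopifnot(inherits(cm, "oc_case_mix"), inherits(context, "oc_context"))
  opts <- cm$options
  for (col in c("qaly_gain_per_patient", "expenditure_per_patient", "los_per_patient")) {
    if (!col %in% names(opts) || anyNA(opts[[col]])) {
      missing_in <- if (col %in% names(opts)) opts$id[is.na(opts[[col]])][1] else opts$id[1]
      abort_missing_input(col, sprintf("for option %s in the optimality assessment", missing_in))
    }
  }
  chosen <- resolve_chosen(cm)
  if (is.null(chosen$qaly_gain_total)) {
    abort_missing_input("qaly_gain_total", "for the chosen option in the optimality assessment")
  }
  e_occ <- effective_occupancy(context)
  lambda <- context$threshold

  ids <- opts$id
  n_forgone <- chosen$los_total / opts$los_per_patient * e_occ
  expenditure <- n_forgone * opts$expenditure_per_patient
  gross <- n_forgone * opts$qaly_gain_per_patient * lambda
  is_chosen <- ids == cm$chosen_id
  if (any(is_chosen)) {
    # chosen row: realized single-stay totals, not equivalents
    n_forgone[is_chosen] <- 1
    expenditure[is_chosen] <- chosen$expenditure_total
    gross[is_chosen] <- chosen$qaly_gain_total * lambda
  } else {
    # external chosen consumption: every listed group is an alternative
    ids <- c(chosen$id, ids)
    n_forgone <- c(1, n_forgone)
    expenditure <- c(chosen$expenditure_total, expenditure)
    gross <- c(chosen$qaly_gain_total * lambda, gross)
    is_chosen <- c(TRUE, is_chosen)
  }
  nmb <- gross - expenditure

  highest_other_nmb <- vapply(seq_along(nmb), function(k) {
    if (length(nmb) == 1) NA_real_ else max(nmb[-k])
  }, numeric(1))
  exp_plus <- expenditure + highest_other_nmb

  best_k <- which.max(nmb)
  tie <- sum(oc_near(nmb, nmb[best_k])) > 1
  chosen_k <- which(is_chosen)
  has_alt <- length(nmb) > 1
  chosen_is_optimal <- !has_alt ||
    nmb[chosen_k] >= max(nmb[-chosen_k]) - .oc_tol * max(1, abs(nmb[chosen_k]))
  methodology <- if (chosen_is_optimal) "B" else "D"
  true_oc <- if (!has_alt) {
    NA_real_
  } else {
    highest_forgone <- max(nmb[-chosen_k])
    if (chosen_is_optimal) highest_forgone else chosen$expenditure_total + highest_forgone
  }

  assessments <- tibble::new_tibble(
    list(
      id = ids,
      chosen = is_chosen,
      n_forgone = n_forgone,
      expenditure_total = expenditure,
      gross_benefit_total = gross,
      nmb_total = nmb,
      expenditure_plus_highest_forgone_nmb = exp_plus
    ),
    nrow = length(ids)
  )
  structure(
    list(
      assessments = assessments,
      optimal_id = opts$id[best_k],
      chosen_is_optimal = chosen_is_optimal,
      recommended_methodology = methodology,
      true_opportunity_cost = true_oc,
      tie_flag = tie,
      chosen_id = cm$chosen_id,
      context = context
    ),
    class = "oc_optimality"
  )
}

#' @export
print.oc_optimality <- function(x, ...) {
  cat("<optimality assessment>\n")
  print(x$assessments)
  cat(sprintf("optimal option:       %s%s\n", x$optimal_id,
              if (x$tie_flag) " (tied)" else ""))
  cat(sprintf("chosen (%s) optimal:  %s\n", x$chosen_id, x$chosen_is_optimal))
  cat(sprintf("methodology:          %s\n", x$recommended_methodology))
  if (is.na(x$true_opportunity_cost)) {
    cat("true opportunity cost: no alternative use available\n")
  } else {
    cat(sprintf("true opportunity cost: %s\n",
                format_money(x$true_opportunity_cost, x$context$currency)))
  }
  invisible(x)
}

#' Bed-days attributable to an exogenous shock
#'
#' During unplanned events (epidemics, ward closures, heat waves), the
#' bed-days to be valued are the excess share of the stays of treated cases
#' plus any beds lost unoccupied through isolation or closure:
#' `consumed * attribution + lost`. Length-of-stay during epidemics is
#' subject to time-dependent bias, so only a proportion of the observed stay
#' is an excess stay; `excess_attribution_fraction` is that scalar proportion.
#'
#' @param beds_consumed_by_cases Bed-days consumed treating cases during the
#'   event.
#' @param beds_lost_unoccupied Bed-days lost unoccupied (isolation, closed
#'   bays/wards).
#' @param excess_attribution_fraction Fraction in \[0, 1\] of the consumed
#'   bed-days that is truly excess (default 1).
#' @return Bed-days, to be used as a chosen option's `los_total`.
#' @examples
#' effective_bed_days(10, 4)       # 14
#' effective_bed_days(10, 4, 0.5)  # 9
#' @export
effective_bed_days <- function(beds_consumed_by_cases,
                               beds_lost_unoccupied = 0,
                               excess_attribution_fraction = 1) {
  if (any(beds_consumed_by_cases < 0) || any(beds_lost_unoccupied < 0)) {
    abort_validation("Bed-day counts must be non-negative.")
  }
  if (any(excess_attribution_fraction < 0 | excess_attribution_fraction > 1)) {
    abort_validation("`excess_attribution_fraction` must lie in [0, 1].")
  }
  beds_consumed_by_cases * excess_attribution_fraction + beds_lost_unoccupied
}

#' One-way sensitivity sweep over a context or group parameter
#'
#' Re-runs [evaluate_all()] at each grid value of one parameter:
#' `"lambda"` (the threshold), `"occupancy_rate"` (the sweep sets
#' `excess_demand = FALSE`, since under excess demand the occupancy term is
#' omitted and the sweep would be inert), or a per-group field written
#' `"<group id>:<field>"`, e.g. `"P2:qaly_gain_per_patient"`.
#'
#' @param cm A [case_mix()].
#' @param context An [economic_context()].
#' @param parameter Parameter name as above.
#' @param grid Non-empty numeric vector of values to evaluate at.
#' @param approach_id Optionally restrict the sweep to one approach id.
#' @return An `oc_sweep` tibble: the [evaluate_all()] rows stacked with a
#'   leading `parameter` / `parameter_value` pair.
#' @examples
#' fx <- worked_example()
#' sensitivity_sweep(fx$case_mix, fx$context, "occupancy_rate",
#'                   c(0.75, 1), approach_id = "1")
#' @export
sensitivity_sweep <- function(cm, context, parameter, grid, approach_id = NULL) {
  if (length(grid) == 0 || anyNA(grid) || !is.numeric(grid)) {
    abort_invalid_context("`grid` must be a non-empty numeric vector.")
  }
  at <- function(value) {
    ctx <- context
    cmx <- cm
    if (parameter == "lambda") {
      if (value <= 0) abort_invalid_context("Threshold grid values must be positive.")
      ctx$threshold <- value
    } else if (parameter == "occupancy_rate") {
      if (value <= 0 || value > 1) {
        abort_invalid_context("Occupancy grid values must lie in (0, 1].")
      }
      ctx$occupancy_rate <- value
      ctx$excess_demand <- FALSE
    } else if (grepl(":", parameter, fixed = TRUE)) {
      part <- strsplit(parameter, ":", fixed = TRUE)[[1]]
      if (length(part) != 2 || !part[1] %in% cmx$options$id ||
          !part[2] %in% names(cmx$options)) {
        abort_invalid_context(sprintf("Unknown sweep parameter '%s'.", parameter))
      }
      cmx$options[[part[2]]][cmx$options$id == part[1]] <- value
      cmx <- case_mix(cmx$options, cmx$chosen)
    } else {
      abort_invalid_context(sprintf("Unknown sweep parameter '%s'.", parameter))
    }
    res <- evaluate_all(cmx, ctx, quiet = TRUE)
    if (!is.null(approach_id)) res <- res[res$approach_id %in% approach_id, ]
    res$parameter <- parameter
    res$parameter_value <- value
    as_tibble(res)[, c("parameter", "parameter_value", "approach_id",
                       "methodology", "unit", "value", "secondary_value")]
  }
  out <- purrr::map_dfr(grid, at)
  structure(out, class = c("oc_sweep", class(out)), parameter = parameter)
}
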