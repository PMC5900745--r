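#' Net monetary and net health benefit
#'
#' The net monetary benefit (NMB) converts a health gain to money at the
#' cost-effectiveness threshold and nets off the expenditure:
#' \deqn{NMB = B \lambda - C.}
#' The net health benefit (NHB) is the same trade-off expressed in QALYs,
#' \eqn{B - C/\lambda}, so that \eqn{NMB = \lambda \cdot NHB} exactly.
#' Both are sign-preserving: options whose expenditure exceeds the monetary
#' value of their health gain come out negative.
#'
#' @param benefit Health benefit in QALYs.
#' @param threshold Cost-effectiveness threshold \eqn{\lambda} (> 0), money
#'   per QALY.
#' @param cost Expenditure, in the same monetary unit as `threshold`.
#' @return Money (NMB) or QALYs (NHB); vectorised over its arguments.
#' @examples
#' net_monetary_benefit(0.6, 20000, 5000) # 7000
#' net_health_benefit(0.6, 20000, 5000)   # 0.35
#' @export
net_monetary_benefit <- function(benefit, threshold, cost) {
  if (!is.numeric(threshold) || any(!is.finite(threshold)) || any(threshold <= 0)) {
    abort_invalid_context("`threshold` (lambda) must be positive.")
  }
  benefit * threshold - cost
}

#' @rdname net_monetary_benefit
#' @export
net_health_benefit <- function(benefit, threshold, cost) {
  net_monetary_benefit(benefit, threshold, cost) / threshold
}

# objective -> required option columns
.oc_objective_fields <- list(
  throughput = "los_per_patient",
  expenditure = "expenditure_per_patient",
  revenue = "revenue_per_patient",
  net_revenue = c("revenue_per_patient", "expenditure_per_patient"),
  health = "qaly_gain_per_patient",
  nmb = c("qaly_gain_per_patient", "expenditure_per_patient")
)

#' Score patient groups under a decision objective
#'
#' Maps each group onto the per-patient scalar a maximising agent compares:
#' `throughput` scores `1 / los_per_patient` (patients treatable per bed-day),
#' `expenditure` scores the expenditure itself (a cost-recovery agent ranks
#' larger spend higher), `revenue` the revenue, `net_revenue` revenue minus
#' expenditure, `health` the QALY gain, and `nmb` the net monetary benefit at
#' the supplied threshold. Larger is always better.
#'
#' @param options A case-mix options data frame (see [case_mix()]).
#' @param objective One of `"throughput"`, `"expenditure"`, `"revenue"`,
#'   `"net_revenue"`, `"health"`, `"nmb"`.
#' @param threshold Cost-effectiveness threshold; required for `"nmb"`.
#' @return The input as a tibble with a `score` column appended.
#' @examples
#' opts <- worked_example()$case_mix$options
#' score_options(opts, "nmb", threshold = 20000)
#' @export
score_options <- function(options, objective, threshold = NULL) {
  objective <- objective[1]
  if (!objective %in% names(.oc_objective_fields)) {
    abort_validation(sprintf("Unknown objective '%s'.", objective))
  }
  options <- as_tibble(options)
  for (col in .oc_objective_fields[[objective]]) {
    if (!col %in% names(options) || anyNA(options[[col]])) {
      oc_abort(
        sprintf("Objective '%s' needs `%s` for every group.", objective, col),
        class = "oppcost_missing_input", field = col
      )
    }
  }
  options$score <- switch(
    objective,
    throughput = 1 / options$los_per_patient,
    expenditure = options$expenditure_per_patient,
    revenue = options$revenue_per_patient,
    net_revenue = options$revenue_per_patient - options$expenditure_per_patient,
    health = options$qaly_gain_per_patient,
    nmb = net_monetary_benefit(options$qaly_gain_per_patient,
                               if (is.null(threshold)) {
                                 abort_invalid_context(
                                   "Objective 'nmb' needs a positive `threshold`.")
                               } else threshold,
                               options$expenditure_per_patient)
  )
  options
}

#' Rank a case mix and identify the second-best alternative
#'
#' Orders the patient groups by descending per-patient score under the
#' context's objective, identifies the best group, and identifies the
#' second-best alternative: the highest-scoring group other than the chosen
#' one — the alternative actually forgone when the chosen option occupies the
#' beds. Ties (scores equal within a relative tolerance of 1e-9) keep input
#' order, set `tie_flag`, and raise a warning.
#'
#' @param cm A [case_mix()].
#' @param context An [economic_context()]; its `objective` and `threshold`
#'   drive the scoring.
#' @return An `oc_ranking`: a tibble with columns `rank`, `id`, `score`,
#'   `chosen`, and attributes `best`, `second_best` (NA when there is no
#'   alternative), `tie_flag`, `objective`.
#' @examples
#' fx <- worked_example()
#' rank_case_mix(fx$case_mix, fx$context)
#' @export
rank_case_mix <- function(cm, context) {
  stopifnot(inherits(cm, "oc_case_mix"), inherits(context, "oc_context"))
  scored <- score_options(cm$options, context$objective, context$threshold)
  ord <- order(-scored$score) # stable: ties keep input position
  ranked <- scored[ord, c("id", "score")]
  ranked$rank <- seq_len(nrow(ranked))
  ranked$chosen <- ranked$id == cm$chosen_id
  ranked <- ranked[, c("rank", "id", "score", "chosen")]
  s <- ranked$score
  tie <- nrow(ranked) > 1 && any(oc_near(s[-1], s[-length(s)]))
  if (tie) {
    warn("Tied scores in case-mix ranking; input order kept.",
         class = "oppcost_tie")
  }
  alt <- ranked$id[!ranked$chosen]
  structure(
    ranked,
    class = c("oc_ranking", class(ranked)),
    best = ranked$id[1],
    second_best = if (length(alt)) alt[1] else NA_character_,
    tie_flag = tie,
    objective = context$objective
  )
}

#' Second-best alternative of a case mix
#'
#' Convenience accessor: the highest-scoring non-chosen group under the
#' context objective, returned as a per-patient field list, or `NULL` when
#' the case mix has no alternative to the chosen option.
#'
#' @inheritParams rank_case_mix
#' @return A list of per-patient fields (`id`, `los_per_patient`, ...) or `NULL`.
#' @export
second_best <- function(cm, context) {
  scored <- score_options(cm$options, context$objective, context$threshold)
  alt <- which(scored$id != cm$chosen_id)
  if (length(alt) == 0) return(NULL)
  as_group(scored[alt[which.max(scored$score[alt])], ])
}
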