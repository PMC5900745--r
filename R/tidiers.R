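# broom-style tidiers for the package's result objects

#' @export
generics::tidy

#' @export
generics::glance

#' Tidy opportunity-cost results
#'
#' @param x An `oc_results` tibble.
#' @param ... Unused.
#' @return A plain tibble of one row per computed approach.
#' @export
tidy.oc_results <- function(x, ...) {
  as_tibble(x)[, c("approach_id", "methodology", "unit", "value",
                   "secondary_value", "description")]
}

#' @rdname tidy.oc_results
#' @return For `glance()`: a one-row summary (chosen id, second-best id,
#'   threshold, numbers of computed and skipped approaches).
#' @export
glance.oc_results <- function(x, ...) {
  ctx <- attr(x, "context")
  tibble(
    chosen_id = attr(x, "chosen_id"),
    second_best = attr(x, "second_best"),
    threshold = ctx$threshold,
    effective_occupancy = effective_occupancy(ctx),
    n_computed = nrow(x),
    n_skipped = length(attr(x, "skipped"))
  )
}

#' Tidy an optimality assessment
#'
#' @param x An `oc_optimality` object.
#' @param ... Unused.
#' @return `tidy()`: the per-option assessment tibble with the option totals;
#'   `glance()`: a one-row tibble with `optimal_id`, `chosen_is_optimal`,
#'   `recommended_methodology`, `true_opportunity_cost` and `tie_flag`.
#' @export
tidy.oc_optimality <- function(x, ...) {
  x$assessments
}

#' @rdname tidy.oc_optimality
#' @export
glance.oc_optimality <- function(x, ...) {
  tibble(
    optimal_id = x$optimal_id,
    chosen_id = x$chosen_id,
    chosen_is_optimal = x$chosen_is_optimal,
    recommended_methodology = x$recommended_methodology,
    true_opportunity_cost = x$true_opportunity_cost,
    tie_flag = x$tie_flag
  )
}

#' Tidy a case-mix ranking
#'
#' @param x An `oc_ranking`.
#' @param ... Unused.
#' @return `tidy()`: the ranking as a plain tibble; `glance()`: one row with
#'   `best`, `second_best`, `tie_flag` and the objective used.
#' @export
tidy.oc_ranking <- function(x, ...) {
  as_tibble(x)
}

#' @rdname tidy.oc_ranking
#' @export
glance.oc_ranking <- function(x, ...) {
  tibble(
    best = attr(x, "best"),
    second_best = attr(x, "second_best"),
    tie_flag = attr(x, "tie_flag"),
    objective = attr(x, "objective")
  )
}
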