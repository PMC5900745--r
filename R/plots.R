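# ggplot2 methods for the result objects

#' @export
ggplot2::autoplot

#' Plot opportunity-cost valuations
#'
#' Bar chart of the value each approach assigns to the same bed-day
#' consumption, faceted by unit (money, QALYs, equivalents) so that only
#' commensurable values share an axis.
#'
#' @param object An `oc_results` tibble from [evaluate_all()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oc_results <- function(object, ...) {
  df <- tidy(object)
  df$approach_id <- factor(df$approach_id, levels = df$approach_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$approach_id, y = .data$value,
                                   fill = .data$methodology)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~unit, scales = "free") +
    ggplot2::labs(
      x = "approach", y = "opportunity-cost value",
      fill = "methodology",
      title = sprintf("Opportunity cost of the bed-days of %s",
                      attr(object, "chosen_id"))
    )
}

#' Plot an optimality assessment
#'
#' Per-option total expenditure, gross benefit and net monetary benefit for
#' the same bed-day consumption, with the chosen option highlighted.
#'
#' @param object An `oc_optimality` from [assess_optimality()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oc_optimality <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$assessments,
    c("expenditure_total", "gross_benefit_total", "nmb_total"),
    names_to = "component", values_to = "amount"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$amount,
                                   fill = .data$component,
                                   alpha = .data$chosen)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.55),
                                guide = "none") +
    ggplot2::labs(x = "patient group", y = "total over displaced equivalents",
                  fill = NULL,
                  title = sprintf("Optimality of %s (methodology %s)",
                                  object$chosen_id, object$recommended_methodology))
}

#' Plot a sensitivity sweep
#'
#' Value of each swept approach against the parameter grid.
#'
#' @param object An `oc_sweep` from [sensitivity_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oc_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$parameter_value,
                                       y = .data$value,
                                       colour = .data$approach_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~unit, scales = "free_y") +
    ggplot2::labs(x = attr(object, "parameter"), y = "opportunity-cost value",
                  colour = "approach")
}
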