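#' Economic context for opportunity-cost valuation
#'
#' Bundles the decision-maker's economic environment: the cost-effectiveness
#' threshold that converts health gains to money, the bed occupancy rate, and
#' whether the setting faces excess demand for beds.
#'
#' The threshold `lambda` (money per QALY) is the monetary value the local
#' decision maker attaches to one quality-adjusted life year; it has no
#' default and must always be supplied. The occupancy rate is the fraction of
#' freed bed capacity that is actually redeployed to alternative patients.
#' Under excess demand (patients awaiting admission, the default) every freed
#' bed is refilled, so the occupancy adjustment is omitted and the effective
#' occupancy factor is 1 regardless of `occupancy_rate`.
#'
#' @param threshold Cost-effectiveness threshold \eqn{\lambda}, money per QALY;
#'   must be strictly positive.
#' @param occupancy_rate Fraction in (0, 1] of freed bed-days redeployed.
#'   Only applied when `excess_demand = FALSE`.
#' @param excess_demand Logical; is there unmet demand for beds? Default
#'   `TRUE`, in which case the occupancy adjustment is dropped.
#' @param objective The maximand used to rank a case mix: one of
#'   `"nmb"` (net monetary benefit), `"health"`, `"net_revenue"`, `"revenue"`,
#'   `"expenditure"`, `"throughput"`.
#' @param perspective Informational label: `"provider"`, `"payer"` or
#'   `"societal"`. It does not change any computation; it documents what the
#'   expenditure fields encode (e.g. reimbursement payments under a payer
#'   perspective).
#' @param currency Currency label used only when rendering reports.
#'
#' @return An object of class `oc_context`.
#' @examples
#' economic_context(threshold = 20000)
#' @export
economic_context <- function(threshold,
                             occupancy_rate = 1,
                             excess_demand = TRUE,
                             objective = c("nmb", "health", "net_revenue",
                                           "revenue", "expenditure", "throughput"),
                             perspective = c("provider", "payer", "societal"),
                             currency = "£") {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold <= 0) {
    abort_invalid_context("`threshold` (lambda) must be a single positive number.")
  }
  if (!is.numeric(occupancy_rate) || length(occupancy_rate) != 1 ||
      is.na(occupancy_rate) || occupancy_rate <= 0 || occupancy_rate > 1) {
    abort_invalid_context("`occupancy_rate` must lie in (0, 1].")
  }
  objective <- rlang::arg_match(objective)
  perspective <- rlang::arg_match(perspective)
  structure(
    list(
      threshold = as.numeric(threshold),
      occupancy_rate = as.numeric(occupancy_rate),
      excess_demand = isTRUE(excess_demand),
      objective = objective,
      perspective = perspective,
      currency = currency
    ),
    class = "oc_context"
  )
}

#' Effective occupancy factor
#'
#' The multiplicative factor applied to forgone patient-equivalent flows:
#' the occupancy rate when there is spare capacity, and exactly 1 under excess
#' demand, where every freed bed is refilled and the adjustment is omitted.
#'
#' @param context An [economic_context()].
#' @return A number in (0, 1].
#' @export
effective_occupancy <- function(context) {
  stopifnot(inherits(context, "oc_context"))
  if (context$excess_demand) 1 else context$occupancy_rate
}

#' @export
print.oc_context <- function(x, ...) {
  cat("<economic context>\n")
  cat(sprintf("  threshold:      %s%s per QALY\n", x$currency,
              format(x$threshold, big.mark = ",")))
  cat(sprintf("  occupancy rate: %s%s\n", format(x$occupancy_rate),
              if (x$excess_demand) " (omitted: excess demand)" else ""))
  cat(sprintf("  objective:      %s\n", x$objective))
  cat(sprintf("  perspective:    %s\n", x$perspective))
  invisible(x)
}
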