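#' The built-in three-patient worked example
#'
#' A hypothetical ward-level case mix of three patient groups competing for
#' the same beds, with a cost-effectiveness threshold of 20,000 per QALY and
#' full occupancy under excess demand. The chosen consumption being valued is
#' the 10 bed-days of patient P1 (expenditure 7,000 of which 3,500 variable,
#' revenue 9,000, QALY gain 1.3); P2 (5 bed-days, 5,000, 6,000, 0.6) is the
#' second-best alternative and P3 (5 bed-days, 5,000, 5,500, 0.4) the
#' third-best. All values are illustrative.
#'
#' @return A list with elements `case_mix` ([case_mix()]) and `context`
#'   ([economic_context()]).
#' @examples
#' fx <- worked_example()
#' evaluate_all(fx$case_mix, fx$context)
#' @export
worked_example <- function() {
  options <- tibble(
    id = c("P1", "P2", "P3"),
    los_per_patient = c(10, 5, 5),
    expenditure_per_patient = c(7000, 5000, 5000),
    variable_cost_per_patient = c(3500, NA, NA),
    revenue_per_patient = c(9000, 6000, 5500),
    qaly_gain_per_patient = c(1.3, 0.6, 0.4)
  )
  list(
    case_mix = case_mix(options, chosen = "P1"),
    context = economic_context(threshold = 20000, occupancy_rate = 1,
                               excess_demand = TRUE, objective = "nmb")
  )
}

#' Generate a synthetic case mix
#'
#' Draws a reproducible random case mix for property testing and simulation.
#' Lengths of stay are log-normal around a 5-bed-day median (a realistic
#' acute-ward stay); expenditure is length of stay times a per-day cost drawn
#' from `cost_per_day`; revenue is expenditure marked up by a fraction drawn
#' from `revenue_markup` (negative margins allowed); QALY gains are uniform
#' on `qaly_range` (marginal gains from treatment: non-negative by default,
#' set the lower bound negative only for stress tests). The chosen option is
#' the NMB-optimal group most of the time, and a uniformly random group with
#' probability `p_random_chosen`, so that a realistic minority of generated
#' mixes have a suboptimal chosen option and exercise the Methodology D path.
#'
#' @param seed Integer seed; identical arguments and seed give an identical
#'   case mix. The caller's RNG state is left untouched.
#' @param n_groups Number of patient groups (>= 1).
#' @param los_meanlog,los_sdlog Log-normal parameters of length of stay
#'   (defaults: median 5 bed-days, sdlog 0.5).
#' @param cost_per_day Range (min, max) of per-day expenditure.
#' @param qaly_range Range of per-patient QALY gains, within \[-2, 2\].
#' @param revenue_markup Range of the revenue markup over expenditure.
#' @param threshold Cost-effectiveness threshold of the generated context.
#' @param p_random_chosen Probability that the chosen option is drawn
#'   uniformly rather than NMB-optimally.
#' @return A list with `case_mix` and `context`, as [worked_example()].
#' @examples
#' generate_case_mix(seed = 42, n_groups = 4)
#' @export
generate_case_mix <- function(seed,
                              n_groups = 3,
                              los_meanlog = log(5),
                              los_sdlog = 0.5,
                              cost_per_day = c(500, 1500),
                              qaly_range = c(0, 1.5),
                              revenue_markup = c(-0.1, 0.3),
                              threshold = 20000,
                              p_random_chosen = 0.2) {
  if (n_groups < 1) abort_validation("`n_groups` must be at least 1.")
  for (rng in list(cost_per_day = cost_per_day, qaly_range = qaly_range,
                   revenue_markup = revenue_markup)) {
    if (length(rng) != 2 || anyNA(rng) || rng[2] < rng[1]) {
      abort_validation("Ranges must be finite length-2 vectors with min <= max.")
    }
  }
  if (qaly_range[1] < -2 || qaly_range[2] > 2) {
    abort_validation("`qaly_range` must lie within [-2, 2].")
  }
  if (cost_per_day[1] < 0) abort_validation("`cost_per_day` must be non-negative.")
  # restore the caller's RNG state on exit (cheaper than withr::with_seed in
  # tight property-test loops, same contract)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
  on.exit(
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    },
    add = TRUE
  )
  set.seed(seed)
  {
    los <- stats::rlnorm(n_groups, los_meanlog, los_sdlog)
    cost <- los * stats::runif(n_groups, cost_per_day[1], cost_per_day[2])
    revenue <- pmax(0, cost * (1 + stats::runif(n_groups, revenue_markup[1],
                                                revenue_markup[2])))
    qaly <- stats::runif(n_groups, qaly_range[1], qaly_range[2])
    variable <- cost * stats::runif(n_groups, 0.3, 0.7)
    nmb <- qaly * threshold - cost
    chosen_k <- if (stats::runif(1) < p_random_chosen) {
      sample.int(n_groups, 1)
    } else {
      which.max(nmb)
    }
    options <- tibble::new_tibble(
      list(
        id = paste0("G", seq_len(n_groups)),
        los_per_patient = los,
        expenditure_per_patient = cost,
        variable_cost_per_patient = variable,
        revenue_per_patient = revenue,
        qaly_gain_per_patient = qaly
      ),
      nrow = n_groups
    )
    list(
      case_mix = case_mix(options, chosen = options$id[chosen_k]),
      context = economic_context(threshold = threshold, objective = "nmb")
    )
  }
}
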