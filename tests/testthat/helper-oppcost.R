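# Shared fixtures and independent one-line arithmetic oracles.
#
# The oracles re-state each estimator formula directly on scalars; property
# tests compare the package's object-based implementations against them.

wex <- function() worked_example()

# a context with spare capacity (the occupancy factor applies)
slack_context <- function(ocr, threshold = 20000) {
  economic_context(threshold = threshold, occupancy_rate = ocr,
                   excess_demand = FALSE)
}

oracle <- list(
  a1 = function(los_i, los_j, E) los_i / los_j * E,
  a2 = function(c_i, c_j) c_i / c_j,
  a3a = function(los_i, c_j, los_j) los_i * c_j / los_j,
  a3b = function(los_i, r_j, los_j, E) los_i * (r_j / los_j) * E,
  a3c = function(los_i, r_j, c_j, los_j) los_i * (r_j - c_j) / los_j,
  a4 = function(los_i, b_j, los_j) los_i * b_j / los_j,
  a5 = function(los_i, b_j, lambda, los_j) los_i * b_j * lambda / los_j,
  a6 = function(c_i, lambda) c_i / lambda,
  new1 = function(los_i, b_j, lambda, c_j, los_j, E) {
    los_i * (b_j * lambda - c_j) / los_j * E
  },
  new2 = function(c_i, b_j, lambda, c_j) c_i * (b_j * lambda - c_j) / c_j,
  a9 = function(c_i, los_i, r_j, c_j, los_j) c_i + los_i * (r_j - c_j) / los_j,
  # the forgone term of New5 is New1, so it carries the occupancy factor
  new5 = function(c_i, los_i, b_j, lambda, c_j, los_j, E) {
    c_i + los_i * (b_j * lambda - c_j) / los_j * E
  }
)

# per-patient fields of a group id in a case mix
group_of <- function(cm, id) {
  cm$options[cm$options$id == id, ]
}

# all fourteen single-value estimators on a chosen/second-best pair,
# returned as a named vector (approach 8 contributes its variable-cost part)
all_approach_values <- function(chosen, sb, context, bf_nr = sb, bf_nmb = sb) {
  suppressWarnings(c(
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
  ))
}
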