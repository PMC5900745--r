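# The fourteen estimators on the worked example and on derived cases.

fx <- worked_example()
chosen <- resolve_chosen(fx$case_mix)
sb <- second_best(fx$case_mix, fx$context)
ctx <- fx$context

test_that("unit-based approaches reproduce the worked example and scale as defined", {
  expect_equal(patient_equivalents(chosen, sb, ctx), 2)
  expect_equal(treatment_equivalents(chosen, sb), 1.4)

  # zero consumption forgoes nothing
  zero <- chosen_option("z", los_total = 0, expenditure_total = 0)
  expect_equal(patient_equivalents(zero, sb, ctx), 0)
  expect_equal(treatment_equivalents(zero, sb), 0)

  # spare capacity: only a fraction of freed beds is redeployed
  expect_equal(patient_equivalents(chosen, sb, slack_context(0.75)), 1.5)

  big <- chosen_option("b", los_total = 10, expenditure_total = 9000)
  cheap_alt <- list(id = "j", los_per_patient = 5, expenditure_per_patient = 4500)
  expect_equal(treatment_equivalents(big, cheap_alt), 2)

  free_alt <- list(id = "j", los_per_patient = 5, expenditure_per_patient = 0)
  expect_error(treatment_equivalents(chosen, free_alt),
               class = "oppcost_degenerate_denominator")
})

test_that("patient-equivalents stay fractional, with flooring only for presentation", {
  pe <- patient_equivalents(chosen, list(id = "j", los_per_patient = 4,
                                         expenditure_per_patient = 1), ctx)
  expect_equal(pe, 2.5)
  fl <- floor_patient_equivalents(pe)
  expect_equal(fl$whole_patients, 2)
  expect_equal(fl$remainder, 0.5)
})

test_that("monetary valuations of the displaced patient-equivalents match the example", {
  expect_equal(monetary_forgone(chosen, sb, ctx, "expenditure"), 10000)
  expect_equal(monetary_forgone(chosen, sb, ctx, "revenue"), 12000)
  expect_equal(monetary_forgone(chosen, sb, ctx, "net_revenue"), 2000)
  # occupancy attaches to the revenue flow
  expect_equal(monetary_forgone(chosen, sb, slack_context(0.75), "revenue"), 9000)

  no_rev <- list(id = "j", los_per_patient = 5, expenditure_per_patient = 5000)
  expect_error(monetary_forgone(chosen, no_rev, ctx, "revenue"),
               class = "oppcost_missing_input")
  expect_error(monetary_forgone(chosen, no_rev, ctx, "net_revenue"),
               class = "oppcost_missing_input")
  expect_equal(monetary_forgone(chosen, no_rev, ctx, "expenditure"), 10000)
})

test_that("gross health and gross monetary benefit forgone match and bridge via the threshold", {
  expect_equal(health_forgone_gross(chosen, sb), 1.2)
  expect_equal(monetary_benefit_forgone_gross(chosen, sb, ctx), 24000)

  no_q <- list(id = "j", los_per_patient = 5, expenditure_per_patient = 5000,
               qaly_gain_per_patient = 0)
  expect_equal(health_forgone_gross(chosen, no_q), 0)
  long <- chosen_option("l", los_total = 20, expenditure_total = 1)
  expect_equal(health_forgone_gross(long, sb), 2.4)

  ctx50 <- economic_context(50000)
  expect_equal(monetary_benefit_forgone_gross(chosen, sb, ctx50), 60000)
  expect_equal(monetary_benefit_forgone_gross(chosen, sb, ctx),
               ctx$threshold * health_forgone_gross(chosen, sb))
})

test_that("the threshold conversion turns expenditure into QALYs displaced elsewhere", {
  expect_equal(threshold_conversion(chosen, ctx), 0.35)
  expect_equal(threshold_conversion(chosen_option("z", 1, 0), ctx), 0)
  expect_equal(threshold_conversion(chosen_option("b", 1, 30000), ctx), 1.5)
})

test_that("chosen-expenditure approaches use no alternative at all", {
  expect_equal(expenditure_incurred(chosen), 7000)
  expect_equal(expenditure_incurred(chosen_option("z", 1, 0)), 0)

  split <- variable_cost_split(chosen)
  expect_equal(split$variable_cost, 3500)
  expect_equal(split$bed_days, 10)
  all_var <- chosen_option("v", 10, 7000, variable_cost_total = 7000)
  expect_equal(variable_cost_split(all_var)$variable_cost, 7000)
  all_fixed <- chosen_option("f", 10, 7000, variable_cost_total = 0)
  expect_equal(variable_cost_split(all_fixed)$variable_cost, 0)
  no_vc <- chosen_option("n", 10, 7000)
  expect_error(variable_cost_split(no_vc), class = "oppcost_missing_input")
})

test_that("net-benefit valuations match the example on both bases", {
  expect_equal(nmb_forgone(chosen, sb, ctx, "patient_equiv"), 14000)
  expect_equal(nmb_forgone(chosen, sb, ctx, "treatment_equiv"), 9800)
  expect_equal(nhb_forgone(chosen, sb, ctx, "patient_equiv"), 0.7)
  expect_equal(nhb_forgone(chosen, sb, ctx, "treatment_equiv"), 0.49)

  # equilibrium degeneracy: benefits equal expenditure, nothing is forgone net
  eq <- list(id = "e", los_per_patient = 5, expenditure_per_patient = 5000,
             qaly_gain_per_patient = 5000 / 20000)
  expect_equal(nmb_forgone(chosen, eq, ctx, "patient_equiv"), 0)
  expect_equal(nmb_forgone(chosen, eq, ctx, "treatment_equiv"), 0)

  # occupancy attaches to the patient-equivalent basis only
  expect_equal(nmb_forgone(chosen, sb, slack_context(0.75), "patient_equiv"), 10500)
  expect_equal(nmb_forgone(chosen, sb, slack_context(0.75), "treatment_equiv"), 9800)
})

test_that("a negative forgone net benefit is returned unclamped, with a warning", {
  bad <- list(id = "b", los_per_patient = 5, expenditure_per_patient = 5000,
              qaly_gain_per_patient = 0.1)
  expect_warning(v <- nmb_forgone(chosen, bad, ctx, "patient_equiv"),
                 class = "oppcost_negative_nmb")
  expect_equal(v, 10 * (0.1 * 20000 - 5000) / 5)
})

test_that("economic cost adds the chosen expenditure to the highest net benefit forgone", {
  expect_equal(economic_cost(chosen, sb, ctx, "net_revenue"), 9000)
  expect_equal(economic_cost(chosen, sb, ctx, "nmb"), 21000)
  # zero forgone net value collapses Methodology D onto C
  eq <- list(id = "e", los_per_patient = 5, expenditure_per_patient = 5000,
             revenue_per_patient = 5000, qaly_gain_per_patient = 0.25)
  expect_equal(economic_cost(chosen, eq, ctx, "net_revenue"),
               expenditure_incurred(chosen))
  expect_equal(economic_cost(chosen, eq, ctx, "nmb"),
               expenditure_incurred(chosen))
})

test_that("the catalog has the sixteen rows, consistently lettered and ordered", {
  cat <- approach_catalog()
  expect_equal(nrow(cat), 16)
  expect_equal(cat$approach_id,
               c("1", "2", "3a", "3b", "3c", "5", "New1", "New2",
                 "4", "6", "New3", "New4", "7", "8", "9", "New5"))
  expect_equal(cat$methodology[cat$approach_id %in% c("1", "2")], c("A", "A"))
  expect_equal(unique(cat$methodology[cat$approach_id %in%
                 c("3a", "3b", "3c", "4", "5", "6", "New1", "New2", "New3", "New4")]), "B")
  expect_equal(cat$methodology[cat$approach_id %in% c("7", "8")], c("C", "C"))
  expect_equal(cat$methodology[cat$approach_id %in% c("9", "New5")], c("D", "D"))
})

test_that("evaluate_all reproduces the full results column in catalog order", {
  res <- evaluate_all(fx$case_mix, ctx, quiet = TRUE)
  expect_s3_class(res, "oc_results")
  expect_equal(res$approach_id, approach_catalog()$approach_id)
  expect_equal(res$value,
               c(2, 1.4, 10000, 12000, 2000, 24000, 14000, 9800,
                 1.2, 0.35, 0.7, 0.49, 7000, 3500, 9000, 21000))
  expect_equal(res$secondary_value[res$approach_id == "8"], 10)
  expect_equal(attr(res, "second_best"), "P2")
  expect_equal(length(attr(res, "skipped")), 0)
})

test_that("evaluate_all skips what it cannot compute and keeps the rest", {
  opts <- fx$case_mix$options
  opts$qaly_gain_per_patient <- NULL
  cm <- case_mix(opts, "P1")
  ctx_nr <- ctx; ctx_nr$objective <- "net_revenue"
  expect_message(res <- evaluate_all(cm, ctx_nr), "Skipping")
  expect_false(any(c("4", "5", "New1", "New2", "New3", "New4", "New5") %in%
                     res$approach_id))
  expect_true(all(c("1", "2", "3a", "3b", "3c", "6", "7", "8", "9") %in%
                    res$approach_id))
  expect_setequal(attr(res, "skipped"),
                  c("4", "5", "New1", "New2", "New3", "New4", "New5"))
})

test_that("a single-group case mix yields only the chosen-expenditure approaches", {
  cm1 <- case_mix(fx$case_mix$options[1, ], "P1")
  res <- evaluate_all(cm1, ctx, quiet = TRUE)
  expect_equal(res$approach_id, c("7", "8"))
  expect_equal(unique(res$methodology), "C")
})

test_that("strict single-approach evaluation errors instead of skipping", {
  expect_equal(evaluate_approach(fx$case_mix, ctx, "6")$value, 0.35)
  expect_error(evaluate_approach(fx$case_mix, ctx, "banana"),
               class = "oppcost_validation_error")
  cm1 <- case_mix(fx$case_mix$options[1, ], "P1")
  expect_error(evaluate_approach(cm1, ctx, "1"),
               class = "oppcost_missing_alternative")
  opts <- fx$case_mix$options
  opts$variable_cost_per_patient <- NULL
  expect_error(evaluate_approach(case_mix(opts, "P1"), ctx, "8"),
               class = "oppcost_missing_input")
})

test_that("every estimator agrees with the one-line arithmetic oracle on random inputs", {
  set.seed(202)
  for (k in 1:200) {
    los_i <- runif(1, 0.5, 30); c_i <- runif(1, 100, 30000)
    vc_i <- c_i * runif(1)
    los_j <- runif(1, 0.5, 20); c_j <- runif(1, 100, 20000)
    r_j <- runif(1, 0, 25000); b_j <- runif(1, 0, 2)
    lambda <- runif(1, 5000, 80000); ocr <- runif(1, 0.5, 1)
    excess <- k %% 2 == 0
    E <- if (excess) 1 else ocr
    ch <- chosen_option("i", los_i, c_i, variable_cost_total = vc_i)
    g <- list(id = "j", los_per_patient = los_j, expenditure_per_patient = c_j,
              revenue_per_patient = r_j, qaly_gain_per_patient = b_j)
    cx <- economic_context(lambda, occupancy_rate = ocr, excess_demand = excess)
    v <- all_approach_values(ch, g, cx)
    expect_equal(v[["1"]], oracle$a1(los_i, los_j, E))
    expect_equal(v[["2"]], oracle$a2(c_i, c_j))
    expect_equal(v[["3a"]], oracle$a3a(los_i, c_j, los_j))
    expect_equal(v[["3b"]], oracle$a3b(los_i, r_j, los_j, E))
    expect_equal(v[["3c"]], oracle$a3c(los_i, r_j, c_j, los_j))
    expect_equal(v[["4"]], oracle$a4(los_i, b_j, los_j))
    expect_equal(v[["5"]], oracle$a5(los_i, b_j, lambda, los_j))
    expect_equal(v[["6"]], oracle$a6(c_i, lambda))
    expect_equal(v[["7"]], c_i)
    expect_equal(v[["8"]], vc_i)
    expect_equal(v[["9"]], oracle$a9(c_i, los_i, r_j, c_j, los_j))
    expect_equal(v[["New1"]], oracle$new1(los_i, b_j, lambda, c_j, los_j, E))
    expect_equal(v[["New2"]], oracle$new2(c_i, b_j, lambda, c_j))
    expect_equal(v[["New3"]], oracle$new1(los_i, b_j, lambda, c_j, los_j, E) / lambda)
    expect_equal(v[["New4"]], oracle$new2(c_i, b_j, lambda, c_j) / lambda)
    expect_equal(v[["New5"]], oracle$new5(c_i, los_i, b_j, lambda, c_j, los_j, E))
  }
})
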