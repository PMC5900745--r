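# Algebraic identities the taxonomy guarantees, on seeded random case mixes.

test_that("decomposition, threshold bridges and degeneracies hold on random mixes", {
  for (seed in 1:200) {
    gen <- generate_case_mix(seed = seed, n_groups = 2 + seed %% 4)
    ctx <- gen$context
    chosen <- resolve_chosen(gen$case_mix)
    sb <- second_best(gen$case_mix, gen$context)
    v <- all_approach_values(chosen, sb, ctx)

    # Methodology D = C + B, exactly
    expect_equal(v[["9"]], v[["7"]] + v[["3c"]])
    expect_equal(v[["New5"]], v[["7"]] + v[["New1"]])
    # threshold bridges between monetary and health units
    expect_equal(v[["New1"]], ctx$threshold * v[["New3"]])
    expect_equal(v[["New2"]], ctx$threshold * v[["New4"]])
    expect_equal(v[["5"]], ctx$threshold * v[["4"]])
    # gross minus displaced expenditure is the net benefit forgone (full occupancy)
    expect_equal(v[["5"]] - v[["3a"]], v[["New1"]])
    # net value per displaced unit times the unit count
    net_j <- sb$qaly_gain_per_patient * ctx$threshold - sb$expenditure_per_patient
    expect_equal(v[["New1"]], v[["1"]] * net_j)
    expect_equal(v[["New2"]], v[["2"]] * net_j)
  }
})

test_that("perfect competition removes every net-benefit term", {
  for (seed in 1:50) {
    gen <- generate_case_mix(seed = seed, n_groups = 3)
    ctx <- gen$context
    chosen <- resolve_chosen(gen$case_mix)
    sb <- second_best(gen$case_mix, gen$context)
    # revenue at cost: approach 9 collapses onto approach 7
    sb_eq <- sb
    sb_eq$revenue_per_patient <- sb_eq$expenditure_per_patient
    expect_equal(economic_cost(chosen, sb_eq, ctx, "net_revenue"),
                 expenditure_incurred(chosen))
    # health benefit worth exactly its expenditure: all net approaches vanish
    sb_eq$qaly_gain_per_patient <- sb_eq$expenditure_per_patient / ctx$threshold
    expect_equal(nmb_forgone(chosen, sb_eq, ctx, "patient_equiv"), 0)
    expect_equal(nmb_forgone(chosen, sb_eq, ctx, "treatment_equiv"), 0)
    expect_equal(nhb_forgone(chosen, sb_eq, ctx, "patient_equiv"), 0)
    expect_equal(nhb_forgone(chosen, sb_eq, ctx, "treatment_equiv"), 0)
    expect_equal(economic_cost(chosen, sb_eq, ctx, "nmb"),
                 expenditure_incurred(chosen))
  }
})

test_that("every approach except the chosen-expenditure pair is linear in consumption", {
  gen <- generate_case_mix(seed = 31, n_groups = 3)
  ctx <- gen$context
  chosen <- resolve_chosen(gen$case_mix)
  sb <- second_best(gen$case_mix, gen$context)
  for (s in c(0.5, 2, 3.7)) {
    scaled_los <- chosen_option(chosen$id, chosen$los_total * s,
                                chosen$expenditure_total,
                                variable_cost_total = chosen$variable_cost_total)
    scaled_all <- chosen_option(chosen$id, chosen$los_total * s,
                                chosen$expenditure_total * s,
                                variable_cost_total = chosen$variable_cost_total)
    # bed-day based approaches scale with LOS_i
    for (f in list(function(ch) patient_equivalents(ch, sb, ctx),
                   function(ch) monetary_forgone(ch, sb, ctx, "expenditure"),
                   function(ch) monetary_forgone(ch, sb, ctx, "revenue"),
                   function(ch) monetary_forgone(ch, sb, ctx, "net_revenue"),
                   function(ch) health_forgone_gross(ch, sb),
                   function(ch) monetary_benefit_forgone_gross(ch, sb, ctx),
                   function(ch) suppressWarnings(nmb_forgone(ch, sb, ctx, "patient_equiv")),
                   function(ch) suppressWarnings(nhb_forgone(ch, sb, ctx, "patient_equiv")))) {
      expect_equal(f(scaled_los), s * f(chosen))
    }
    # expenditure-based approaches scale with C_i
    for (f in list(function(ch) treatment_equivalents(ch, sb),
                   function(ch) threshold_conversion(ch, ctx),
                   function(ch) suppressWarnings(nmb_forgone(ch, sb, ctx, "treatment_equiv")),
                   function(ch) suppressWarnings(nhb_forgone(ch, sb, ctx, "treatment_equiv")))) {
      expect_equal(f(scaled_all), s * f(chosen))
    }
    # the chosen-expenditure pair does not scale with bed-days
    expect_equal(expenditure_incurred(scaled_los), expenditure_incurred(chosen))
    expect_equal(variable_cost_split(scaled_los)$variable_cost,
                 variable_cost_split(chosen)$variable_cost)
  }
})

test_that("the occupancy factor multiplies exactly the patient-equivalent flows", {
  gen <- generate_case_mix(seed = 77, n_groups = 3)
  chosen <- resolve_chosen(gen$case_mix)
  sb <- second_best(gen$case_mix, gen$context)
  full <- gen$context
  ocr <- 0.8
  part <- slack_context(ocr, threshold = full$threshold)
  v_full <- all_approach_values(chosen, sb, full)
  v_part <- all_approach_values(chosen, sb, part)
  scaled <- c("1", "3b", "New1", "New3")
  expect_equal(v_part[scaled], ocr * v_full[scaled])
  # New5 inherits the scaling of its New1 term only
  expect_equal(v_part[["New5"]], v_full[["7"]] + ocr * v_full[["New1"]])
  unscaled <- setdiff(names(v_full), c(scaled, "New5"))
  expect_equal(v_part[unscaled], v_full[unscaled])
  expect_lte(effective_occupancy(part), 1)
})

test_that("the inequality and arg-max characterisations of optimality agree", {
  for (seed in 1:200) {
    gen <- generate_case_mix(seed = seed, n_groups = 2 + seed %% 4)
    a <- suppressWarnings(assess_optimality(gen$case_mix, gen$context))
    s <- a$assessments
    k <- which(s$chosen)
    # (i) chosen expenditure + highest NMB forgone < chosen gross benefit
    ineq <- s$expenditure_plus_highest_forgone_nmb[k] < s$gross_benefit_total[k]
    # (ii) the chosen option maximises total NMB
    argmax <- s$nmb_total[k] >= max(s$nmb_total[-k])
    expect_equal(ineq, argmax)
    expect_equal(a$chosen_is_optimal, argmax)
    expect_equal(a$recommended_methodology, if (argmax) "B" else "D")
  }
})
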