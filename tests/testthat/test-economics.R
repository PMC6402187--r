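test_that("phase II program costs reproduce the reference and scaled values", {
  expect_equal(phase2_program_cost(scn1, cm_default), 4000)
  # proportional costing with 2-dp quantiles gives the printed headline
  expect_equal(phase2_program_cost(scn2, cm_prop), 4000 * (2.8 / 1.96)^2)
  expect_equal(round(phase2_program_cost(scn2, cm_prop)), 8163)
  # economies factor < 1 strictly cheaper whenever the ratio exceeds 1
  expect_lt(phase2_program_cost(scn2, cm_default),
            phase2_program_cost(scn2, cm_prop))
  # empty portfolio
  empty <- scenario("none", stage_design(0.05, 0.8), n_candidates = 1e-12)
  expect_equal(phase2_program_cost(empty, cm_default), 0, tolerance = 1e-6)
})

test_that("phase III cost is entrants times the per-treatment cost", {
  expect_equal(phase3_program_cost(run_flow(scn1), cm_default), 16.25 * 163)
  expect_equal(phase3_program_cost(run_flow(scn4[["Scenario 3"]]),
                                   cm_default), 13.25 * 163)
})

test_that("expected returns use exact unrounded passers", {
  expect_equal(expected_return(run_flow(scn2), cm_default),
               2500 * 16.209375)             # prints as $40,523M
  expect_equal(expected_return(run_flow(scn4[["Scenario 4"]]), cm_default),
               2500 * 19.275)                # prints as $48,188M
  expect_equal(expected_return(run_flow(scn4[["Scenario 3"]]), cm_default),
               2500 * 10.126875)             # prints as $25,317M
})

test_that("profit assembles return minus costs and respects its invariants", {
  ec <- profit(scn2, cm_default)
  expect_equal(ec$total_cost, ec$cost_phase2 + ec$cost_phase3,
               tolerance = 1e-6)
  expect_equal(ec$profit, ec$expected_return - ec$total_cost,
               tolerance = 1e-6)
  # zero passers: pure loss
  dead <- scenario("dead", stage_design(1e-9, 1e-9),
                   phase3 = stage_design(1e-9, 1e-9, n_trials = 2))
  ecd <- profit(dead, cm_default)
  expect_equal(ecd$profit, -(ecd$cost_phase2 + ecd$cost_phase3),
               tolerance = 1e-6)

  # monotone in the monetary knobs
  p_base <- profit(scn2, cm_default)$profit
  expect_lt(profit(scn2, cost_model(cost_per_participant = 3e5))$profit,
            p_base)
  expect_gt(profit(scn2, cost_model(return_per_success = 3000))$profit,
            p_base)
})

test_that("adjusted analyses halve phase II cost at multiplier sqrt(2)", {
  cm_adj <- cost_model(economies_factor = 1,
                       phase2_effect_multiplier = sqrt(2))
  expect_equal(phase2_program_cost(scn2, cm_adj),
               phase2_program_cost(scn2, cm_prop) / 2, tolerance = 1e-9)
  expect_equal(phase2_program_cost(scn1, cm_adj), 4000 / 2)
})

test_that("return depends only on the total number of phase III passers", {
  fl <- run_flow(scn2)
  tweaked <- fl
  shift <- 0.004
  tweaked$pass[tweaked$class == "effective" & tweaked$stage == "III"] <-
    flow_cell(fl, "effective", "III", "pass") - shift
  tweaked$pass[tweaked$class == "ineffective" & tweaked$stage == "III"] <-
    flow_cell(fl, "ineffective", "III", "pass") + shift
  expect_equal(expected_return(tweaked, cm_default),
               expected_return(fl, cm_default))
})

test_that("scenario comparison reports percent deltas and flags zero baselines", {
  e1 <- profit(scn1, cm_default)
  e2 <- profit(scn2, cm_default)
  self <- compare_scenarios(e1, e1)
  expect_true(all(unlist(self) == 0))

  cmp <- compare_scenarios(profit(scn2, cm_prop), profit(scn1, cm_prop),
                           mode = "printed")
  expect_equal(round(cmp$cost_phase2_pct_change, 1), 104.1)
  expect_equal(round(cmp$productivity_pct_change, 1), 60.4)
  expect_equal(round(cmp$cost_phase3_pct_change, 1),
               round(100 * (23.75 - 16.25) / 16.25, 1))  # 46.2

  # zero-profit baseline flagged as undefined, not an error
  broke <- cost_model(return_per_success = 1e-9)
  e0 <- profit(scenario("z", stage_design(1e-9, 1e-9)), broke)
  e0$profit <- 0
  expect_true(is.na(compare_scenarios(e2, e0)$profit_pct_change))

  mixed <- profit(scenario("m", stage_design(0.05, 0.8), p_eff = 0.1),
                  cm_default)
  expect_error(compare_scenarios(e2, mixed), "candidate mix")
})
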