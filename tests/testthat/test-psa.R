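test_that("input sampling is reproducible and respects domains", {
  spec <- psa_spec(n_samples = 500, seed = 99)
  d1 <- sample_inputs(spec)
  d2 <- sample_inputs(spec)
  expect_identical(d1, d2)
  expect_true(all(d1$p_eff > 0 & d1$p_eff < 1))
  expect_true(all(d1$effect_multiplier > 0.5))
  expect_true(all(d1$cost_per_participant >= 1e5 &
                    d1$cost_per_participant <= 4e5))
  expect_true(all(d1$return_per_success > 0))
})

test_that("sample means converge to closed-form distribution means", {
  spec <- psa_spec(n_samples = 10000, seed = 5)
  d <- sample_inputs(spec)
  for (nm in names(d)) {
    mu <- trialflow:::mean_one_dist(spec$distributions[[nm]])
    se <- sd(d[[nm]]) / sqrt(nrow(d))
    expect_lt(abs(mean(d[[nm]]) - mu), 3 * se)
  }
})

test_that("point-mass distributions make every draw deterministic", {
  d <- trialflow:::sample_one_dist(list(dist = "point", value = 3.5), 10)
  expect_equal(d, rep(3.5, 10))
  expect_error(trialflow:::sample_one_dist(list(dist = "cauchy"), 5),
               "unknown distribution")
})

test_that("achieved power recovers nominal power at multiplier one", {
  expect_equal(achieved_power(0.05, 0.5, 1), 0.5, tolerance = 1e-12)
  expect_equal(achieved_power(0.05, 0.9, 1), 0.9, tolerance = 1e-12)
  m <- seq(0.6, 1.6, by = 0.2)
  expect_true(all(diff(achieved_power(0.05, 0.8, m)) > 0))
})

test_that("binomial portfolios respect conservation and expectations", {
  set.seed(314)
  # degenerate certainty: every candidate a true positive
  sure <- scenario("sure", stage_design(0.5, 1 - 1e-15),
                   phase3 = stage_design(0.5, 1 - 1e-15, n_trials = 2),
                   p_eff = 1)
  ps <- simulate_portfolio(sure, n_rep = 20)
  expect_true(all(ps$eff_pass3 == 100))

  reps <- simulate_portfolio(scn1, n_rep = 20000)
  expect_true(all(reps$eff_pass2 <= reps$eff_enter))
  expect_true(all(reps$eff_pass3 <= reps$eff_pass2))
  expect_true(all(reps$ineff_pass2 <= reps$ineff_enter))
  expect_true(all(reps$ineff_pass3 <= reps$ineff_pass2))
  expect_true(all(reps$eff_enter + reps$ineff_enter == 100))
  # binomial expectation oracle for effective passers of both phases
  mu <- 100 * 0.25 * 0.5 * 0.81       # 10.125
  se <- sd(reps$eff_pass3) / sqrt(nrow(reps))
  expect_lt(abs(mean(reps$eff_pass3) - mu), 3 * se)
  # variance sanity at one stage: Binomial(25, 0.5) has variance 6.25
  half <- simulate_portfolio(scenario("h", stage_design(0.05, 0.5),
                                      p_eff = 0.25), n_rep = 20000)
  v <- var(half$eff_pass2[half$eff_enter == 25])
  expect_equal(v, 6.25, tolerance = 0.35)
})

test_that("point-mass PSA collapses to the deterministic profits", {
  spec <- psa_spec(n_samples = 50, seed = 3,
                   distributions = point_mass_distributions())
  res <- run_psa(spec)
  for (nm in names(scn4)) {
    det <- profit(scn4[[nm]], cm_default)$profit
    expect_true(all(abs(res$profits[, nm] - det) < 1e-6))
  }
  expect_true(all(is.na(res$correlations$spearman_rho)))
})

test_that("identical specs and seeds give identical PSA results", {
  spec <- psa_spec(n_samples = 300, seed = 77)
  r1 <- run_psa(spec, portfolio = "binomial")
  r2 <- run_psa(spec, portfolio = "binomial")
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$profits, r2$profits)
})

test_that("dispersed PSA orders scenarios and correlates with value drivers", {
  res <- run_psa(psa_spec(n_samples = 4000, seed = 8))
  m <- res$summary$mean
  names(m) <- res$summary$scenario
  expect_gt(m[["Scenario 4"]], m[["Scenario 2"]])
  expect_gt(m[["Scenario 2"]], m[["Scenario 1"]])
  expect_gt(m[["Scenario 1"]], m[["Scenario 3"]])
  # overlapping distributions: the alternatives lose to the baseline on a
  # nonzero fraction of draws
  expect_gt(mean(res$differences[, "Scenario 2"] < 0), 0)
  expect_gt(mean(res$differences[, "Scenario 4"] < 0), 0)

  co <- res$correlations
  pick <- function(cmp, inp) co$spearman_rho[co$comparison == cmp &
                                               co$input == inp]
  expect_gt(pick("Scenario 2 - Scenario 1", "return_per_success"), 0)
  expect_gt(pick("Scenario 2 - Scenario 1", "p_eff"), 0)
  expect_gt(pick("Scenario 4 - Scenario 1", "return_per_success"), 0)
  expect_gt(pick("Scenario 4 - Scenario 1", "p_eff"), 0)
})

test_that("an input the model ignores shows no rank correlation", {
  set.seed(21)
  res <- run_psa(psa_spec(n_samples = 2000, seed = 13))
  res$draws$dummy <- runif(2000)
  co <- correlate_profit_differences(res)
  dummy_rho <- co$spearman_rho[co$input == "dummy"]
  expect_true(all(abs(dummy_rho) < 3 / sqrt(2000)))
})

test_that("binomial-mode PSA means track the expected flow", {
  res <- run_psa(psa_spec(n_samples = 6000, seed = 4,
                          distributions = point_mass_distributions()),
                 portfolio = "binomial")
  for (nm in c("Scenario 1", "Scenario 4")) {
    det <- profit(scn4[[nm]], cm_default)$profit
    se <- sd(res$profits[, nm]) / sqrt(nrow(res$profits))
    expect_lt(abs(mean(res$profits[, nm]) - det), 3 * se)
  }
})
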