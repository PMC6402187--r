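test_that("normal quantile matches printed conventions and round-trips", {
  expect_equal(standard_normal_quantile(0.5), 0)
  expect_equal(standard_normal_quantile(0.975, "two_decimals"), 1.96)
  expect_equal(standard_normal_quantile(0.8, "two_decimals"), 0.84)
  expect_error(standard_normal_quantile(0), "between 0 and 1")
  expect_error(standard_normal_quantile(1.2), "between 0 and 1")

  p <- seq(0.001, 0.999, length.out = 101)
  expect_equal(pnorm(standard_normal_quantile(p)), p, tolerance = 1e-9)
})

test_that("two-sample power matches simulated two-arm trials", {
  # independent oracle: simulate normal two-arm studies and count rejections
  sim_power <- function(es, n, alpha, n_sim = 40000) {
    set.seed(421)
    x <- matrix(rnorm(n_sim * 2, mean = c(0, es), sd = 1 / sqrt(n)),
                ncol = 2, byrow = TRUE)  # arm means, se = 1/sqrt(n)
    z <- (x[, 2] - x[, 1]) / sqrt(2 / n)
    mean(abs(z) > qnorm(1 - alpha / 2))
  }
  for (case in list(c(0.2772, 100), c(0.2772, 205), c(0.5, 64))) {
    analytic <- power_two_sample(case[1], case[2], 0.05)
    mc <- sim_power(case[1], case[2], 0.05)
    se <- sqrt(mc * (1 - mc) / 40000)
    expect_lt(abs(analytic - mc), 3 * se + 1e-3)
  }
  # calibration of the reference N = 200 phase II study
  expect_equal(power_two_sample(0.2772, 100, 0.05), 0.5, tolerance = 1e-3)
  expect_equal(power_two_sample(0.2772, 205, 0.05), 0.8, tolerance = 2e-3)
  # limit case: huge effect
  expect_equal(power_two_sample(10, 2, 0.05), 1, tolerance = 1e-6)
})

test_that("power is monotone in sample size and effect size", {
  es <- seq(0.1, 0.5, length.out = 10)
  n <- seq(10, 200, length.out = 12)
  pw <- outer(es, n, power_two_sample, alpha = 0.05)
  expect_true(all(diff(pw) > 0))       # along effect size
  expect_true(all(t(diff(t(pw))) > 0)) # along n
})

test_that("required_n_per_arm inverts the power curve", {
  expect_equal(required_n_per_arm(0.2772, 0.05, 0.5), 100L)
  expect_equal(required_n_per_arm(0.2772, 0.05, 0.8), 205L)

  set.seed(7)
  for (i in 1:25) {
    es <- runif(1, 0.15, 1.2)
    alpha <- runif(1, 0.005, 0.2)
    pow <- runif(1, 0.4, 0.97)
    n <- required_n_per_arm(es, alpha, pow)
    expect_gte(power_two_sample(es, n, alpha), pow - 1e-12)
    if (n > 2) expect_lt(power_two_sample(es, n - 1, alpha), pow)
  }
  # quartering under effect-size doubling (unrounded arithmetic)
  n1 <- 2 * (qnorm(0.975) + qnorm(0.8))^2 / 0.2^2
  n2 <- 2 * (qnorm(0.975) + qnorm(0.8))^2 / 0.4^2
  expect_equal(n1 / n2, 4)
  expect_error(required_n_per_arm(0.3, 0.05, 0.01), "unachievable")
})

test_that("sample-size ratio reproduces printed cost scaling and chains", {
  ref <- reference_phase2_design()
  expect_equal(sample_size_ratio(ref, ref), 1)
  expect_equal(sample_size_ratio(stage_design(0.05, 0.8), ref,
                                 rounding = "two_decimals"),
               (1.96 + 0.84)^2 / 1.96^2)  # the 104.1% phase II cost increase
  expect_equal(sample_size_ratio(stage_design(0.01, 0.5), ref,
                                 rounding = "two_decimals"),
               (2.58 / 1.96)^2)

  a <- stage_design(0.2, 0.95); b <- stage_design(0.05, 0.8)
  c_ <- stage_design(0.01, 0.6)
  expect_equal(sample_size_ratio(a, b) * sample_size_ratio(b, c_),
               sample_size_ratio(a, c_), tolerance = 1e-9)
})

test_that("composite stages multiply per-trial probabilities", {
  s1 <- stage_design(0.07, 0.66, n_trials = 1)
  expect_equal(composite_stage(s1), list(alpha = 0.07, power = 0.66))
  s2 <- stage_design(0.05, 0.90, n_trials = 2)
  expect_equal(composite_stage(s2), list(alpha = 0.0025, power = 0.81))
  expect_equal(composite_stage(stage_design(0.05, 0.80, n_trials = 2)),
               list(alpha = 0.0025, power = 0.64))
  # composites never exceed per-trial values
  set.seed(11)
  for (i in 1:20) {
    s <- stage_design(runif(1, 0.01, 0.4), runif(1, 0.4, 0.99),
                      n_trials = sample(1:4, 1))
    cc <- composite_stage(s)
    expect_lte(cc$alpha, s$alpha)
    expect_lte(cc$power, s$power)
  }
})
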