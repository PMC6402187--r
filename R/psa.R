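#' Default input distributions for the probabilistic sensitivity analysis
#'
#' Four independent sampled inputs; alpha and power thresholds stay fixed at
#' their scenario values:
#' * `effect_multiplier` — multiplier on the true standardized effect size
#'   relative to the one the designs were powered for: Normal(1, 0.15)
#'   truncated below at 0.5.
#' * `p_eff` — proportion of truly effective candidates: Beta(5, 15)
#'   (mean 0.25).
#' * `cost_per_participant` — Uniform($100,000, $400,000), the range of the
#'   deterministic cost sweep.
#' * `return_per_success` — LogNormal with median $2,500M and coefficient of
#'   variation 0.5.
#'
#' Each entry is a list with a `dist` name and parameters; `dist = "point"`
#' with `value =` gives a degenerate distribution. Supported: `point`,
#' `truncnorm` (mean, sd, lower), `beta` (shape1, shape2), `uniform`
#' (min, max), `lognormal` (meanlog, sdlog).
#'
#' @return Named list of distribution specifications.
#' @export
default_psa_distributions <- function() {
  list(
    effect_multiplier = list(dist = "truncnorm", mean = 1, sd = 0.15,
                             lower = 0.5),
    p_eff = list(dist = "beta", shape1 = 5, shape2 = 15),
    cost_per_participant = list(dist = "uniform", min = 1e5, max = 4e5),
    return_per_success = list(dist = "lognormal", meanlog = log(2500),
                              sdlog = sqrt(log(1.25)))
  )
}

#' Point-mass distributions at the deterministic defaults
#'
#' Collapses every sampled input to its deterministic base value, so the PSA
#' reproduces the deterministic model exactly (used for degeneracy checks).
#'
#' @param cm A [cost_model()] supplying the cost and return values.
#' @param p_eff Effective-candidate proportion.
#' @return Named list of point-mass distribution specifications.
#' @export
point_mass_distributions <- function(cm = cost_model(), p_eff = 0.25) {
  list(
    effect_multiplier = list(dist = "point", value = 1),
    p_eff = list(dist = "point", value = p_eff),
    cost_per_participant = list(dist = "point",
                                value = cm$cost_per_participant),
    return_per_success = list(dist = "point", value = cm$return_per_success)
  )
}

sample_one_dist <- function(d, n) {
  switch(d$dist,
    point = rep(d$value, n),
    truncnorm = {
      # inverse-CDF sampling restricted to the upper tail above `lower`
      p0 <- stats::pnorm(d$lower, d$mean, d$sd)
      stats::qnorm(p0 + stats::runif(n) * (1 - p0), d$mean, d$sd)
    },
    beta = stats::rbeta(n, d$shape1, d$shape2),
    uniform = stats::runif(n, d$min, d$max),
    lognormal = stats::rlnorm(n, d$meanlog, d$sdlog),
    stop(sprintf("unknown distribution '%s'", d$dist), call. = FALSE)
  )
}

mean_one_dist <- function(d) {
  switch(d$dist,
    point = d$value,
    truncnorm = {
      a <- (d$lower - d$mean) / d$sd
      d$mean + d$sd * stats::dnorm(a) / (1 - stats::pnorm(a))
    },
    beta = d$shape1 / (d$shape1 + d$shape2),
    uniform = (d$min + d$max) / 2,
    lognormal = exp(d$meanlog + d$sdlog^2 / 2)
  )
}

#' Specification of a probabilistic sensitivity analysis
#'
#' @param n_samples Monte Carlo samples (default 10,000).
#' @param portfolio_size Candidates per portfolio (default 100).
#' @param seed Integer seed; identical specs with identical seeds give
#'   bit-identical results.
#' @param distributions Input distributions, as in
#'   [default_psa_distributions()].
#' @param scenarios Named list of [scenario()] objects; the FIRST is the
#'   comparison baseline for profit differences.
#' @param cm A [cost_model()]; its sampled fields (`cost_per_participant`,
#'   `return_per_success`) are overridden draw by draw.
#' @return An object of class `psa_spec`.
#' @export
psa_spec <- function(n_samples = 10000, portfolio_size = 100, seed = 1L,
                     distributions = default_psa_distributions(),
                     scenarios = default_scenarios(),
                     cm = cost_model()) {
  stopifnot(
    n_samples >= 1, portfolio_size >= 1,
    is.numeric(seed), length(seed) == 1,
    length(scenarios) >= 1, inherits(cm, "cost_model")
  )
  required <- c("effect_multiplier", "p_eff", "cost_per_participant",
                "return_per_success")
  if (!all(required %in% names(distributions))) {
    stop("distributions must be named: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  for (scn in scenarios) stopifnot(inherits(scn, "scenario"))
  structure(
    list(n_samples = as.integer(n_samples),
         portfolio_size = as.integer(portfolio_size),
         seed = as.integer(seed), distributions = distributions,
         scenarios = scenarios, cost_model = cm),
    class = "psa_spec"
  )
}

#' Draw the Monte Carlo input table
#'
#' `n_samples` rows of jointly independent draws of the four sampled inputs.
#' Seeds the generator from `spec$seed`, so the same spec always yields the
#' same table.
#'
#' @param spec A [psa_spec()].
#' @return data.frame with columns `effect_multiplier`, `p_eff`,
#'   `cost_per_participant`, `return_per_success`.
#' @export
sample_inputs <- function(spec) {
  stopifnot(inherits(spec, "psa_spec"))
  set.seed(spec$seed)
  as.data.frame(lapply(spec$distributions, sample_one_dist,
                       n = spec$n_samples))
}

#' Achieved per-trial power when the true effect differs from the design
#' assumption
#'
#' A trial designed for nominal power at a reference effect size has an
#' (unrounded) sample size with sqrt(n/2) = (z_alpha + z_power) / ES. If the
#' true effect is `multiplier` times the design effect size, the achieved
#' power is 1 - Phi(z_alpha - multiplier * (z_alpha + z_power)) — the
#' reference effect size cancels. At multiplier 1 this returns the nominal
#' power exactly; alpha is unaffected (an ineffective treatment has no
#' effect whatever the multiplier).
#'
#' @param alpha Per-trial Type-I error.
#' @param nominal_power Per-trial design power.
#' @param multiplier True effect size / design effect size (> 0, vectorised).
#' @param sidedness Quantile convention, as in [stage_design()].
#' @return Achieved per-trial power (vectorised over `multiplier`).
#' @export
achieved_power <- function(alpha, nominal_power, multiplier,
                           sidedness = c("two-sided", "one-sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(all(multiplier > 0))
  za <- alpha_quantile(alpha, sidedness)
  zb <- standard_normal_quantile(nominal_power)
  1 - stats::pnorm(za - multiplier * (za + zb))
}

## composite pass probabilities of a scenario at a given effect multiplier
scenario_pass_probs <- function(scn, effect_multiplier = 1) {
  p2 <- achieved_power(scn$phase2$alpha, scn$phase2$power, effect_multiplier,
                       scn$phase2$sidedness)^scn$phase2$n_trials
  p3 <- achieved_power(scn$phase3$alpha, scn$phase3$power, effect_multiplier,
                       scn$phase3$sidedness)^scn$phase3$n_trials
  list(
    eff_pass2 = p2, eff_pass3 = p3,
    ineff_pass2 = scn$phase2$alpha^scn$phase2$n_trials,
    ineff_pass3 = scn$phase3$alpha^scn$phase3$n_trials
  )
}

#' Simulate integer portfolios through the pipeline (binomial draws)
#'
#' One portfolio: the number of effective candidates is
#' Binomial(portfolio_size, p_eff); each class then passes each stage with
#' its composite probability via further binomial draws, so every replicate
#' satisfies 0 <= passes <= entrants at every stage. Uses the current RNG
#' state (seed with [set.seed()] for reproducibility).
#'
#' @param scn A [scenario()].
#' @param n_rep Number of independent portfolio replicates.
#' @param p_eff Effective proportion (default the scenario's).
#' @param effect_multiplier True effect size relative to the design
#'   assumption (default 1: nominal powers).
#' @param portfolio_size Candidates per portfolio (default the scenario's
#'   `n_candidates`).
#' @return data.frame with `n_rep` rows and integer columns `eff_enter`,
#'   `eff_pass2`, `eff_pass3`, `ineff_enter`, `ineff_pass2`, `ineff_pass3`.
#' @export
simulate_portfolio <- function(scn, n_rep = 1, p_eff = scn$p_eff,
                               effect_multiplier = 1,
                               portfolio_size = scn$n_candidates) {
  stopifnot(inherits(scn, "scenario"), n_rep >= 1,
            p_eff >= 0, p_eff <= 1, portfolio_size >= 1)
  pr <- scenario_pass_probs(scn, effect_multiplier)
  eff <- stats::rbinom(n_rep, portfolio_size, p_eff)
  eff2 <- stats::rbinom(n_rep, eff, pr$eff_pass2)
  ineff2 <- stats::rbinom(n_rep, portfolio_size - eff, pr$ineff_pass2)
  eff3 <- stats::rbinom(n_rep, eff2, pr$eff_pass3)
  ineff3 <- stats::rbinom(n_rep, ineff2, pr$ineff_pass3)
  data.frame(eff_enter = eff, eff_pass2 = eff2, eff_pass3 = eff3,
             ineff_enter = portfolio_size - eff, ineff_pass2 = ineff2,
             ineff_pass3 = ineff3)
}

## vectorised per-draw profit for one scenario; counts may be expected
## (continuous) or realized (integer)
draw_profits <- function(scn, cm, draws, counts) {
  f <- draws$cost_per_participant / 200000
  cost2 <- scn$n_candidates * cm$phase2_cost_reference *
    phase2_cost_multiplier(scn$phase2, cm) * f
  entrants3 <- counts$eff_pass2 + counts$ineff_pass2
  cost3 <- entrants3 * cm$phase3_cost_per_treatment * f
  ret <- (counts$eff_pass3 + counts$ineff_pass3) * draws$return_per_success
  ret - cost2 - cost3
}

#' Run the probabilistic sensitivity analysis
#'
#' For each of `n_samples` parameter draws and each scenario, propagates the
#' portfolio through the two-stage pipeline and prices it. With
#' `portfolio = "expected"` (default) the flow uses expected counts, so all
#' Monte Carlo variation comes from the parameter distributions and a
#' point-mass spec collapses exactly to the deterministic profit. With
#' `portfolio = "binomial"` each draw additionally realizes an integer
#' portfolio by binomial sampling; scenarios share one set of underlying
#' uniform variates (common random numbers, applied through the binomial
#' quantile function), so scenario differences are paired and their variance
#' reduced.
#'
#' @param spec A [psa_spec()].
#' @param portfolio `"expected"` or `"binomial"`.
#' @return A `psa_result`: list with `draws` (input table), `profits`
#'   (n_samples x n_scenarios matrix, $M), `summary` (per-scenario mean and
#'   2.5/97.5 percentiles), `differences` (profits minus the first
#'   scenario's), `correlations` (see [correlate_profit_differences()]),
#'   and `portfolio` (the mode used).
#' @export
run_psa <- function(spec, portfolio = c("expected", "binomial")) {
  portfolio <- match.arg(portfolio)
  stopifnot(inherits(spec, "psa_spec"))
  draws <- sample_inputs(spec)  # seeds the RNG from spec$seed
  n <- spec$n_samples
  N <- spec$portfolio_size
  cm <- spec$cost_model

  if (portfolio == "binomial") {
    # shared uniforms across scenarios: common-random-number pairing
    u_eff <- stats::runif(n); u2e <- stats::runif(n); u2i <- stats::runif(n)
    u3e <- stats::runif(n); u3i <- stats::runif(n)
    eff_enter <- stats::qbinom(u_eff, N, draws$p_eff)
  }

  profits <- sapply(spec$scenarios, function(scn) {
    scn_n <- scenario(scn$name, scn$phase2, phase3 = scn$phase3,
                      p_eff = scn$p_eff, n_candidates = N)
    pr <- scenario_pass_probs(scn_n, draws$effect_multiplier)
    counts <- if (portfolio == "expected") {
      eff <- N * draws$p_eff
      e2 <- eff * pr$eff_pass2
      i2 <- (N - eff) * pr$ineff_pass2
      list(eff_pass2 = e2, ineff_pass2 = i2,
           eff_pass3 = e2 * pr$eff_pass3,
           ineff_pass3 = i2 * pr$ineff_pass3)
    } else {
      e2 <- stats::qbinom(u2e, eff_enter, pr$eff_pass2)
      i2 <- stats::qbinom(u2i, N - eff_enter, pr$ineff_pass2)
      list(eff_pass2 = e2, ineff_pass2 = i2,
           eff_pass3 = stats::qbinom(u3e, e2, pr$eff_pass3),
           ineff_pass3 = stats::qbinom(u3i, i2, pr$ineff_pass3))
    }
    draw_profits(scn_n, cm, draws, counts)
  })
  profits <- matrix(profits, nrow = n,
                    dimnames = list(NULL, names(spec$scenarios)))

  summary <- data.frame(
    scenario = colnames(profits),
    mean = colMeans(profits),
    q2.5 = apply(profits, 2, stats::quantile, 0.025, names = FALSE),
    q97.5 = apply(profits, 2, stats::quantile, 0.975, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  differences <- profits[, -1, drop = FALSE] - profits[, 1]

  res <- structure(
    list(draws = draws, profits = profits, summary = summary,
         differences = differences, correlations = NULL,
         portfolio = portfolio, spec = spec),
    class = "psa_result"
  )
  res$correlations <- correlate_profit_differences(res)
  res
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("<psa_result> %d draws, %s portfolios\n",
              nrow(x$profits), x$portfolio))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Rank correlations between profit differences and sampled inputs
#'
#' For each non-baseline scenario, the Spearman correlation between its
#' profit difference from the baseline (first) scenario and each sampled
#' input column. Spearman is used because the inputs are skewed. Degenerate
#' (zero-variance) columns or differences yield `NA`.
#'
#' @param result A [run_psa()] result.
#' @return data.frame with columns `comparison`, `input`, `spearman_rho`.
#' @export
correlate_profit_differences <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  diffs <- result$differences
  if (ncol(diffs) == 0) return(
    data.frame(comparison = character(), input = character(),
               spearman_rho = numeric()))
  rows <- list()
  base <- colnames(result$profits)[1]
  for (j in seq_len(ncol(diffs))) {
    d <- diffs[, j]
    for (inp in names(result$draws)) {
      v <- result$draws[[inp]]
      rho <- if (stats::sd(d) == 0 || stats::sd(v) == 0) NA_real_ else
        stats::cor(d, v, method = "spearman")
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = sprintf("%s - %s", colnames(diffs)[j], base),
        input = inp, spearman_rho = rho, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
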