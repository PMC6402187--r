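#' Standard normal quantile with an optional printed-rounding convention
#'
#' Thin wrapper around [stats::qnorm()] that optionally rounds the quantile to
#' two decimal places. Two-decimal quantiles (1.96, 0.84, 2.58, ...) are the
#' convention of printed sample-size arithmetic and are what the economic
#' layer uses by default to reproduce published cost ratios; full precision is
#' the default everywhere else.
#'
#' @param p Probability, strictly between 0 and 1.
#' @param rounding `"none"` (full precision) or `"two_decimals"`.
#' @return The quantile z with `pnorm(z) = p` (before rounding).
#' @examples
#' standard_normal_quantile(0.975, "two_decimals") # 1.96
#' standard_normal_quantile(0.8, "two_decimals")   # 0.84
#' @export
standard_normal_quantile <- function(p, rounding = c("none", "two_decimals")) {
  rounding <- match.arg(rounding)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  }
  z <- stats::qnorm(p)
  if (rounding == "two_decimals") z <- round(z, 2)
  z
}

## z for the rejection threshold: alpha/2 in each tail when two-sided
alpha_quantile <- function(alpha, sidedness, rounding = "none") {
  p <- if (sidedness == "two-sided") 1 - alpha / 2 else 1 - alpha
  standard_normal_quantile(p, rounding)
}

#' Describe one development stage by its per-trial operating characteristics
#'
#' A stage (phase II or phase III) is a set of `n_trials` independent trials
#' that must all pass. Each trial rejects the null for an ineffective
#' treatment with probability `alpha` (Type-I error) and for an effective
#' treatment with probability `power` (1 - Type-II error). `sidedness` only
#' matters for sample-size arithmetic, where the two-sided convention uses
#' the alpha/2 quantile.
#'
#' @param alpha Per-trial Type-I error rate, in (0, 1).
#' @param power Per-trial power, in (0, 1).
#' @param n_trials Number of independent trials that must all pass (>= 1).
#' @param sidedness `"two-sided"` (default) or `"one-sided"`.
#' @return An object of class `stage_design`.
#' @examples
#' phase3 <- stage_design(0.05, 0.90, n_trials = 2)
#' composite_stage(phase3) # alpha 0.0025, power 0.81
#' @export
stage_design <- function(alpha, power, n_trials = 1L,
                         sidedness = c("two-sided", "one-sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(
    is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1,
    is.numeric(power), length(power) == 1, power > 0, power < 1,
    is.numeric(n_trials), length(n_trials) == 1, n_trials >= 1,
    n_trials == as.integer(n_trials)
  )
  structure(
    list(alpha = alpha, power = power, n_trials = as.integer(n_trials),
         sidedness = sidedness),
    class = "stage_design"
  )
}

#' @export
print.stage_design <- function(x, ...) {
  comp <- composite_stage(x)
  cat(sprintf(
    "<stage_design> %d trial(s), per-trial alpha = %g, power = %g (%s)\n",
    x$n_trials, x$alpha, x$power, x$sidedness))
  if (x$n_trials > 1) {
    cat(sprintf("  composite alpha = %g, composite power = %g\n",
                comp$alpha, comp$power))
  }
  invisible(x)
}

#' Composite operating characteristics of a multi-trial stage
#'
#' A stage requiring k independent trials to all pass lets an ineffective
#' treatment through with probability alpha^k and an effective one with
#' probability power^k. The regulatory two-trial phase III with per-trial
#' alpha 5% and power 90% therefore has composite alpha 0.25% and composite
#' power 81%.
#'
#' @param stage A [stage_design()].
#' @return A list with elements `alpha` and `power` (composite probabilities).
#' @export
composite_stage <- function(stage) {
  stopifnot(inherits(stage, "stage_design"))
  list(alpha = stage$alpha^stage$n_trials, power = stage$power^stage$n_trials)
}

#' Power of a two-arm comparison under the normal approximation
#'
#' Power = 1 - Phi(z_{1-a} - ES * sqrt(n/2)) for a two-arm trial with `n`
#' participants per arm and standardized mean difference ES = (mu1 - mu0) /
#' sigma. Under the two-sided convention z_{1-a} is the alpha/2 quantile;
#' the (negligible) probability of rejecting on the wrong side is ignored,
#' as is conventional for this approximation.
#'
#' @param effect_size Standardized mean difference, > 0. Vectorised.
#' @param n_per_arm Participants per arm, >= 2. Vectorised.
#' @param alpha Type-I error rate of the single trial.
#' @param sidedness `"two-sided"` (default) or `"one-sided"`.
#' @return Power in (0, 1), strictly increasing in both `effect_size` and
#'   `n_per_arm`.
#' @examples
#' power_two_sample(0.2772, 100, 0.05) # ~ 0.50: the reference N = 200 study
#' @export
power_two_sample <- function(effect_size, n_per_arm, alpha,
                             sidedness = c("two-sided", "one-sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(all(effect_size > 0), all(n_per_arm >= 2),
            alpha > 0, alpha < 1)
  za <- alpha_quantile(alpha, sidedness)
  1 - stats::pnorm(za - effect_size * sqrt(n_per_arm / 2))
}

#' Smallest per-arm sample size achieving a requested power
#'
#' Inverts the two-arm normal-approximation power formula:
#' n = 2 * (z_{1-a} + z_power)^2 / ES^2, rounded up to the next integer.
#' Doubling the effect size divides the unrounded n by four.
#'
#' @inheritParams power_two_sample
#' @param power Requested power, in (0, 1). Must exceed the floor reached as
#'   n grows from nothing, i.e. `z_power > -z_{1-a}` must hold.
#' @param rounding Quantile rounding mode passed to
#'   [standard_normal_quantile()].
#' @return Integer participants per arm (total study size is twice this).
#' @examples
#' required_n_per_arm(0.2772, 0.05, 0.5) # 100 (the N = 200 reference design)
#' required_n_per_arm(0.2772, 0.05, 0.8) # 205
#' @export
required_n_per_arm <- function(effect_size, alpha, power,
                               sidedness = c("two-sided", "one-sided"),
                               rounding = c("none", "two_decimals")) {
  sidedness <- match.arg(sidedness)
  rounding <- match.arg(rounding)
  stopifnot(effect_size > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  za <- alpha_quantile(alpha, sidedness, rounding)
  zb <- standard_normal_quantile(power, rounding)
  if (za + zb <= 0) {
    stop("requested power is unachievable at this alpha (z_alpha + z_power <= 0)",
         call. = FALSE)
  }
  n <- 2 * (za + zb)^2 / effect_size^2
  max(2L, as.integer(ceiling(n - 1e-9)))
}

#' Sample-size ratio between two stage designs
#'
#' The per-arm sample size under the normal approximation is proportional to
#' (z_{1-a} + z_power)^2 / ES^2; at a common effect size the ratio of two
#' designs' sample sizes is therefore ((z_{1-a} + z_power) /
#' (z_{1-a,ref} + z_power,ref))^2, independent of the effect size. This ratio
#' is what scales phase II program costs across designs.
#'
#' @param design,reference [stage_design()] objects (per-trial values used).
#' @param rounding Quantile rounding mode; the printed-economics convention is
#'   `"two_decimals"`.
#' @return Dimensionless ratio > 0.
#' @examples
#' sample_size_ratio(stage_design(0.05, 0.8), stage_design(0.05, 0.5),
#'                   rounding = "two_decimals") # (1.96 + 0.84)^2 / 1.96^2
#' @export
sample_size_ratio <- function(design, reference,
                              rounding = c("none", "two_decimals")) {
  rounding <- match.arg(rounding)
  stopifnot(inherits(design, "stage_design"), inherits(reference, "stage_design"))
  num <- alpha_quantile(design$alpha, design$sidedness, rounding) +
    standard_normal_quantile(design$power, rounding)
  den <- alpha_quantile(reference$alpha, reference$sidedness, rounding) +
    standard_normal_quantile(reference$power, rounding)
  (num / den)^2
}

#' The reference phase II design (alpha 5% two-sided, power 50%)
#'
#' The anchor for all cost scaling: a single phase II trial with two-sided
#' alpha 5% and 50% power. At effect size 0.2772 this design needs 100
#' participants per arm (a 200-participant study), which at $200,000 per
#' participant costs the reference $40M.
#'
#' @return A [stage_design()].
#' @export
reference_phase2_design <- function() stage_design(0.05, 0.50, 1L)

#' Reference standardized effect size calibrating the N = 200 phase II study
#'
#' The effect size at which the reference phase II design (alpha 5%
#' two-sided, 50% power) requires exactly 100 participants per arm.
#' @return A number (0.2772).
#' @export
reference_effect_size <- function() 0.2772
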