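#' Round half away from zero (printed-table convention)
#'
#' Published tables round expected counts half-up (16.25 prints as 16.3),
#' whereas [round()] rounds half to even (16.2). All "printed mode" numbers
#' in this package use half-up rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places to keep.
#' @return `x` rounded half away from zero.
#' @examples
#' round_half_up(16.25, 1) # 16.3 (base round() gives 16.2)
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Define a development scenario: phase II design, phase III design,
#' candidate mix
#'
#' A scenario sends `n_candidates` treatments, of which a fraction `p_eff`
#' are truly effective, through a single phase II trial and then (for phase
#' II passers) through a two-trial confirmatory phase III. The default phase
#' III (per-trial alpha 5%, power 90%, two trials) is the regulatory
#' standard and is held fixed across the canonical scenarios.
#'
#' @param name Scenario label.
#' @param phase2 A [stage_design()] with `n_trials = 1`.
#' @param phase3 A [stage_design()]; default two trials at alpha 5%,
#'   power 90% each (composite alpha 0.25%, composite power 81%).
#' @param p_eff Proportion of candidates that are truly effective, in [0, 1].
#' @param n_candidates Number of candidates entering phase II.
#' @return An object of class `scenario`.
#' @examples
#' status_quo <- scenario("Scenario 1", stage_design(0.05, 0.50))
#' run_flow(status_quo)
#' @export
scenario <- function(name, phase2,
                     phase3 = stage_design(0.05, 0.90, n_trials = 2L),
                     p_eff = 0.25, n_candidates = 100) {
  stopifnot(
    inherits(phase2, "stage_design"), inherits(phase3, "stage_design"),
    is.numeric(p_eff), length(p_eff) == 1, p_eff >= 0, p_eff <= 1,
    is.numeric(n_candidates), length(n_candidates) == 1, n_candidates > 0
  )
  structure(
    list(name = as.character(name), phase2 = phase2, phase3 = phase3,
         p_eff = p_eff, n_candidates = n_candidates),
    class = "scenario"
  )
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf(
    "<scenario> %s: phase II alpha = %g, power = %g; phase III %d x (alpha = %g, power = %g); %g%% effective of %g candidates\n",
    x$name, x$phase2$alpha, x$phase2$power, x$phase3$n_trials,
    x$phase3$alpha, x$phase3$power, 100 * x$p_eff, x$n_candidates))
  invisible(x)
}

#' The four canonical development scenarios
#'
#' Scenario 1 ("status quo"): phase II alpha 5%, power 50%. Scenario 2
#' ("high power"): alpha 5%, power 80%. Scenario 3 ("stringent alpha"):
#' alpha 1%, power 50%. Scenario 4 ("lenient alpha, high power"): alpha 20%,
#' power 95% — the profit-maximising design found by [find_optimum()]. All
#' share the two-trial phase III (alpha 5%, power 90% per trial), 25%
#' effective candidates, and a 100-candidate portfolio.
#'
#' @param p_eff Proportion of effective candidates (default 0.25).
#' @param n_candidates Portfolio size (default 100).
#' @param phase3 Shared phase III design.
#' @return Named list of four [scenario()] objects.
#' @export
default_scenarios <- function(p_eff = 0.25, n_candidates = 100,
                              phase3 = stage_design(0.05, 0.90, n_trials = 2L)) {
  defs <- list(
    "Scenario 1" = c(0.05, 0.50),
    "Scenario 2" = c(0.05, 0.80),
    "Scenario 3" = c(0.01, 0.50),
    "Scenario 4" = c(0.20, 0.95)
  )
  lapply(stats::setNames(names(defs), names(defs)), function(nm) {
    scenario(nm, stage_design(defs[[nm]][1], defs[[nm]][2]),
             phase3 = phase3, p_eff = p_eff, n_candidates = n_candidates)
  })
}

#' Propagate expected treatment counts through phase II and phase III
#'
#' Effective treatments pass each stage with that stage's composite power;
#' ineffective treatments pass with the composite Type-I error. Counts are
#' expectations (continuous), not integers; failures at phase II leave the
#' pipeline permanently. For the status-quo scenario this yields 12.5
#' effective and 3.75 ineffective phase II passers, of which 10.125 and
#' 0.009 pass the two-trial phase III.
#'
#' @param scn A [scenario()].
#' @return A `flow_result`: a data.frame with one row per (class, stage) and
#'   columns `class`, `stage`, `enter`, `pass`, `fail`, carrying the scenario
#'   as attribute `scenario`.
#' @export
run_flow <- function(scn) {
  stopifnot(inherits(scn, "scenario"))
  c2 <- composite_stage(scn$phase2)
  c3 <- composite_stage(scn$phase3)
  n_eff <- scn$p_eff * scn$n_candidates
  n_ineff <- (1 - scn$p_eff) * scn$n_candidates

  enter <- c(n_eff, n_ineff,
             n_eff * c2$power, n_ineff * c2$alpha)
  p_pass <- c(c2$power, c2$alpha, c3$power, c3$alpha)
  pass <- enter * p_pass

  res <- data.frame(
    class = rep(c("effective", "ineffective"), times = 2),
    stage = rep(c("II", "III"), each = 2),
    enter = enter,
    pass = pass,
    fail = enter - pass,
    stringsAsFactors = FALSE
  )
  structure(res, class = c("flow_result", "data.frame"), scenario = scn)
}

flow_cell <- function(flow, class, stage, what) {
  flow[[what]][flow$class == class & flow$stage == stage]
}

#' Classify pipeline outcomes as true/false positives/negatives
#'
#' True positives are effective treatments passing both phases; false
#' negatives are effective treatments failing at either phase (the "missed
#' opportunities"); false positives are ineffective treatments passing both
#' phases; true negatives are ineffective treatments failing at either
#' phase. In printed mode each per-stage expected count is rounded to one
#' decimal (half-up) before summing, matching published table arithmetic
#' (e.g. 12.5 + 2.4 = 14.9 false negatives in the status quo).
#'
#' @param flow A [run_flow()] result.
#' @param mode `"exact"` (default) or `"printed"`.
#' @return A list of class `classification` with elements `true_positives`,
#'   `false_negatives`, `false_positives`, `true_negatives`.
#' @export
classify_outcomes <- function(flow, mode = c("exact", "printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(flow, "flow_result"))
  r <- if (mode == "printed") function(x) round_half_up(x, 1) else identity
  out <- list(
    true_positives  = r(flow_cell(flow, "effective", "III", "pass")),
    false_negatives = r(flow_cell(flow, "effective", "II", "fail")) +
      r(flow_cell(flow, "effective", "III", "fail")),
    false_positives = r(flow_cell(flow, "ineffective", "III", "pass")),
    true_negatives  = r(flow_cell(flow, "ineffective", "II", "fail")) +
      r(flow_cell(flow, "ineffective", "III", "fail"))
  )
  structure(out, class = "classification", mode = mode,
            scenario = attr(flow, "scenario"))
}

#' @export
print.classification <- function(x, ...) {
  cat(sprintf(
    "<classification> (%s mode) TP %.4g | FN %.4g | FP %.4g | TN %.4g\n",
    attr(x, "mode"), x$true_positives, x$false_negatives,
    x$false_positives, x$true_negatives))
  invisible(x)
}

#' Productivity and passage metrics for a development flow
#'
#' Productivity is the fraction of the truly effective candidates entering
#' phase II that pass both phases (true positives over all effective). Also
#' reported: the percentage of all candidates passing phase II, the
#' percentage of phase III entrants that are effective, and — when a
#' baseline flow is supplied — the relative change in productivity. In
#' printed mode expected counts are rounded to one decimal before ratios are
#' formed, which is what reproduces published percentages such as 40.4%
#' (10.1 / 25) and 84.0% (20.0 / 23.8).
#'
#' @param flow A [run_flow()] result.
#' @param baseline Optional baseline `flow_result` sharing `n_candidates`
#'   and `p_eff` (for the relative-change metric).
#' @param mode `"exact"` or `"printed"`.
#' @return A list with elements `productivity_pct`, `pass_phase2_pct`,
#'   `effective_among_phase3_entrants_pct`, `pass_phase3_of_entrants_pct`,
#'   and (with a baseline) `productivity_change_pct`.
#' @export
productivity_metrics <- function(flow, baseline = NULL,
                                 mode = c("exact", "printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(flow, "flow_result"))
  scn <- attr(flow, "scenario")
  r <- if (mode == "printed") function(x) round_half_up(x, 1) else identity

  n_eff <- scn$p_eff * scn$n_candidates
  tp <- r(flow_cell(flow, "effective", "III", "pass"))
  pass2_eff <- r(flow_cell(flow, "effective", "II", "pass"))
  pass2_ineff <- r(flow_cell(flow, "ineffective", "II", "pass"))
  entrants3 <- pass2_eff + pass2_ineff
  pass3 <- r(flow_cell(flow, "effective", "III", "pass")) +
    r(flow_cell(flow, "ineffective", "III", "pass"))

  out <- list(
    productivity_pct = 100 * tp / n_eff,
    pass_phase2_pct = 100 * entrants3 / scn$n_candidates,
    effective_among_phase3_entrants_pct = 100 * pass2_eff / entrants3,
    pass_phase3_of_entrants_pct = 100 * pass3 / entrants3
  )
  if (!is.null(baseline)) {
    stopifnot(inherits(baseline, "flow_result"))
    bscn <- attr(baseline, "scenario")
    if (!isTRUE(all.equal(bscn$n_candidates, scn$n_candidates)) ||
        !isTRUE(all.equal(bscn$p_eff, scn$p_eff))) {
      stop("baseline flow has a different candidate mix", call. = FALSE)
    }
    base <- productivity_metrics(baseline, mode = mode)
    out$productivity_change_pct <-
      100 * (out$productivity_pct - base$productivity_pct) /
      base$productivity_pct
  }
  out
}
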