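#' Monetary parameters of the development pipeline
#'
#' All program costs are expressed in $M per treatment at the reference
#' phase II design (alpha 5% two-sided, power 50%, a 200-participant study
#' at $200,000 per participant = $40M). Phase II costs for other designs
#' scale with the normal-approximation sample-size ratio, discounted by an
#' economies-of-scale factor applied to the incremental part; phase III
#' costs are per treatment entering phase III and do not vary with the
#' phase II design. Both program costs scale linearly with
#' `cost_per_participant` relative to the $200,000 reference.
#'
#' @param phase2_cost_reference Phase II program cost per treatment at the
#'   reference design ($M, default 40).
#' @param phase3_cost_per_treatment Phase III program cost per treatment
#'   entering phase III ($M, default 163).
#' @param cost_per_participant Cost per study participant in dollars
#'   (default 200,000; the reference 200-participant study then costs $40M).
#' @param economies_factor Fraction of the incremental sample-size-driven
#'   cost actually incurred, in (0, 1]. Default 0.8: larger studies pay only
#'   80% of the proportional extra cost. Set to 1 for strict
#'   proportional-to-sample-size costing (the convention that reproduces a
#'   printed Scenario 2 phase II cost of $8,163M).
#' @param return_per_success Revenue per treatment passing phase III
#'   ($M, default 2,500).
#' @param phase2_effect_multiplier Effect-size multiplier >= 1 for
#'   "adjusted" analyses in which surrogate endpoints or enriched
#'   populations raise the phase II effect size, shrinking the required
#'   sample size (and cost) by the squared multiplier. Default 1.
#' @param z_rounding Quantile rounding for the sample-size ratio;
#'   `"two_decimals"` (default) is the printed-economics convention.
#' @return An object of class `cost_model`.
#' @examples
#' cm <- cost_model()
#' phase2_program_cost(default_scenarios()[["Scenario 1"]], cm) # 4000
#' @export
cost_model <- function(phase2_cost_reference = 40,
                       phase3_cost_per_treatment = 163,
                       cost_per_participant = 200000,
                       economies_factor = 0.8,
                       return_per_success = 2500,
                       phase2_effect_multiplier = 1,
                       z_rounding = c("two_decimals", "none")) {
  z_rounding <- match.arg(z_rounding)
  stopifnot(
    phase2_cost_reference >= 0, phase3_cost_per_treatment >= 0,
    cost_per_participant >= 0, return_per_success >= 0,
    economies_factor > 0, economies_factor <= 1,
    phase2_effect_multiplier >= 1
  )
  structure(
    list(phase2_cost_reference = phase2_cost_reference,
         phase3_cost_per_treatment = phase3_cost_per_treatment,
         cost_per_participant = cost_per_participant,
         economies_factor = economies_factor,
         return_per_success = return_per_success,
         phase2_effect_multiplier = phase2_effect_multiplier,
         z_rounding = z_rounding),
    class = "cost_model"
  )
}

#' @export
print.cost_model <- function(x, ...) {
  cat(sprintf(
    "<cost_model> phase II ref $%gM, phase III $%gM/treatment, $%s/participant,\n  economies factor %g, return $%gM/success, phase II effect multiplier %g, z rounding %s\n",
    x$phase2_cost_reference, x$phase3_cost_per_treatment,
    format(x$cost_per_participant, big.mark = ","), x$economies_factor,
    x$return_per_success, x$phase2_effect_multiplier, x$z_rounding))
  invisible(x)
}

participant_cost_factor <- function(cm) cm$cost_per_participant / 200000

## sample-size-driven phase II cost multiplier relative to the reference
## design, with economies-of-scale discount on the incremental part
phase2_cost_multiplier <- function(phase2, cm) {
  ratio <- sample_size_ratio(phase2, reference_phase2_design(),
                             rounding = cm$z_rounding) /
    cm$phase2_effect_multiplier^2
  if (ratio > 1) 1 + cm$economies_factor * (ratio - 1) else ratio
}

#' Phase II program cost of a scenario
#'
#' `n_candidates` x reference cost x sample-size-driven multiplier x
#' participant-cost factor. The multiplier is the sample-size ratio of the
#' scenario's phase II design to the reference design (divided by the
#' squared effect multiplier for adjusted analyses), with the
#' economies-of-scale factor applied to the part exceeding 1.
#'
#' @param scn A [scenario()].
#' @param cm A [cost_model()].
#' @return Cost in $M.
#' @export
phase2_program_cost <- function(scn, cm) {
  stopifnot(inherits(scn, "scenario"), inherits(cm, "cost_model"))
  scn$n_candidates * cm$phase2_cost_reference *
    phase2_cost_multiplier(scn$phase2, cm) * participant_cost_factor(cm)
}

#' Phase III program cost of a flow
#'
#' Expected treatments entering phase III times the per-treatment phase III
#' cost, scaled by the participant-cost factor. The phase III design is
#' identical across scenarios, so its per-treatment cost is constant.
#'
#' @param flow A [run_flow()] result.
#' @param cm A [cost_model()].
#' @return Cost in $M.
#' @export
phase3_program_cost <- function(flow, cm) {
  stopifnot(inherits(flow, "flow_result"), inherits(cm, "cost_model"))
  entrants <- flow_cell(flow, "effective", "III", "enter") +
    flow_cell(flow, "ineffective", "III", "enter")
  entrants * cm$phase3_cost_per_treatment * participant_cost_factor(cm)
}

#' Expected return of a flow
#'
#' Return per success times the total expected treatments passing phase III
#' — both classes, exact unrounded expected counts (an approved ineffective
#' treatment earns revenue just the same).
#'
#' @param flow A [run_flow()] result.
#' @param cm A [cost_model()].
#' @return Return in $M.
#' @export
expected_return <- function(flow, cm) {
  stopifnot(inherits(flow, "flow_result"), inherits(cm, "cost_model"))
  passers <- flow_cell(flow, "effective", "III", "pass") +
    flow_cell(flow, "ineffective", "III", "pass")
  cm$return_per_success * passers
}

#' Full economic result of a scenario
#'
#' Assembles phase II cost, phase III cost, expected return, and profit
#' (return minus total cost) for one scenario.
#'
#' @param scn A [scenario()].
#' @param cm A [cost_model()].
#' @param flow Optional precomputed [run_flow()] result for `scn`.
#' @return An object of class `economic_result` with elements `cost_phase2`,
#'   `cost_phase3`, `total_cost`, `expected_return`, `profit` (all $M).
#' @export
profit <- function(scn, cm = cost_model(), flow = run_flow(scn)) {
  stopifnot(inherits(scn, "scenario"), inherits(cm, "cost_model"),
            inherits(flow, "flow_result"))
  c2 <- phase2_program_cost(scn, cm)
  c3 <- phase3_program_cost(flow, cm)
  ret <- expected_return(flow, cm)
  structure(
    list(cost_phase2 = c2, cost_phase3 = c3, total_cost = c2 + c3,
         expected_return = ret, profit = ret - c2 - c3),
    class = "economic_result", scenario = scn, flow = flow
  )
}

#' @export
print.economic_result <- function(x, ...) {
  scn <- attr(x, "scenario")
  cat(sprintf(
    "<economic_result> %s: phase II $%.0fM + phase III $%.0fM; return $%.0fM; profit $%.0fM\n",
    scn$name, x$cost_phase2, x$cost_phase3, x$expected_return, x$profit))
  invisible(x)
}

#' Percent differences between two scenarios' economics and productivity
#'
#' Relative changes (a - b) / b x 100 in productivity, per-phase costs,
#' return, and profit. A zero baseline component yields `NA` (flagged
#' undefined), not an error.
#'
#' @param a,b [profit()] results (each carrying its scenario and flow).
#' @param mode Rounding mode for the productivity component.
#' @return Named list of percent changes (`*_pct_change`).
#' @export
compare_scenarios <- function(a, b, mode = c("exact", "printed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "economic_result"), inherits(b, "economic_result"))
  sa <- attr(a, "scenario"); sb <- attr(b, "scenario")
  if (!isTRUE(all.equal(sa$n_candidates, sb$n_candidates)) ||
      !isTRUE(all.equal(sa$p_eff, sb$p_eff))) {
    stop("scenarios have different candidate mixes", call. = FALSE)
  }
  pct <- function(x, y) if (abs(y) < .Machine$double.eps) NA_real_ else
    100 * (x - y) / y
  prod_a <- productivity_metrics(attr(a, "flow"), mode = mode)$productivity_pct
  prod_b <- productivity_metrics(attr(b, "flow"), mode = mode)$productivity_pct
  list(
    productivity_pct_change = pct(prod_a, prod_b),
    cost_phase2_pct_change = pct(a$cost_phase2, b$cost_phase2),
    cost_phase3_pct_change = pct(a$cost_phase3, b$cost_phase3),
    return_pct_change = pct(a$expected_return, b$expected_return),
    profit_pct_change = pct(a$profit, b$profit)
  )
}
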