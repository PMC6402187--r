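#' Grid of phase II (alpha, power) designs to evaluate
#'
#' @param alpha_values Strictly increasing per-trial Type-I error rates in
#'   (0, 1). The default {0.01, 0.05, 0.10, 0.20, 0.30} spans the stringent
#'   through lenient conventions.
#' @param power_values Strictly increasing per-trial powers in (0, 1);
#'   default 0.50 to 0.99 in steps of 0.01.
#' @param scenario_template A [scenario()] supplying everything except the
#'   phase II design (phase III, candidate mix).
#' @param cm A [cost_model()].
#' @return An object of class `search_grid`.
#' @export
search_grid <- function(alpha_values = c(0.01, 0.05, 0.10, 0.20, 0.30),
                        power_values = seq(0.50, 0.99, by = 0.01),
                        scenario_template = default_scenarios()[["Scenario 1"]],
                        cm = cost_model()) {
  stopifnot(
    length(alpha_values) >= 1, all(alpha_values > 0), all(alpha_values < 1),
    !is.unsorted(alpha_values, strictly = TRUE),
    length(power_values) >= 1, all(power_values > 0), all(power_values < 1),
    !is.unsorted(power_values, strictly = TRUE),
    inherits(scenario_template, "scenario"), inherits(cm, "cost_model")
  )
  structure(
    list(alpha_values = alpha_values, power_values = power_values,
         scenario_template = scenario_template, cost_model = cm),
    class = "search_grid"
  )
}

grid_scenario <- function(grid, alpha, power) {
  tpl <- grid$scenario_template
  scenario(sprintf("alpha=%g, power=%g", alpha, power),
           stage_design(alpha, power, 1L, tpl$phase2$sidedness),
           phase3 = tpl$phase3, p_eff = tpl$p_eff,
           n_candidates = tpl$n_candidates)
}

#' Profit and productivity over a phase II design grid
#'
#' Evaluates [run_flow()] + [profit()] at every (alpha, power) cell, holding
#' phase III, the candidate mix, and the cost model fixed.
#'
#' @param grid A [search_grid()].
#' @return A `profit_surface`: a data.frame with one row per cell and
#'   columns `alpha`, `power`, `profit`, `productivity_pct`, plus the grid
#'   as attribute.
#' @export
profit_surface <- function(grid) {
  stopifnot(inherits(grid, "search_grid"))
  cells <- expand.grid(alpha = grid$alpha_values, power = grid$power_values,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    scn <- grid_scenario(grid, cells$alpha[i], cells$power[i])
    fl <- run_flow(scn)
    ec <- profit(scn, grid$cost_model, fl)
    c(profit = ec$profit,
      productivity_pct = productivity_metrics(fl)$productivity_pct)
  })
  res <- do.call(rbind, res)
  out <- cbind(cells, as.data.frame(res))
  structure(out, class = c("profit_surface", "data.frame"), grid = grid)
}

#' Profit-maximising cell of a profit surface
#'
#' Ties are broken deterministically towards the lowest alpha, then the
#' lowest power.
#'
#' @param surface A [profit_surface()].
#' @return A list with `alpha`, `power`, `profit`.
#' @examples
#' \donttest{
#' find_optimum(profit_surface(search_grid())) # alpha 0.20, power 0.95
#' }
#' @export
find_optimum <- function(surface) {
  stopifnot(inherits(surface, "profit_surface"), nrow(surface) >= 1)
  best <- surface[surface$profit == max(surface$profit), , drop = FALSE]
  best <- best[order(best$alpha, best$power), , drop = FALSE]
  list(alpha = best$alpha[1], power = best$power[1], profit = best$profit[1])
}

#' Profit as a function of cost per participant
#'
#' Re-prices each scenario over a range of per-participant costs. Both the
#' phase II and phase III program costs scale linearly with cost per
#' participant (a global unit-cost sweep), so each curve is affine with
#' negative slope; returns do not depend on the cost parameter.
#'
#' @param scenarios List of [scenario()] objects (e.g.
#'   [default_scenarios()]).
#' @param cost_values Per-participant costs in dollars, all > 0.
#' @param cm Base [cost_model()]; its `cost_per_participant` is replaced by
#'   each swept value.
#' @param phase3_power Optional per-trial phase III power override (e.g.
#'   0.80 vs the default 0.90) applied to every scenario.
#' @return A data.frame with columns `scenario`, `cost_per_participant`,
#'   `profit`; attribute `convention` records that both phases scale.
#' @export
sweep_cost_per_participant <- function(scenarios,
                                       cost_values = seq(1e5, 4e5, by = 5e4),
                                       cm = cost_model(),
                                       phase3_power = NULL) {
  stopifnot(all(cost_values > 0), inherits(cm, "cost_model"))
  rows <- list()
  for (scn in scenarios) {
    stopifnot(inherits(scn, "scenario"))
    if (!is.null(phase3_power)) {
      scn <- scenario(scn$name, scn$phase2,
                      phase3 = stage_design(scn$phase3$alpha, phase3_power,
                                            scn$phase3$n_trials,
                                            scn$phase3$sidedness),
                      p_eff = scn$p_eff, n_candidates = scn$n_candidates)
    }
    fl <- run_flow(scn)
    for (cpp in cost_values) {
      cmi <- cm
      cmi$cost_per_participant <- cpp
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scn$name, cost_per_participant = cpp,
        profit = profit(scn, cmi, fl)$profit, stringsAsFactors = FALSE)
    }
  }
  structure(do.call(rbind, rows),
            convention = "phase II and phase III program costs both scale with cost_per_participant / 200000")
}

#' Profit as a function of the proportion of effective candidates
#'
#' @param scenarios List of [scenario()] objects.
#' @param p_values Proportions of effective candidates in [0, 1].
#' @param cm A [cost_model()].
#' @return A data.frame with columns `scenario`, `p_eff`, `profit`.
#' @export
sweep_p_eff <- function(scenarios, p_values = seq(0, 0.5, by = 0.05),
                        cm = cost_model()) {
  stopifnot(all(p_values >= 0), all(p_values <= 1), inherits(cm, "cost_model"))
  rows <- list()
  for (scn in scenarios) {
    stopifnot(inherits(scn, "scenario"))
    for (p in p_values) {
      scn_p <- scenario(scn$name, scn$phase2, phase3 = scn$phase3,
                        p_eff = p, n_candidates = scn$n_candidates)
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = scn$name, p_eff = p,
        profit = profit(scn_p, cm)$profit, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
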