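#' Default run configuration
#'
#' The four canonical scenarios, the default cost model, the default PSA,
#' the default search grid and sweeps, printed-rounding reporting, seed 1.
#' This is also the schema against which [load_config()] validates: a config
#' file may override any subset of these fields, and unknown keys are
#' rejected.
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    rounding = "printed",
    scenarios = lapply(default_scenarios(), function(s) list(
      name = s$name,
      phase2 = list(alpha = s$phase2$alpha, power = s$phase2$power,
                    n_trials = s$phase2$n_trials,
                    sidedness = s$phase2$sidedness),
      phase3 = list(alpha = s$phase3$alpha, power = s$phase3$power,
                    n_trials = s$phase3$n_trials,
                    sidedness = s$phase3$sidedness),
      p_eff = s$p_eff, n_candidates = s$n_candidates)),
    cost_model = list(
      phase2_cost_reference = 40, phase3_cost_per_treatment = 163,
      cost_per_participant = 200000, economies_factor = 0.8,
      return_per_success = 2500, phase2_effect_multiplier = 1,
      z_rounding = "two_decimals"),
    surface = list(alpha_values = c(0.01, 0.05, 0.10, 0.20, 0.30),
                   power_values = seq(0.50, 0.99, by = 0.01)),
    sweeps = list(cost_per_participant = seq(1e5, 4e5, by = 5e4),
                  p_eff = seq(0.05, 0.50, by = 0.05)),
    psa = list(enabled = TRUE, n_samples = 10000, portfolio_size = 100,
               portfolio = "expected")
  ), class = "run_config")
}

validate_keys <- function(x, allowed, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop(sprintf("unknown config key(s) at %s: %s", path,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

check_prob <- function(x, path) {
  if (!is.numeric(x) || length(x) != 1 || x <= 0 || x >= 1) {
    stop(sprintf("%s must be a probability strictly between 0 and 1 (got %s)",
                 path, deparse(x)), call. = FALSE)
  }
}

merge_stage <- function(base, ovr, path) {
  validate_keys(ovr, c("alpha", "power", "n_trials", "sidedness"), path)
  out <- utils::modifyList(base, ovr)
  check_prob(out$alpha, paste0(path, "$alpha"))
  check_prob(out$power, paste0(path, "$power"))
  out
}

#' Load (and validate) a run configuration from a YAML file
#'
#' The file may specify any subset of the fields of [default_config()];
#' missing fields take their default values, so an empty file yields the
#' full default configuration. Unknown keys and out-of-domain values are
#' rejected with the offending field path.
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  as_run_config(raw)
}

#' Coerce a plain list of overrides into a validated run configuration
#'
#' @param raw Named list of overrides (possibly empty).
#' @return A `run_config`.
#' @export
as_run_config <- function(raw = list()) {
  cfg <- unclass(default_config())
  validate_keys(raw, names(cfg), "config")

  if (!is.null(raw$seed)) {
    stopifnot(is.numeric(raw$seed), length(raw$seed) == 1)
    cfg$seed <- as.integer(raw$seed)
  }
  if (!is.null(raw$rounding)) {
    if (!raw$rounding %in% c("printed", "exact")) {
      stop("config$rounding must be 'printed' or 'exact'", call. = FALSE)
    }
    cfg$rounding <- raw$rounding
  }
  if (!is.null(raw$scenarios)) {
    cfg$scenarios <- lapply(seq_along(raw$scenarios), function(i) {
      s <- raw$scenarios[[i]]
      path <- sprintf("config$scenarios[[%d]]", i)
      validate_keys(s, c("name", "phase2", "phase3", "p_eff", "n_candidates"),
                    path)
      base <- unclass(default_config())$scenarios[[1]]
      out <- utils::modifyList(base, s[setdiff(names(s),
                                               c("phase2", "phase3"))])
      out$phase2 <- merge_stage(base$phase2, s$phase2 %||% list(),
                                paste0(path, "$phase2"))
      out$phase3 <- merge_stage(base$phase3, s$phase3 %||% list(),
                                paste0(path, "$phase3"))
      if (out$p_eff < 0 || out$p_eff > 1) {
        stop(paste0(path, "$p_eff must lie in [0, 1]"), call. = FALSE)
      }
      out
    })
    names(cfg$scenarios) <- vapply(cfg$scenarios, `[[`, "", "name")
  }
  if (!is.null(raw$cost_model)) {
    validate_keys(raw$cost_model, names(cfg$cost_model), "config$cost_model")
    cfg$cost_model <- utils::modifyList(cfg$cost_model, raw$cost_model)
  }
  if (!is.null(raw$surface)) {
    validate_keys(raw$surface, c("alpha_values", "power_values"),
                  "config$surface")
    cfg$surface <- utils::modifyList(cfg$surface, raw$surface)
  }
  if (!is.null(raw$sweeps)) {
    validate_keys(raw$sweeps, c("cost_per_participant", "p_eff"),
                  "config$sweeps")
    cfg$sweeps <- utils::modifyList(cfg$sweeps, raw$sweeps)
  }
  if (!is.null(raw$psa)) {
    validate_keys(raw$psa, names(cfg$psa), "config$psa")
    cfg$psa <- utils::modifyList(cfg$psa, raw$psa)
  }

  # exercise the constructors so domain violations surface here
  config_cost_model(structure(cfg, class = "run_config"))
  config_scenarios(structure(cfg, class = "run_config"))
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a run configuration to a YAML file
#'
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Materialise the scenario objects of a configuration
#' @param config A `run_config`.
#' @return Named list of [scenario()] objects.
#' @export
config_scenarios <- function(config) {
  out <- lapply(config$scenarios, function(s) {
    scenario(s$name,
             stage_design(s$phase2$alpha, s$phase2$power, s$phase2$n_trials,
                          s$phase2$sidedness),
             phase3 = stage_design(s$phase3$alpha, s$phase3$power,
                                   s$phase3$n_trials, s$phase3$sidedness),
             p_eff = s$p_eff, n_candidates = s$n_candidates)
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}

#' Materialise the cost model of a configuration
#' @param config A `run_config`.
#' @return A [cost_model()].
#' @export
config_cost_model <- function(config) {
  do.call(cost_model, config$cost_model)
}

#' Render the pipeline-passage table for a set of flows
#'
#' One row per (scenario, class) with entering/passing/failing counts at
#' each phase. In printed mode each expected count is rounded to one decimal
#' half-up — the convention of published pipeline tables (the status quo row
#' reads pass 12.5 / fail 12.5 / pass 3.8 / fail 71.3 at phase II); exact
#' mode shows full precision.
#'
#' @param flows List of [run_flow()] results (or a single one).
#' @param mode `"printed"` (default) or `"exact"`.
#' @return A data.frame with columns `scenario`, `class`, `enter_II`,
#'   `pass_II`, `fail_II`, `enter_III`, `pass_III`, `fail_III`.
#' @export
render_flow_table <- function(flows, mode = c("printed", "exact")) {
  mode <- match.arg(mode)
  if (inherits(flows, "flow_result")) flows <- list(flows)
  stopifnot(length(flows) >= 1)
  r <- if (mode == "printed") function(x) round_half_up(x, 1) else identity
  rows <- lapply(flows, function(fl) {
    stopifnot(inherits(fl, "flow_result"))
    scn <- attr(fl, "scenario")
    do.call(rbind, lapply(c("effective", "ineffective"), function(cl) {
      data.frame(
        scenario = scn$name, class = cl,
        enter_II = r(flow_cell(fl, cl, "II", "enter")),
        pass_II = r(flow_cell(fl, cl, "II", "pass")),
        fail_II = r(flow_cell(fl, cl, "II", "fail")),
        enter_III = r(flow_cell(fl, cl, "III", "enter")),
        pass_III = r(flow_cell(fl, cl, "III", "pass")),
        fail_III = r(flow_cell(fl, cl, "III", "fail")),
        stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Run the full analysis bundle and write it to disk
#'
#' Computes, for every configured scenario: the expected flow, outcome
#' classification, productivity metrics (with the first scenario as
#' baseline), and economics; then the profit surface over the configured
#' grid, the cost-per-participant and effective-proportion sweeps, and
#' (unless disabled) the probabilistic sensitivity analysis. Writes CSV
#' tables plus JSON summary and metadata (recording seed, rounding,
#' sidedness and economies conventions) under `out_dir`. Two runs with the
#' same configuration produce identical files.
#'
#' @param config A `run_config` (default [default_config()]).
#' @param out_dir Output directory (created if missing).
#' @return The result bundle, invisibly.
#' @export
run_all <- function(config = default_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)) {
    stop(sprintf("cannot create output directory '%s'", out_dir),
         call. = FALSE)
  }
  scns <- config_scenarios(config)
  cm <- config_cost_model(config)
  mode <- config$rounding

  flows <- lapply(scns, run_flow)
  econ <- mapply(function(scn, fl) profit(scn, cm, fl),
                 scns, flows, SIMPLIFY = FALSE)

  flow_tab <- render_flow_table(flows, mode = if (mode == "printed")
    "printed" else "exact")

  metric_tab <- do.call(rbind, lapply(names(flows), function(nm) {
    m <- productivity_metrics(flows[[nm]], baseline = flows[[1]],
                              mode = mode)
    data.frame(scenario = nm, as.data.frame(m), stringsAsFactors = FALSE)
  }))

  class_tab <- do.call(rbind, lapply(names(flows), function(nm) {
    cl <- classify_outcomes(flows[[nm]], mode = mode)
    data.frame(scenario = nm, as.data.frame(unclass(cl)),
               stringsAsFactors = FALSE)
  }))

  econ_tab <- do.call(rbind, lapply(names(econ), function(nm) {
    e <- econ[[nm]]
    data.frame(scenario = nm, cost_phase2 = e$cost_phase2,
               cost_phase3 = e$cost_phase3, total_cost = e$total_cost,
               expected_return = e$expected_return, profit = e$profit,
               stringsAsFactors = FALSE)
  }))

  surf <- profit_surface(search_grid(config$surface$alpha_values,
                                     config$surface$power_values,
                                     scns[[1]], cm))
  optimum <- find_optimum(surf)
  sweep_cost <- sweep_cost_per_participant(
    scns, config$sweeps$cost_per_participant, cm)
  sweep_p <- sweep_p_eff(scns, config$sweeps$p_eff, cm)

  psa <- NULL
  if (isTRUE(config$psa$enabled)) {
    spec <- psa_spec(n_samples = config$psa$n_samples,
                     portfolio_size = config$psa$portfolio_size,
                     seed = config$seed, scenarios = scns, cm = cm)
    psa <- run_psa(spec, portfolio = config$psa$portfolio)
  }

  wcsv <- function(x, name) utils::write.csv(
    x, file.path(out_dir, name), row.names = FALSE)
  wcsv(flow_tab, "flow.csv")
  wcsv(class_tab, "classification.csv")
  wcsv(metric_tab, "metrics.csv")
  wcsv(econ_tab, "economics.csv")
  wcsv(as.data.frame(surf), "profit_surface.csv")
  wcsv(sweep_cost, "sweep_cost_per_participant.csv")
  wcsv(sweep_p, "sweep_p_eff.csv")
  if (!is.null(psa)) {
    wcsv(cbind(psa$draws, as.data.frame(psa$profits)), "psa_draws.csv")
    wcsv(psa$summary, "psa_summary.csv")
    wcsv(psa$correlations, "psa_correlations.csv")
  }
  summary <- list(
    optimum = optimum,
    productivity_pct = stats::setNames(metric_tab$productivity_pct,
                                       metric_tab$scenario),
    profit = stats::setNames(econ_tab$profit, econ_tab$scenario)
  )
  metadata <- list(
    package = "trialflow",
    version = as.character(utils::packageVersion("trialflow")),
    seed = config$seed, rounding = mode,
    sidedness = scns[[1]]$phase2$sidedness,
    z_rounding = cm$z_rounding,
    economies_factor = cm$economies_factor,
    cost_sweep_convention = attr(sweep_cost, "convention"),
    psa_enabled = isTRUE(config$psa$enabled)
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(metadata, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(flows = flows, flow_table = flow_tab,
                 classification = class_tab, metrics = metric_tab,
                 economics = econ_tab, surface = surf, optimum = optimum,
                 sweep_cost = sweep_cost, sweep_p_eff = sweep_p, psa = psa,
                 metadata = metadata))
}
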