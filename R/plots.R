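#' Plot profit against phase II power, one curve per alpha
#'
#' @param surface A [profit_surface()].
#' @return A ggplot object.
#' @export
plot_profit_surface <- function(surface) {
  stopifnot(inherits(surface, "profit_surface"))
  require_ggplot()
  df <- as.data.frame(surface)
  df$alpha <- factor(df$alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$power, y = .data$profit,
                                   colour = .data$alpha)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Phase II power (per trial)", y = "Profit ($M)",
                  colour = "Phase II alpha")
}

#' Plot a one-dimensional profit sweep, one curve per scenario
#'
#' @param sweep Output of [sweep_cost_per_participant()] or [sweep_p_eff()].
#' @return A ggplot object.
#' @export
plot_sweep <- function(sweep) {
  require_ggplot()
  xvar <- intersect(c("cost_per_participant", "p_eff"), names(sweep))[1]
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data[[xvar]], y = .data$profit,
                                      colour = .data$scenario)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = xvar, y = "Profit ($M)", colour = NULL)
}

#' Plot the simulated profit distributions of a sensitivity analysis
#'
#' @param result A [run_psa()] result.
#' @return A ggplot object.
#' @export
plot_psa_profits <- function(result) {
  stopifnot(inherits(result, "psa_result"))
  require_ggplot()
  df <- utils::stack(as.data.frame(result$profits))
  names(df) <- c("profit", "scenario")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$profit,
                                   colour = .data$scenario)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "Profit ($M)", y = "Density", colour = NULL)
}

require_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}
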