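#' Efficiency-curve figure
#'
#' Fraction of the cohort flagged for screening against the sensitivity
#' achieved, one step curve per score, faceted by outcome.
#'
#' @param curves The `curves` tibble from [evaluate_all()].
#' @return A ggplot object.
#' @export
plot_efficiency_curves <- function(curves) {
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$sensitivity,
                               y = .data$fraction_screened,
                               colour = .data$score)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~outcome) +
    ggplot2::scale_x_continuous(labels = scales::percent) +
    ggplot2::scale_y_continuous(labels = scales::percent) +
    ggplot2::labs(x = "Sensitivity", y = "Proportion of cohort screened",
                  colour = "Score") +
    ggplot2::theme_bw()
}

#' Discrimination (AUC) grid figure
#'
#' AUC point estimates with 95% CI error bars per score, faceted by outcome
#' and infection subgroup.
#'
#' @param grid The `discrimination` tibble from [evaluate_all()].
#' @return A ggplot object.
#' @export
plot_discrimination <- function(grid) {
  d <- grid[grid$available, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$score, y = .data$auc)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::facet_grid(outcome ~ subgroup) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = NULL, y = "AUC (95% CI)") +
    ggplot2::theme_bw()
}

#' Workload-reduction scatter
#'
#' One point per stratum (e.g. hospital): the reduction in the proportion
#' screened at a matched-sensitivity threshold against the gain in
#' sensitivity at a matched-specificity threshold.
#'
#' @param workload Tibble with columns `stratum`, `delta_sensitivity`,
#'   `fewer_screened_fraction`.
#' @return A ggplot object.
#' @export
plot_workload_scatter <- function(workload) {
  ggplot2::ggplot(workload,
                  ggplot2::aes(x = .data$delta_sensitivity,
                               y = .data$fewer_screened_fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_x_continuous(labels = scales::percent) +
    ggplot2::scale_y_continuous(labels = scales::percent) +
    ggplot2::labs(x = "Increase in sensitivity (matched specificity)",
                  y = "Reduction in proportion screened (matched sensitivity)") +
    ggplot2::theme_bw()
}
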