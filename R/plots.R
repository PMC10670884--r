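# ggplot2 views of simulated outcomes and reports.

#' Stacked-bar stage distribution across regimens
#'
#' Absolute stage-at-diagnosis counts per 100,000 women for each regimen,
#' as a stacked bar chart (regimens ordered as given).
#'
#' @param outcomes Outcomes tibble from [compare_regimens()], or a stage
#'   table from [stage_table()] / [reference_stage_distribution()].
#' @return A ggplot object.
#' @export
plot_stage_distribution <- function(outcomes) {
  st <- if ("n_stage_0" %in% names(outcomes)) stage_table(outcomes)
        else tibble::as_tibble(outcomes)
  long <- tidyr::pivot_longer(
    st[, c("regimen", paste0("stage_", 0:4))],
    cols = -"regimen", names_to = "stage", names_prefix = "stage_",
    values_to = "count"
  )
  long$regimen <- factor(long$regimen, levels = unique(st$regimen))
  long$stage <- factor(long$stage, levels = rev(as.character(0:4)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$regimen, y = .data$count,
                                     fill = .data$stage)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "RdYlBu", direction = -1,
                               name = "Stage") +
    ggplot2::labs(x = NULL, y = "Cancers diagnosed per 100,000 women") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Mortality reduction by regimen
#'
#' Deaths averted per 1000 women versus the baseline, per regimen.
#'
#' @param report Report tibble from [build_report()].
#' @return A ggplot object.
#' @export
plot_mortality_reduction <- function(report) {
  report$regimen <- factor(report$regimen, levels = report$regimen)
  ggplot2::ggplot(report, ggplot2::aes(x = .data$regimen,
                                       y = .data$reduction_per_1000)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL,
                  y = sprintf("Deaths averted per 1000 women vs %s",
                              report$baseline[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @export
autoplot.mammosim_outcomes <- function(object, ...) {
  plot_stage_distribution(object)
}

#' @export
autoplot.mammosim_report <- function(object, ...) {
  plot_mortality_reduction(object)
}
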