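# broom-style views of outcome and report objects.

#' Tidy per-regimen outcomes
#'
#' One row per regimen and statistic: rates per 1000 women alive at the
#' window entry age (deaths, recalls, biopsies), screens per woman, and
#' stage counts per 100,000.
#'
#' @param x A `mammosim_outcomes` tibble.
#' @param ... Unused.
#' @return A long tibble `regimen`, `statistic`, `value`.
#' @export
tidy.mammosim_outcomes <- function(x, ...) {
  st <- stage_table(x)
  wide <- dplyr::left_join(.rates_from_outcomes(x), st, by = "regimen")
  tidyr::pivot_longer(wide, cols = -"regimen", names_to = "statistic",
                      values_to = "value")
}

#' Glance at per-regimen outcomes
#'
#' @param x A `mammosim_outcomes` tibble.
#' @param ... Unused.
#' @return One-row tibble: number of regimens, cohort size, women alive at
#'   entry, and the range of deaths per 1000 across regimens.
#' @export
glance.mammosim_outcomes <- function(x, ...) {
  d <- 1000 * x$bc_deaths_in_window / x$n_at_entry
  tibble::tibble(
    n_regimens = nrow(x),
    n_women = x$n_women[1],
    n_at_entry = x$n_at_entry[1],
    min_deaths_per_1000 = min(d),
    max_deaths_per_1000 = max(d)
  )
}

#' Tidy a comparison report
#'
#' @param x A `mammosim_report` tibble.
#' @param ... Unused.
#' @return A long tibble `regimen`, `statistic`, `value`.
#' @export
tidy.mammosim_report <- function(x, ...) {
  tidyr::pivot_longer(
    tibble::as_tibble(x)[, setdiff(names(x), c("baseline", "participation"))],
    cols = -"regimen", names_to = "statistic", values_to = "value"
  )
}

#' Glance at a comparison report
#'
#' @param x A `mammosim_report` tibble.
#' @param ... Unused.
#' @return One-row tibble: baseline label, participation, best regimen by
#'   mortality reduction and its reduction per 1000.
#' @export
glance.mammosim_report <- function(x, ...) {
  best <- which.max(x$reduction_per_1000)
  tibble::tibble(
    baseline = x$baseline[1],
    participation = x$participation[1],
    n_regimens = nrow(x),
    best_regimen = x$regimen[best],
    best_reduction_per_1000 = x$reduction_per_1000[best]
  )
}
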