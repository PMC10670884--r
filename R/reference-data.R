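# Published per-regimen outcome values reported for the OncoSim-Breast
# microsimulation of a 1975 Canadian birth cohort (1.53 million histories,
# outcomes tallied from ages 40 to 76). Shipped so the reporting arithmetic
# can be exercised on a real calibrated model's numbers, independent of this
# package's synthetic parameters.

#' Published reference outcomes per screening regimen
#'
#' A rate table in the printed-values input format of [build_report()]:
#' breast-cancer deaths per 1000 women alive at 40, life years saved per
#' 1000 women versus no screening, annual national (Canadian) deaths
#' averted, mean lifetime screens per woman, recalls among women without
#' cancer per 1000 women, and negative biopsies per 1000
#' women, as reported for the OncoSim-Breast model (Canadian Partnership
#' Against Cancer) under six screening regimens. Values are published
#' model output, not output of this package's simulator.
#'
#' @return Tibble with one row per regimen.
#' @examples
#' build_report(reference_outcomes())
#' @export
reference_outcomes <- function() {
  tibble::tribble(
    ~regimen, ~deaths_per_1000, ~ly_saved_per_1000, ~canada_annual_averted,
    ~screens_per_woman, ~recalls_per_1000, ~neg_biopsies_per_1000,
    "no_screening", 15.7, 0, NA, NA, NA, NA,
    "50-74 biennial", 11.1, 33.2, 1074, 11.6, 641, 57.1,
    "40-74 biennial", 9.7, 58.1, 1397, 16.3, 959, 85.3,
    "40-49 ann, 50-74 bi", 9.1, 68.3, 1538, 20.9, 1236, 110.0,
    "40-74 annual", 7.8, 78.9, 1862, 31.6, 1772, 157.7,
    "40-49 annual", 12.4, 44.8, 770, 9.3, 660, 58.8
  )
}

#' Published reference stage distributions per screening regimen
#'
#' Coarse stage-at-diagnosis counts per 100,000 women alive at 40 over 36
#' years of follow-up, with the published total and early-invasive (stage 1
#' or 2A) fraction, for the same six regimens as [reference_outcomes()].
#' Columns are ordered by scheduled lifetime screens.
#'
#' @return Tibble with one row per regimen: `stage_0` .. `stage_4`,
#'   `total`, `early_invasive_fraction`.
#' @export
reference_stage_distribution <- function() {
  tibble::tribble(
    ~regimen, ~stage_0, ~stage_1, ~stage_2, ~stage_3, ~stage_4, ~total,
    ~early_invasive_fraction,
    "no_screening", 403, 2019, 3641, 1417, 545, 8025, 0.54,
    "40-49 annual", 565, 2496, 3400, 1246, 469, 8176, 0.59,
    "50-74 biennial", 998, 4133, 2977, 878, 354, 9341, 0.72,
    "40-74 biennial", 1015, 4334, 2869, 790, 314, 9322, 0.74,
    "40-49 ann, 50-74 bi", 1042, 4526, 2768, 737, 294, 9367, 0.76,
    "40-74 annual", 1208, 5367, 2299, 503, 231, 9608, 0.82
  )
}
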