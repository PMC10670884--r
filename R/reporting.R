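# Reporting: every derived statistic used to compare screening regimens -
# mortality reductions, life years, NNS, national scalings, participation
# mixtures and stage tables - computable either from simulated outcomes or
# from a published per-regimen rate table.

#' Absolute mortality reduction per 1000 women
#'
#' @param baseline_deaths_per_1000 Deaths per 1000 women without screening.
#' @param regimen_deaths_per_1000 Deaths per 1000 women under the regimen.
#' @return `baseline - regimen`, deaths averted per 1000 women.
#' @examples
#' absolute_reduction(15.7, 11.1) # 4.6
#' @export
absolute_reduction <- function(baseline_deaths_per_1000,
                               regimen_deaths_per_1000) {
  if (any(baseline_deaths_per_1000 < 0) || any(regimen_deaths_per_1000 < 0)) {
    stop("death rates must be >= 0", call. = FALSE)
  }
  baseline_deaths_per_1000 - regimen_deaths_per_1000
}

#' Relative mortality reduction
#'
#' @param reduction_per_1000 Absolute reduction in deaths per 1000 women.
#' @param baseline_deaths_per_1000 Baseline deaths per 1000 women, `> 0`.
#' @return Percent reduction, `100 * reduction / baseline`.
#' @examples
#' relative_reduction(4.6, 15.7) # ~29.3
#' @export
relative_reduction <- function(reduction_per_1000,
                               baseline_deaths_per_1000) {
  if (any(baseline_deaths_per_1000 <= 0)) {
    stop("baseline must be > 0", call. = FALSE)
  }
  100 * reduction_per_1000 / baseline_deaths_per_1000
}

#' Participation-weighted mixture of outcomes
#'
#' Outcome offered to a partially participating population: the `p`-weighted
#' mixture of the fully screened and unscreened values (all-or-none lifetime
#' participation).
#'
#' @param screened_value Outcome under full participation.
#' @param unscreened_value Outcome with no screening.
#' @param p Participation fraction in \[0, 1\].
#' @return `p * screened + (1 - p) * unscreened`, same units as the inputs.
#' @examples
#' participation_weighted(7.9, 0, 0.7) # 5.53
#' @export
participation_weighted <- function(screened_value, unscreened_value, p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  p * screened_value + (1 - p) * unscreened_value
}

#' Scale a per-1000 reduction to a national annual count
#'
#' National annual deaths averted:
#' `reduction_per_1000 * women_per_cohort_year / 1000 * participation`,
#' rounded to the nearest integer. With `national_value` supplied the factor
#' is applied to an already-scaled national count instead (auxiliary mode,
#' e.g. applying a participation fraction or a cross-country population
#' ratio to a published national number).
#'
#' @param reduction_per_1000 Deaths averted per 1000 women, `>= 0`.
#' @param scale A [population_scale()] object.
#' @param participation Participation fraction.
#' @param national_value Optional already-scaled national count; when given,
#'   the result is `round(national_value * participation)`.
#' @return Annual deaths averted (integer-rounded).
#' @examples
#' scale_to_population(national_value = 1862, participation = 0.7) # 1303
#' @export
scale_to_population <- function(reduction_per_1000 = NULL,
                                scale = population_scale(),
                                participation = 1,
                                national_value = NULL) {
  stopifnot(participation >= 0)
  if (!is.null(national_value)) {
    return(round(national_value * participation))
  }
  if (any(reduction_per_1000 < 0)) {
    stop("reduction must be >= 0", call. = FALSE)
  }
  round(reduction_per_1000 * scale$women_per_cohort_year / 1000 *
          participation)
}

#' Population scaling constants
#'
#' The number of women entering the cohort each year used for national
#' scaling (default 235,820, a Canadian birth-cohort figure) and the
#' population ratio for transferring national counts to a larger country
#' (default 8.3, the US:Canada ratio).
#'
#' @param women_per_cohort_year Women turning the entry age each year.
#' @param us_multiplier Cross-country population ratio.
#' @return A list of class `mammosim_scale`.
#' @export
population_scale <- function(women_per_cohort_year = 235820,
                             us_multiplier = 8.3) {
  stopifnot(women_per_cohort_year > 0, us_multiplier > 0)
  structure(list(women_per_cohort_year = women_per_cohort_year,
                 us_multiplier = us_multiplier), class = "mammosim_scale")
}

#' Number needed to screen to avert one death
#'
#' @param reduction_per_1000 Deaths averted per 1000 women screened, `> 0`.
#' @return Women who must be screened per death averted,
#'   `1000 / reduction_per_1000`.
#' @examples
#' nns_per_death(7.9) # ~126.6
#' @export
nns_per_death <- function(reduction_per_1000) {
  if (any(reduction_per_1000 <= 0)) {
    stop("no benefit: NNS undefined for reduction <= 0", call. = FALSE)
  }
  1000 / reduction_per_1000
}

#' Number needed to screen per life year gained
#'
#' @param ly_saved_per_1000 Life years saved per 1000 women screened, `> 0`.
#' @return Women who must be screened per life year gained,
#'   `1000 / ly_saved_per_1000`.
#' @examples
#' nns_per_life_year(78.9) # ~12.7
#' @export
nns_per_life_year <- function(ly_saved_per_1000) {
  if (any(ly_saved_per_1000 <= 0)) {
    stop("no benefit: NNS undefined for ly <= 0", call. = FALSE)
  }
  1000 / ly_saved_per_1000
}

#' Mean life years gained per death averted
#'
#' @param ly_saved_per_1000 Life years saved per 1000 women.
#' @param reduction_per_1000 Deaths averted per 1000 women, `> 0`.
#' @return Mean years of life gained by each averted death.
#' @examples
#' mean_ly_per_death_averted(78.9, 7.9) # ~10
#' @export
mean_ly_per_death_averted <- function(ly_saved_per_1000,
                                      reduction_per_1000) {
  if (any(reduction_per_1000 <= 0)) {
    stop("reduction must be > 0", call. = FALSE)
  }
  ly_saved_per_1000 / reduction_per_1000
}

#' Stage-at-diagnosis table per 100,000 women
#'
#' Scales substage diagnosis counts to a cohort of `per` women alive at the
#' window entry age, reports coarse-stage counts, the total, and the
#' early-invasive fraction - the share of invasive cancers diagnosed at
#' stage 1 or 2A (computed from substages, which coarse tables merge).
#'
#' @param outcomes Outcomes tibble from [run_cohort()] /
#'   [compare_regimens()] (one or more rows).
#' @param per Reference cohort size (default 100,000).
#' @return Tibble with one row per regimen: `stage_0` .. `stage_4` scaled
#'   counts, `total`, and `early_invasive_fraction`.
#' @export
stage_table <- function(outcomes, per = 100000) {
  sc <- per / outcomes$n_at_entry
  inv <- outcomes$n_stage_1 + outcomes$n_stage_2a + outcomes$n_stage_2b +
    outcomes$n_stage_3 + outcomes$n_stage_4
  tibble::tibble(
    regimen = outcomes$regimen,
    stage_0 = outcomes$n_stage_0 * sc,
    stage_1 = outcomes$n_stage_1 * sc,
    stage_2 = (outcomes$n_stage_2a + outcomes$n_stage_2b) * sc,
    stage_3 = outcomes$n_stage_3 * sc,
    stage_4 = outcomes$n_stage_4 * sc,
    total = outcomes$total_cancers * sc,
    early_invasive_fraction = ifelse(
      inv > 0, (outcomes$n_stage_1 + outcomes$n_stage_2a) / inv, NA_real_
    )
  )
}

#' Totals of a printed stage-distribution column
#'
#' Sums coarse stage counts (per 100,000 women) into total cancers; used in
#' printed-values mode where only the published stage rows are available.
#'
#' @param stage_counts Numeric vector of coarse-stage counts (stages 0-4).
#' @return Total cancers.
#' @examples
#' stage_column_total(c(403, 2019, 3641, 1417, 545)) # 8025
#' @export
stage_column_total <- function(stage_counts) {
  stopifnot(length(stage_counts) == 5, all(stage_counts >= 0))
  sum(stage_counts)
}

#' Build a regimen comparison report
#'
#' Turns per-regimen outcomes into every derived comparison statistic,
#' against a named baseline regimen. Two input modes share one code path:
#'
#' * **simulated mode** - an outcomes tibble from [compare_regimens()] /
#'   [run_cohort()]; rates are computed from counts per 1000 women alive at
#'   the window entry age;
#' * **printed-values mode** - a rate table (e.g.
#'   [reference_outcomes()]) that already carries `deaths_per_1000`,
#'   `ly_saved_per_1000`, `screens_per_woman`, `recalls_per_1000`,
#'   `neg_biopsies_per_1000`, so the comparison arithmetic of a published
#'   analysis is reproduced exactly, independent of this package's synthetic
#'   calibration.
#'
#' With `participation < 1`, per-offered quantities (deaths, reductions,
#' national counts, screens, recalls, biopsies) are `p`-weighted against the
#' baseline while per-actually-screened quantities (NNS, life years saved
#' per 1000 screened) are left unchanged - participation dilutes the offer,
#' not the benefit to attenders.
#'
#' @param outcomes Simulated outcomes tibble or printed rate table.
#' @param baseline Regimen label of the no-screening baseline.
#' @param scale A [population_scale()].
#' @param participation Participation fraction applied at the report level.
#' @param life_years For simulated outcomes, `"window"` (horizon-truncated,
#'   default) or `"lifetime"` accounting.
#' @return Tibble of class `mammosim_report`, one row per non-baseline
#'   regimen: `deaths_per_1000`, `reduction_per_1000`, `relative_reduction`,
#'   `ly_saved_per_1000`, `national_annual_averted`, `nns_per_death`,
#'   `nns_per_ly`, `screens_per_woman`, `recalls_per_1000`,
#'   `neg_biopsies_per_1000`.
#' @examples
#' build_report(reference_outcomes())
#' @export
build_report <- function(outcomes, baseline = "no_screening",
                         scale = population_scale(), participation = 1,
                         life_years = c("window", "lifetime")) {
  life_years <- match.arg(life_years)
  rates <- if ("deaths_per_1000" %in% names(outcomes)) {
    tibble::as_tibble(outcomes)
  } else {
    .rates_from_outcomes(outcomes, life_years)
  }
  if (!baseline %in% rates$regimen) {
    stop("baseline regimen '", baseline, "' not found", call. = FALSE)
  }
  if (!"ly_saved_per_1000" %in% names(rates)) {
    base_ly <- rates$ly_per_woman[rates$regimen == baseline]
    rates$ly_saved_per_1000 <- 1000 * (rates$ly_per_woman - base_ly)
  }
  base <- rates[rates$regimen == baseline, ]
  reg <- rates[rates$regimen != baseline, ]
  p <- participation

  red_full <- absolute_reduction(base$deaths_per_1000, reg$deaths_per_1000)
  red <- participation_weighted(red_full, 0, p)
  deaths <- participation_weighted(reg$deaths_per_1000, base$deaths_per_1000,
                                   p)
  out <- tibble::tibble(
    regimen = reg$regimen,
    baseline = baseline,
    participation = p,
    deaths_per_1000 = deaths,
    reduction_per_1000 = red,
    relative_reduction = relative_reduction(red, base$deaths_per_1000),
    ly_saved_per_1000 = reg$ly_saved_per_1000,
    national_annual_averted = scale_to_population(pmax(red_full, 0), scale, p),
    nns_per_death = ifelse(red_full > 0, 1000 / red_full, NA_real_),
    nns_per_ly = ifelse(reg$ly_saved_per_1000 > 0,
                        1000 / reg$ly_saved_per_1000, NA_real_),
    screens_per_woman = p * reg$screens_per_woman,
    recalls_per_1000 = p * reg$recalls_per_1000,
    neg_biopsies_per_1000 = p * reg$neg_biopsies_per_1000
  )
  structure(out, class = c("mammosim_report", class(out)))
}

# per-1000 rates from simulated outcome counts
.rates_from_outcomes <- function(outcomes, life_years = "window") {
  ly <- if (life_years == "lifetime") outcomes$ly_lifetime
        else outcomes$ly_window
  n <- outcomes$n_at_entry
  tibble::tibble(
    regimen = outcomes$regimen,
    deaths_per_1000 = 1000 * outcomes$bc_deaths_in_window / n,
    ly_per_woman = ly / n,
    screens_per_woman = outcomes$total_screens / n,
    recalls_per_1000 = 1000 * outcomes$fp_recalls / n,
    neg_biopsies_per_1000 = 1000 * outcomes$neg_biopsies / n
  )
}
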