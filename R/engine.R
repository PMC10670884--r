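# Cohort engine: per-woman life histories under a regimen, aggregated into
# per-regimen outcomes. Natural history is shared across regimens (common
# random numbers); only screen-related draws differ.

#' Simulate per-woman life histories under a screening regimen
#'
#' Runs the full pipeline - onset, growth, spread, surfacing, screening,
#' diagnosis, survival, competing mortality - for `n_women` women and returns
#' one row per woman. All randomness comes from counter-based streams keyed
#' by `(seed, purpose, year/age, woman_id)`, so the natural history of woman
#' `i` is identical under every regimen and across any partition of the
#' cohort; only screening draws (keyed by screen age) differ between
#' regimens.
#'
#' @param params Parameter set from [make_default_params()] or
#'   [read_params()].
#' @param regimen A [regimen()] object.
#' @param n_women Number of women to simulate.
#' @param seed Integer master seed (defaults to `params$seed`).
#' @param woman_ids Optional explicit 0-based woman ids (overrides
#'   `n_women`).
#' @return A tibble with one row per woman: natural-history fields
#'   (`other_death_age`, `onset_age`, `starts_insitu`, `subtype`, `gamma`,
#'   `invasive_age`, `nodal_age`, `distant_age`, `surfacing_age`; ages are
#'   `Inf` when the event never happens), screening fields
#'   (`attends_screening`, `n_screens`, `n_fp_recalls`, `n_neg_biopsies`),
#'   detection (`mode`, `age_at_dx`, `stage_at_dx`, `diameter_at_dx`) and
#'   death (`bc_death_age`, `age_at_death`, `cause`).
#' @examples
#' p <- make_default_params(1)
#' h <- simulate_histories(p, regimen("50-74 biennial", 50, 74, 2), 500)
#' dplyr::count(h, mode)
#' @export
simulate_histories <- function(params, regimen, n_women, seed = params$seed,
                               woman_ids = NULL) {
  validate_params(params)
  if (is.null(woman_ids)) {
    stopifnot(n_women >= 1)
    woman_ids <- 0:(n_women - 1)
  }
  woman_ids <- as.integer(woman_ids)
  nh <- .natural_history(params, woman_ids, seed)
  .apply_regimen(nh, params, regimen, seed)
}

#' Simulate a single woman's life history
#'
#' Convenience wrapper: [simulate_histories()] for one `woman_id`. Because
#' draws are counter-based, the returned row is identical to the
#' corresponding row of any cohort run with the same seed.
#'
#' @inheritParams simulate_histories
#' @param woman_id 0-based woman index.
#' @return One-row life-history tibble.
#' @export
run_history <- function(params, regimen, woman_id = 0, seed = params$seed) {
  simulate_histories(params, regimen, seed = seed, woman_ids = woman_id)
}

#' Aggregate life histories into per-regimen cohort outcomes
#'
#' Tallies a history table over a reporting window (default ages 40 to 76,
#' emulating follow-up truncation at a fixed calendar year): breast-cancer
#' deaths with `age_at_death` inside the window, diagnoses with `age_at_dx`
#' inside the window by substage, lifetime screens / false-positive recalls /
#' negative biopsies, and life years both truncated at the horizon and over
#' the full lifetime. Denominators use women alive at the window entry age.
#'
#' @param histories A history tibble from [simulate_histories()].
#' @param window Numeric `c(entry_age, horizon_age)`, default `c(40, 76)`.
#' @param name Regimen label to attach.
#' @return One-row tibble of class `mammosim_outcomes`: `n_women`,
#'   `n_at_entry`, `bc_deaths_in_window`, `total_cancers`, substage counts
#'   (`n_stage_0`, `n_stage_1`, `n_stage_2a`, `n_stage_2b`, `n_stage_3`,
#'   `n_stage_4`), `total_screens`, `fp_recalls`, `neg_biopsies`,
#'   `ly_window`, `ly_lifetime`.
#' @export
summarize_cohort <- function(histories, window = c(40, 76),
                             name = "cohort") {
  stopifnot(length(window) == 2, window[1] < window[2])
  entry <- window[1]
  horizon <- window[2]
  at_entry <- histories$age_at_death >= entry
  dx <- !is.na(histories$age_at_dx) & histories$age_at_dx >= entry &
    histories$age_at_dx <= horizon
  stg <- table(histories$stage_at_dx[dx])
  death_age <- histories$age_at_death[at_entry]
  tibble::tibble(
    regimen = name,
    n_women = nrow(histories),
    n_at_entry = sum(at_entry),
    bc_deaths_in_window = sum(
      histories$cause == "breast_cancer" & at_entry &
        histories$age_at_death <= horizon
    ),
    total_cancers = sum(dx),
    n_stage_0 = unname(stg["0"]),
    n_stage_1 = unname(stg["1"]),
    n_stage_2a = unname(stg["2A"]),
    n_stage_2b = unname(stg["2B"]),
    n_stage_3 = unname(stg["3"]),
    n_stage_4 = unname(stg["4"]),
    total_screens = sum(histories$n_screens),
    fp_recalls = sum(histories$n_fp_recalls),
    neg_biopsies = sum(histories$n_neg_biopsies),
    ly_window = sum(pmin(death_age, horizon) - entry),
    ly_lifetime = sum(death_age - entry)
  ) |>
    structure(class = c("mammosim_outcomes", "tbl_df", "tbl", "data.frame"))
}

#' Run one regimen end to end
#'
#' [simulate_histories()] followed by [summarize_cohort()]; deterministic for
#' fixed `(params, regimen, n_women, seed)`.
#'
#' @inheritParams simulate_histories
#' @inheritParams summarize_cohort
#' @return One-row outcomes tibble (see [summarize_cohort()]).
#' @export
run_cohort <- function(params, regimen, n_women, seed = params$seed,
                       window = c(40, 76)) {
  simulate_histories(params, regimen, n_women, seed = seed) |>
    summarize_cohort(window = window, name = regimen$name)
}

#' Compare screening regimens on one simulated cohort
#'
#' Simulates the cohort's natural history once and applies each regimen to
#' it (common random numbers), returning one outcomes row per regimen. This
#' is the design that makes between-regimen differences low variance and the
#' stage-shift orderings exact per woman.
#'
#' @inheritParams simulate_histories
#' @param regimens Named list of [regimen()] objects (e.g.
#'   [default_regimens()]).
#' @param keep_histories If `TRUE`, attach the per-regimen history tables as
#'   attribute `"histories"`.
#' @inheritParams summarize_cohort
#' @return Outcomes tibble with one row per regimen, in input order.
#' @examples
#' p <- make_default_params(1)
#' compare_regimens(p, default_regimens()[c(1, 3)], n_women = 2000)
#' @export
compare_regimens <- function(params, regimens, n_women, seed = params$seed,
                             window = c(40, 76), keep_histories = FALSE) {
  validate_params(params)
  stopifnot(n_women >= 1, length(regimens) >= 1)
  nh <- .natural_history(params, 0:(n_women - 1), seed)
  hist_list <- purrr::map(regimens, ~ .apply_regimen(nh, params, .x, seed))
  out <- purrr::imap(hist_list, function(h, nm) {
    summarize_cohort(h, window = window,
                     name = if (is.null(regimens[[nm]]$name)) nm
                            else regimens[[nm]]$name)
  }) |>
    purrr::list_rbind()
  out <- structure(out, class = c("mammosim_outcomes", class(tibble::tibble())))
  if (keep_histories) attr(out, "histories") <- hist_list
  out
}
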