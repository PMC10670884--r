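# Reporting arithmetic: reductions, NNS, participation, scaling, stage tables.

test_that("absolute and relative reductions reproduce published arithmetic", {
  expect_equal(absolute_reduction(15.7, 11.1), 4.6)
  expect_equal(absolute_reduction(11.1, 9.7), 1.4)
  expect_equal(absolute_reduction(9.1, 9.1), 0)
  expect_error(absolute_reduction(-1, 0), ">= 0")
  expect_equal(relative_reduction(0, 15.7), 0)
  # printed value 29.10% comes from unrounded model output; rounded-input
  # arithmetic agrees within half a percentage point
  expect_lt(abs(relative_reduction(4.6, 15.7) - 29.10), 0.5)
  expect_equal(relative_reduction(2.3, 7.85), relative_reduction(4.6, 15.7))
  expect_error(relative_reduction(4.6, 0), "> 0")
})

test_that("participation weighting and national scaling match worked examples", {
  expect_equal(participation_weighted(7.9, 0, 0.7), 5.53)
  expect_equal(participation_weighted(7.9, 1, 1), 7.9)
  expect_equal(participation_weighted(7.9, 1.23, 0), 1.23)
  expect_error(participation_weighted(1, 0, 1.1), "\\[0, 1\\]")
  expect_equal(scale_to_population(national_value = 1862,
                                   participation = 0.7), 1303)
  expect_equal(scale_to_population(national_value = 1862 - 1074), 788)
  expect_equal(scale_to_population(0), 0)
  # per-1000 mode: 7.9/1000 of 235,820 women per cohort year
  expect_equal(scale_to_population(7.9), round(7.9 * 235.820))
  # cross-country transfer by population ratio
  expect_equal(population_scale()$us_multiplier, 8.3)
})

test_that("number needed to screen obeys its identities and printed values", {
  expect_equal(nns_per_death(1000), 1)
  set.seed(3)
  r <- stats::runif(20, 0.5, 20)
  expect_equal(nns_per_death(r) * r, rep(1000, 20))
  expect_lt(abs(nns_per_death(7.9) - 126.7), 0.2)
  expect_equal(round(nns_per_life_year(58.1), 1), 17.2)
  expect_equal(round(nns_per_life_year(78.9), 1), 12.7)
  expect_equal(nns_per_life_year(1000), 1)
  expect_error(nns_per_death(0), "undefined")
  expect_error(nns_per_life_year(-1), "undefined")
})

test_that("life years per averted death reproduce the worked comparisons", {
  expect_equal(round(mean_ly_per_death_averted(78.9, 7.9)), 10)
  expect_equal(mean_ly_per_death_averted(5, 5), 1)
  expect_equal(round(58.1 / 33.2, 2), 1.75) # fold gain, start at 40 vs 50
  expect_error(mean_ly_per_death_averted(10, 0), "> 0")
})

test_that("stage tables sum and scale correctly", {
  ref <- reference_stage_distribution()
  totals <- apply(ref[, paste0("stage_", 0:4)], 1, stage_column_total)
  # published totals round to within one cancer of the printed stage rows
  expect_true(all(abs(totals - ref$total) <= 1))
  expect_equal(unname(totals[ref$regimen == "no_screening"]), 8025)
  expect_equal(unname(totals[ref$regimen == "40-74 annual"]), 9608)
  # simulated mode: per-100k scaling, totals and early-invasive fraction
  p <- make_default_params(1)
  out <- compare_regimens(p, default_regimens()[c("no_screening",
                                                  "biennial_50_74")], 4000)
  st <- stage_table(out)
  expect_equal(st$stage_0 + st$stage_1 + st$stage_2 + st$stage_3 + st$stage_4,
               st$total)
  expect_equal(st$total, out$total_cancers * 1e5 / out$n_at_entry)
  expect_true(all(st$early_invasive_fraction >= 0 &
                    st$early_invasive_fraction <= 1))
  # empty cohort: all zeros
  empty <- summarize_cohort(simulate_histories(
    trace_params(onset_age = 45), no_screening(), 5
  ))
  empty$n_at_entry <- 5 # immortal table: everyone reaches entry
  st0 <- stage_table(empty)
  expect_equal(st0$stage_4, 0)
})

test_that("build_report composes the printed-values mode exactly", {
  rep <- build_report(reference_outcomes())
  r5074 <- rep[rep$regimen == "50-74 biennial", ]
  expect_equal(r5074$reduction_per_1000, 4.6)
  expect_lt(abs(r5074$relative_reduction - 29.10), 0.5)
  rann <- rep[rep$regimen == "40-74 annual", ]
  expect_equal(rann$reduction_per_1000, 7.9)
  expect_lt(abs(rann$nns_per_death - 126.7), 0.2)
  expect_equal(round(rann$nns_per_ly, 1), 12.7)
  expect_equal(rann$national_annual_averted, round(7.9 * 235.820))
  expect_error(build_report(reference_outcomes(), baseline = "nope"),
               "not found")
})

test_that("participation enters the report linearly and spares NNS", {
  full <- build_report(reference_outcomes())
  part <- build_report(reference_outcomes(), participation = 0.7)
  expect_equal(part$reduction_per_1000, 0.7 * full$reduction_per_1000)
  expect_equal(part$recalls_per_1000, 0.7 * full$recalls_per_1000)
  expect_equal(part$screens_per_woman, 0.7 * full$screens_per_woman)
  # the worked example: 7.9 -> 5.5 per 1000 offered, 1862 -> 1303 nationally
  rann <- part[part$regimen == "40-74 annual", ]
  expect_equal(round(rann$reduction_per_1000, 1), 5.5)
  expect_equal(rann$national_annual_averted,
               round(0.7 * round(7.9 * 235.820)))
  # benefits to those actually screened are untouched by participation
  expect_equal(part$nns_per_death, full$nns_per_death)
  expect_equal(part$nns_per_ly, full$nns_per_ly)
  expect_equal(part$ly_saved_per_1000, full$ly_saved_per_1000)
  # weighting then differencing equals differencing then weighting
  expect_equal(
    participation_weighted(15.7, 0, 0.7) - participation_weighted(11.1, 0, 0.7),
    0.7 * (15.7 - 11.1)
  )
})

test_that("simulated-mode reports are deterministic and self-consistent", {
  p <- make_default_params(1)
  out <- compare_regimens(p, default_regimens()[c(1, 3, 6)], 5000)
  rep1 <- build_report(out)
  rep2 <- build_report(compare_regimens(p, default_regimens()[c(1, 3, 6)],
                                        5000))
  expect_identical(rep1, rep2)
  expect_equal(rep1$nns_per_death * rep1$reduction_per_1000,
               rep(1000, nrow(rep1)))
  # participation 1 leaves the report unadjusted
  expect_identical(build_report(out, participation = 1), rep1)
})

test_that("tidy, glance and autoplot views are well formed", {
  p <- make_default_params(1)
  out <- compare_regimens(p, default_regimens()[c(1, 3)], 3000)
  td <- tidy(out)
  expect_true(all(c("regimen", "statistic", "value") %in% names(td)))
  expect_equal(nrow(glance(out)), 1)
  rep <- build_report(out)
  expect_s3_class(autoplot(out), "ggplot")
  expect_s3_class(autoplot(rep), "ggplot")
  expect_s3_class(plot_stage_distribution(reference_stage_distribution()),
                  "ggplot")
  expect_equal(nrow(glance(rep)), 1)
})
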