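# Screening schedules, sensitivity, surfacing, recalls and biopsies.

test_that("scheduled screen ages enumerate regimen phases", {
  expect_length(scheduled_screen_ages(regimen("bi", 50, 74, 2)), 13)
  expect_length(scheduled_screen_ages(regimen("ann", 40, 74, 1)), 35)
  # ten scheduled screens in the 40s, consistent with a reported mean
  # lifetime screen count of 9.3 for that regimen
  expect_equal(scheduled_screen_ages(regimen("ann49", 40, 49, 1)), 40:49)
  expect_length(scheduled_screen_ages(no_screening()), 0)
  hybrid <- default_regimens()$hybrid_40_74
  expect_equal(scheduled_screen_ages(hybrid),
               sort(unique(c(40:49, seq(50, 74, 2)))))
  # nested screen sets: every biennial 40-74 screen age is a hybrid age
  expect_true(all(scheduled_screen_ages(regimen("bi", 40, 74, 2)) %in%
                    scheduled_screen_ages(hybrid)))
  expect_error(regimen("bad", 60, 50, 2), "start_age")
  expect_error(regimen("bad", 40, 74, 0), "interval")
})

test_that("sensitivity is logistic in diameter", {
  s <- list(smax = 0.95, d50 = 10, k = 0.4, insitu = 0.5)
  expect_equal(screening_sensitivity(10, s), 0.95 / 2) # midpoint
  expect_equal(screening_sensitivity(1e6, s), 0.95) # asymptote
  expect_equal(screening_sensitivity(15, s),
               0.95 / (1 + exp(-2))) # independent scalar evaluation
  d <- seq(0, 100, by = 0.5)
  expect_true(all(diff(screening_sensitivity(d, s)) >= 0))
  expect_true(all(screening_sensitivity(d, s) <= 0.95))
  expect_error(screening_sensitivity(-1, s), ">= 0")
})

test_that("clinical surfacing follows the cumulative diameter hazard", {
  p <- trace_params(c0 = 0, gamma = 0.3)
  expect_identical(clinical_surfacing_age(45, 0.3, p, 0.5), Inf) # zero hazard
  p <- trace_params(c0 = 1000, gamma = 0.3)
  expect_equal(clinical_surfacing_age(45, 0.3, p, 0.5), 45) # saturation
})

test_that("surfacing delay for a constant-diameter tumor is geometric", {
  # d = d0 = dref so the yearly hazard is exactly c0
  p <- trace_params(onset_age = 20, gamma = 1e-12, c0 = 0.3, dref = 2)
  h <- simulate_histories(p, no_screening(), 50000)
  waits <- (h$surfacing_age - h$invasive_age)[is.finite(h$surfacing_age)]
  expect_geometric(waits, prob = 1 - exp(-0.3), from = 0)
})

test_that("screen visits detect, recall and biopsy per the decision rule", {
  p <- make_default_params(1)
  state <- list(has_cancer = FALSE, insitu = FALSE, diameter = NA,
                n_screens = 0L, n_fp_recalls = 0L, n_neg_biopsies = 0L)
  # no cancer, fp rate zero: a screen but no recall and no biopsy
  p0 <- p
  p0$fp_recall_rate <- 0
  out <- screen_event(state, p0, u_fp = 1e-9, u_biopsy = 1e-9)
  expect_equal(out$n_screens, 1L)
  expect_equal(out$n_fp_recalls, 0L)
  expect_equal(out$n_neg_biopsies, 0L)
  # recall and biopsy both triggered by small uniforms
  out <- screen_event(state, p, u_fp = 0.01, u_biopsy = 0.01)
  expect_equal(out$n_fp_recalls, 1L)
  expect_equal(out$n_neg_biopsies, 1L)
  # cancer present with saturated sensitivity: detected, no recall counted
  state$has_cancer <- TRUE
  state$diameter <- 50
  out <- screen_event(state, p, u_detect = 0.94)
  expect_true(out$detected)
  expect_equal(out$n_fp_recalls, 0L)
})

test_that("forced detection happens at the first attended screen", {
  # sensitivity 1 from diameter 0 on: detected at the first screen at or
  # after onset (age 46 for onset just past 45 under biennial 40-74)
  p <- trace_params(onset_age = 45, gamma = 0.5, smax = 1, d50 = -100, k = 1)
  h <- simulate_histories(p, regimen("bi", 40, 74, 2), 300)
  expect_true(all(h$mode == "screen"))
  expect_true(all(h$age_at_dx == 46))
  expect_true(all(h$n_screens == 4)) # 40, 42, 44, 46 then diagnosis
})

test_that("recall and biopsy counts follow the binomial expectation", {
  # no cancers ever: recalls are Binomial(13 screens, 0.055) per woman
  p <- make_default_params(1)
  p$onset_hazard <- rep(0, 110)
  p$life_table <- immortal_life_table()
  n <- 100000
  out <- run_cohort(p, regimen("bi", 50, 74, 2), n)
  recalls_per_woman <- out$fp_recalls / n
  expect_equal(out$total_screens, 13 * n)
  se_r <- sqrt(13 * 0.055 * 0.945 / n)
  expect_lt(abs(recalls_per_woman - 13 * 0.055), 3 * se_r)
  biopsies_per_woman <- out$neg_biopsies / n
  pb <- 0.055 * 0.09
  se_b <- sqrt(13 * pb * (1 - pb) / n)
  expect_lt(abs(biopsies_per_woman - 13 * pb), 3 * se_b)
  # no-screening regimen: no recalls, no biopsies at all
  out0 <- run_cohort(p, no_screening(), 1000)
  expect_equal(out0$fp_recalls, 0)
  expect_equal(out0$neg_biopsies, 0)
  expect_equal(out0$total_screens, 0)
})
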