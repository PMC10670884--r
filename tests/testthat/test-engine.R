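# Cohort engine: common random numbers, determinism, hand-traced histories,
# conservation and Monte-Carlo error structure.

test_that("zero-sensitivity screening reproduces no screening field for field", {
  p <- make_default_params(1)
  p$sensitivity$smax <- 0
  p$sensitivity$insitu <- 0
  p$fp_recall_rate <- 0
  h0 <- simulate_histories(p, no_screening(), 3000)
  h1 <- simulate_histories(p, regimen("ann", 40, 74, 1), 3000)
  # everything except the screen counter must be identical
  cols <- setdiff(names(h0), "n_screens")
  expect_identical(h0[cols], h1[cols])
  expect_true(all(h1$n_fp_recalls == 0))
})

test_that("cohort runs are deterministic and order-independent", {
  p <- make_default_params(1)
  reg <- regimen("bi", 50, 74, 2)
  out1 <- run_cohort(p, reg, 2000)
  out2 <- run_cohort(p, reg, 2000)
  expect_identical(out1, out2)
  # a single woman's history equals her row in the cohort run
  h <- simulate_histories(p, reg, 2000)
  expect_identical(run_history(p, reg, woman_id = 1234),
                   h[h$woman_id == 1234, ])
})

test_that("a scripted deterministic history matches the hand-computed trace", {
  # onset forced just past 45, fixed growth 0.5/yr, no spread, certain
  # clinical surfacing two years in, perfect screens
  p <- trace_params(onset_age = 45, gamma = 0.5, c0 = 0.12, dref = 15,
                    smax = 1, d50 = -100, k = 1)
  w <- 17
  e_onset <- -log(rng_uniform(1, w, "onset"))
  onset <- 45 + e_onset / 1000
  # surfacing: cumulative hazard 0.12/15 * d(j) crosses -log(u_surf)
  d_at <- function(j) 128 * (2 / 128)^exp(-0.5 * j)
  thr <- -log(rng_uniform(1, w, "surfacing"))
  cum <- 0
  j <- 0
  while (cum + 0.12 * d_at(j) / 15 <= thr) {
    cum <- cum + 0.12 * d_at(j) / 15
    j <- j + 1
  }
  h0 <- run_history(p, no_screening(), woman_id = w)
  expect_equal(h0$onset_age, onset)
  expect_equal(h0$surfacing_age, onset + j)
  expect_equal(h0$age_at_dx, onset + j)
  expect_equal(h0$mode, "clinical")
  expect_equal(h0$diameter_at_dx, d_at(j))
  # under annual screening the same tumor is found at the first screen
  # after onset, at the year-1 diameter, stage 1 (no spread, small tumor)
  h1 <- run_history(p, regimen("ann", 40, 74, 1), woman_id = w)
  expect_equal(h1$age_at_dx, 46)
  expect_equal(h1$mode, "screen")
  expect_equal(h1$diameter_at_dx, 128 * (2 / 128)^exp(-0.5 * (46 - onset)))
  expect_equal(as.character(h1$stage_at_dx), "1")
  # survival draws: same anchor (the surfacing age) in both scenarios
  uc <- rng_uniform(1, w, "cure")
  ut <- rng_uniform(1, w, "surv_time")
  surv <- p$survival
  for (h in list(h0, h1)) {
    stg <- as.character(h$stage_at_dx)
    expected <- if (uc < surv$cure[surv$stage == stg]) NA_real_ else {
      h0$surfacing_age - log(ut) / surv$rate[surv$stage == stg]
    }
    expect_equal(h$bc_death_age, expected)
  }
})

test_that("forced in situ transitions land exactly one year after onset", {
  p <- trace_params(onset_age = 45, insitu_fraction = 1,
                    insitu_progression_prob = 1)
  h <- simulate_histories(p, no_screening(), 500)
  expect_true(all(h$starts_insitu))
  expect_equal(h$invasive_age, h$onset_age + 1)
})

test_that("women without onset contribute no cancers and every woman dies once", {
  p <- make_default_params(1)
  p$onset_hazard <- rep(0, 110)
  out <- run_cohort(p, regimen("bi", 50, 74, 2), 5000)
  expect_equal(out$total_cancers, 0)
  expect_equal(out$bc_deaths_in_window, 0)
  h <- simulate_histories(make_default_params(1), regimen("bi", 50, 74, 2),
                          5000)
  expect_true(all(!is.na(h$age_at_death)))
  expect_true(all(h$age_at_death <= 109))
  expect_true(all(h$cause %in% c("breast_cancer", "other")))
  # life years inside the window can never exceed its width
  out2 <- summarize_cohort(h)
  expect_lte(out2$ly_window, out2$n_at_entry * 36)
})

test_that("all-or-none participation is an exact mixture of attend / ignore", {
  p <- make_default_params(1)
  n <- 5000
  full <- simulate_histories(p, regimen("ann", 40, 74, 1), n)
  none <- simulate_histories(p, no_screening(), n)
  part <- simulate_histories(p, regimen("ann", 40, 74, 1, participation = 0.7),
                             n)
  att <- part$attends_screening
  expect_lt(abs(mean(att) - 0.7), 3 * sqrt(0.21 / n))
  cols <- setdiff(names(part), "attends_screening")
  expect_identical(part[att, cols], full[att, cols])
  expect_identical(part[!att, cols], none[!att, cols])
})

test_that("batched cohorts reproduce the pooled Monte-Carlo error scale", {
  p <- make_default_params(1)
  reg <- regimen("bi", 50, 74, 2)
  h <- simulate_histories(p, reg, 100000)
  batch <- floor(h$woman_id / 10000)
  cancers <- sapply(split(h, batch), function(b) {
    summarize_cohort(b)$total_cancers
  })
  se_batch <- stats::sd(cancers) / sqrt(10) # batch-means SE of the total / 10
  pooled <- sum(cancers)
  # binomial SE of the pooled total, scaled to a batch-of-10 mean
  se_pool <- sqrt(pooled * (1 - pooled / 100000)) / 10
  expect_lt(se_batch / se_pool, 1.5)
  expect_gt(se_batch / se_pool, 1 / 1.5)
})
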