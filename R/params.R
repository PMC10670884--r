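# Parameter sets: the synthetic stand-in for a calibrated natural-history
# model. Everything downstream reads from this one validated structure.

.stage_levels <- c("0", "1", "2A", "2B", "3", "4")

#' Default synthetic parameter set
#'
#' Returns a fully populated, validated parameter set describing the cohort's
#' natural history, detection and survival model. The values are synthetic
#' defaults chosen to emulate the qualitative features of breast cancer
#' epidemiology at a realistic scale - an age-increasing all-cause mortality
#' hazard, a breast-cancer onset hazard peaking in the late 60s with a
#' cumulative risk to age 80 of about 12% (roughly the familiar 1-in-9
#' lifetime risk), right-skewed lognormal tumor growth rates, size-dependent
#' mammographic sensitivity, size-driven nodal/distant spread, and survival
#' that worsens monotonically with stage at diagnosis. They are explicit
#' stand-ins, not a calibration to any registry.
#'
#' @param seed Integer master seed stored in the set; the same seed always
#'   yields an identical parameter set.
#' @return A `mammosim_params` object (a named list). Components:
#' \describe{
#'   \item{life_table}{tibble `age`, `qx` (see [make_life_table()]).}
#'   \item{onset_hazard}{per-age onset rate (1/year), ages 0..109.}
#'   \item{subtype_weights}{named probability vector over tumor subtypes.}
#'   \item{growth}{`meanlog`, `sdlog` of the lognormal growth rate (1/year),
#'     initial diameter `d0` and asymptotic diameter `dmax` (mm).}
#'   \item{insitu_fraction}{probability a new cancer starts in situ.}
#'   \item{insitu_progression_prob}{annual in situ to invasive probability.}
#'   \item{stage_model}{size cut-offs `size_t1`, `size_t2` (mm) and logistic
#'     `(pmax, d50, k)` annual nodal- and distant-spread probabilities.}
#'   \item{sensitivity}{logistic screen sensitivity `(smax, d50, k)` plus the
#'     fixed in situ sensitivity `insitu`.}
#'   \item{clinical_detection}{surfacing hazard scale `c0` (1/year) at
#'     reference diameter `dref` (mm).}
#'   \item{fp_recall_rate, biopsy_given_recall, neg_biopsy_given_no_cancer}{
#'     per-screen false-positive recall and biopsy probabilities.}
#'   \item{survival}{tibble `stage`, `cure`, `rate`: per-stage cure
#'     probability and exponential death rate (1/year) for the non-cured.}
#'   \item{seed}{the stored seed.}
#' }
#' @examples
#' p <- make_default_params(seed = 1)
#' validate_params(p)
#' @export
make_default_params <- function(seed = 1) {
  age <- 0:109
  params <- list(
    schema_version = 1L,
    life_table = make_life_table(),
    # Gaussian-shaped age profile peaking at 68; cumulative hazard to age 80
    # ~0.128, i.e. ~12% cumulative onset risk
    onset_hazard = 0.0038 * exp(-((age - 68)^2) / (2 * 18^2)),
    subtype_weights = c(
      luminal_a = 0.40, luminal_b = 0.20, her2 = 0.10,
      triple_negative = 0.15, other = 0.15
    ),
    growth = list(meanlog = log(0.25), sdlog = 0.6, d0 = 2, dmax = 128),
    insitu_fraction = 0.25,
    insitu_progression_prob = 0.2,
    stage_model = list(
      size_t1 = 20, size_t2 = 50,
      nodal = list(pmax = 0.35, d50 = 25, k = 0.15),
      distant = list(pmax = 0.25, d50 = 35, k = 0.12)
    ),
    sensitivity = list(smax = 0.95, d50 = 10, k = 0.4, insitu = 0.5),
    clinical_detection = list(c0 = 0.25, dref = 15),
    fp_recall_rate = 0.055,
    biopsy_given_recall = 0.09,
    neg_biopsy_given_no_cancer = 1,
    survival = tibble::tibble(
      stage = .stage_levels,
      cure = c(0.98, 0.92, 0.84, 0.74, 0.55, 0.05),
      rate = c(0.02, 0.05, 0.09, 0.14, 0.22, 0.35)
    ),
    seed = as.integer(seed)
  )
  class(params) <- "mammosim_params"
  params <- validate_params(params)
  params
}

#' Validate a parameter set
#'
#' Checks every structural invariant of a parameter set and stops with an
#' error naming the offending field on the first violation: probabilities in
#' \[0, 1\], subtype weights summing to 1 (within 1e-9), strictly increasing
#' stage size cut-offs, cure probabilities strictly decreasing and death
#' rates strictly increasing with stage, a valid life table, and a
#' non-negative onset hazard of length 110.
#'
#' @param params A parameter set (see [make_default_params()]).
#' @return `params`, invisibly reclassed as `mammosim_params`, if valid.
#' @export
validate_params <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter set: %s %s", field, msg), call. = FALSE)
  }
  need <- c(
    "life_table", "onset_hazard", "subtype_weights", "growth",
    "insitu_fraction", "insitu_progression_prob", "stage_model",
    "sensitivity", "clinical_detection", "fp_recall_rate",
    "biopsy_given_recall", "neg_biopsy_given_no_cancer", "survival", "seed"
  )
  missing <- setdiff(need, names(params))
  if (length(missing)) fail(missing[1], "is missing")
  .validate_life_table(params$life_table)

  oh <- params$onset_hazard
  if (length(oh) != 110) fail("onset_hazard", "must have length 110")
  if (any(is.na(oh)) || any(oh < 0)) fail("onset_hazard", "must be >= 0")

  sw <- params$subtype_weights
  if (is.null(names(sw)) || any(!nzchar(names(sw)))) {
    fail("subtype_weights", "must be a named vector")
  }
  if (any(sw < 0) || abs(sum(sw) - 1) > 1e-9) {
    fail("subtype_weights", "must be non-negative and sum to 1")
  }

  g <- params$growth
  if (!all(c("meanlog", "sdlog", "d0", "dmax") %in% names(g))) {
    fail("growth", "needs meanlog, sdlog, d0, dmax")
  }
  if (g$sdlog < 0) fail("growth$sdlog", "must be >= 0")
  if (g$d0 <= 0 || g$d0 >= g$dmax) fail("growth", "requires 0 < d0 < dmax")

  probs <- c(
    insitu_fraction = params$insitu_fraction,
    insitu_progression_prob = params$insitu_progression_prob,
    fp_recall_rate = params$fp_recall_rate,
    biopsy_given_recall = params$biopsy_given_recall,
    neg_biopsy_given_no_cancer = params$neg_biopsy_given_no_cancer,
    sensitivity_smax = params$sensitivity$smax,
    sensitivity_insitu = params$sensitivity$insitu,
    nodal_pmax = params$stage_model$nodal$pmax,
    distant_pmax = params$stage_model$distant$pmax
  )
  bad <- which(is.na(probs) | probs < 0 | probs > 1)
  if (length(bad)) fail(names(probs)[bad[1]], "must be a probability in [0, 1]")

  sm <- params$stage_model
  if (!(sm$size_t1 > 0 && sm$size_t2 > sm$size_t1)) {
    fail("stage_model", "size cut-offs must satisfy 0 < size_t1 < size_t2")
  }
  if (params$sensitivity$k < 0) fail("sensitivity$k", "must be >= 0")
  if (params$clinical_detection$c0 < 0) {
    fail("clinical_detection$c0", "must be >= 0")
  }
  if (params$clinical_detection$dref <= 0) {
    fail("clinical_detection$dref", "must be > 0")
  }

  sv <- params$survival
  if (!identical(as.character(sv$stage), .stage_levels)) {
    fail("survival$stage", "must list stages 0, 1, 2A, 2B, 3, 4 in order")
  }
  if (any(sv$cure < 0 | sv$cure > 1)) fail("survival$cure", "must be in [0, 1]")
  if (any(diff(sv$cure) >= 0)) {
    fail("survival$cure", "must be strictly decreasing with stage")
  }
  if (any(sv$rate <= 0)) fail("survival$rate", "must be > 0")
  if (any(diff(sv$rate) <= 0)) {
    fail("survival$rate", "must be strictly increasing with stage")
  }
  if (length(params$seed) != 1 || is.na(params$seed)) {
    fail("seed", "must be a single integer")
  }
  class(params) <- "mammosim_params"
  invisible(params)
}

#' @export
print.mammosim_params <- function(x, ...) {
  cat("<mammosim_params> schema", x$schema_version, " seed", x$seed, "\n")
  cat("  lifetime onset risk to 80:",
      sprintf("%.3f", 1 - exp(-sum(x$onset_hazard[1:80]))), "\n")
  cat("  growth: lognormal(meanlog=", sprintf("%.3f", x$growth$meanlog),
      ", sdlog=", x$growth$sdlog, "), d0=", x$growth$d0,
      "mm, dmax=", x$growth$dmax, "mm\n", sep = "")
  cat("  sensitivity: smax=", x$sensitivity$smax, " d50=", x$sensitivity$d50,
      "mm k=", x$sensitivity$k, "/mm\n", sep = "")
  invisible(x)
}

#' Cumulative breast-cancer onset risk implied by a parameter set
#'
#' Closed form on the piecewise-constant hazard: `1 - exp(-sum(h(age)))` over
#' ages below `to_age`.
#'
#' @param params A parameter set.
#' @param to_age Upper age (exclusive), default 80.
#' @return Probability of cancer onset before `to_age`.
#' @export
cumulative_onset_risk <- function(params, to_age = 80) {
  stopifnot(to_age >= 1, to_age <= 110)
  1 - exp(-sum(params$onset_hazard[seq_len(to_age)]))
}
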