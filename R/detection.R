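# Detection: size-dependent screen sensitivity, clinical surfacing,
# false-positive recalls and negative biopsies.

#' Mammographic sensitivity as a function of tumor diameter
#'
#' Logistic size-dependent sensitivity,
#' `smax / (1 + exp(-k * (d - d50)))`: half of `smax` at `d50`, saturating at
#' `smax` for large tumors, monotone nondecreasing in diameter.
#'
#' @param diameter Invasive tumor diameter(s), mm, `>= 0`.
#' @param sensitivity Sensitivity component of a parameter set (`smax`,
#'   `d50`, `k`).
#' @return Detection probability per screen.
#' @examples
#' p <- make_default_params()
#' screening_sensitivity(p$sensitivity$d50, p$sensitivity) # smax / 2
#' @export
screening_sensitivity <- function(diameter,
                                  sensitivity = make_default_params()$sensitivity) {
  if (any(diameter < 0)) stop("diameter must be >= 0", call. = FALSE)
  sensitivity$smax / (1 + exp(-sensitivity$k * (diameter - sensitivity$d50)))
}

#' Clinical surfacing age of an invasive tumor
#'
#' The tumor surfaces clinically (symptoms, self- or clinical exam) in the
#' first year after invasive onset at which the cumulative diameter-scaled
#' hazard `sum(c0 * d(j) / dref)` on the yearly grid exceeds the exponential
#' threshold `-log(u)`. May exceed any death age - some cancers never
#' surface before the woman dies of other causes; `Inf` means the hazard
#' never accumulates enough by age 110.
#'
#' @param invasive_age Age at invasive onset (years).
#' @param gamma Tumor growth rate (1/year).
#' @param params Parameter set (uses `clinical_detection` and `growth`).
#' @param u Uniform(0, 1) deviate.
#' @return Surfacing age in years (possibly `Inf`).
#' @export
clinical_surfacing_age <- function(invasive_age, gamma, params, u) {
  stopifnot(u > 0, u < 1, invasive_age >= 0)
  c0 <- params$clinical_detection$c0
  dref <- params$clinical_detection$dref
  thr <- -log(u)
  cum <- 0
  j <- 0L
  while (invasive_age + j < 110) {
    cum <- cum + c0 * tumor_diameter(j, gamma, params$growth$d0,
                                     params$growth$dmax) / dref
    if (cum > thr) return(invasive_age + j)
    j <- j + 1L
  }
  Inf
}

#' One screening visit for one woman
#'
#' The per-screen decision rule: if an undiagnosed cancer is present the
#' screen detects it when `u_detect` falls below the size-dependent
#' sensitivity (in situ lesions use the fixed in situ sensitivity); if no
#' cancer is present, a false-positive recall occurs when `u_fp` falls below
#' the per-screen recall rate, and a recalled woman receives a (by
#' construction negative) biopsy when `u_biopsy` falls below the
#' biopsy-given-recall probability. Counters are incremented accordingly.
#'
#' @param state List with logical `has_cancer`, logical `insitu`, numeric
#'   `diameter` (mm, invasive only) and counters `n_screens`,
#'   `n_fp_recalls`, `n_neg_biopsies`.
#' @param params Parameter set.
#' @param u_detect,u_fp,u_biopsy Uniform(0, 1) deviates.
#' @return `state` with updated counters and logical `detected`.
#' @export
screen_event <- function(state, params, u_detect = 0.5, u_fp = 0.5,
                         u_biopsy = 0.5) {
  state$n_screens <- state$n_screens + 1L
  state$detected <- FALSE
  if (isTRUE(state$has_cancer)) {
    sens <- if (isTRUE(state$insitu)) params$sensitivity$insitu
            else screening_sensitivity(state$diameter, params$sensitivity)
    state$detected <- u_detect < sens
  } else if (u_fp < params$fp_recall_rate) {
    state$n_fp_recalls <- state$n_fp_recalls + 1L
    if (u_biopsy < params$biopsy_given_recall *
        params$neg_biopsy_given_no_cancer) {
      state$n_neg_biopsies <- state$n_neg_biopsies + 1L
    }
  }
  state
}

# Vectorized screening + diagnosis + death resolution for one regimen over a
# natural-history table. Screen draws are keyed by screen AGE, so regimens
# sharing a screen age share those draws (nested regimens couple exactly).
.apply_regimen <- function(nh, params, regimen, seed) {
  n <- nrow(nh)
  wkey <- .rng_wkey(nh$woman_id)
  pur <- .rng_purpose
  u_of <- function(purpose, counter, idx) {
    .rng_u_keyed(.rng_base(seed, pur[[purpose]], counter), wkey[idx])
  }
  d0 <- params$growth$d0
  dmax <- params$growth$dmax

  attends <- nh$u_participation < regimen$participation
  det_age <- rep(Inf, n)
  n_screens <- integer(n)
  n_fp <- integer(n)
  n_bx <- integer(n)

  for (a in scheduled_screen_ages(regimen)) {
    # attending, alive, and not yet diagnosed by screen or clinic
    # (a screen in the clinical surfacing year precedes the clinical exam)
    elig <- which(attends & a < nh$other_death_age & is.infinite(det_age) &
                    nh$surfacing_age >= a)
    if (!length(elig)) next
    n_screens[elig] <- n_screens[elig] + 1L
    has_ca <- nh$onset_age[elig] <= a
    ca <- elig[has_ca]
    if (length(ca)) {
      inv <- nh$invasive_age[ca] <= a
      sens <- rep(params$sensitivity$insitu, length(ca))
      sens[inv] <- screening_sensitivity(
        tumor_diameter(a - nh$invasive_age[ca[inv]], nh$gamma[ca[inv]],
                       d0, dmax),
        params$sensitivity
      )
      hit <- u_of("detect", a, ca) < sens
      det_age[ca[hit]] <- a
    }
    noca <- elig[!has_ca]
    if (length(noca)) {
      fp <- noca[u_of("fp", a, noca) < params$fp_recall_rate]
      n_fp[fp] <- n_fp[fp] + 1L
      bx <- fp[u_of("biopsy", a, fp) < params$biopsy_given_recall *
                 params$neg_biopsy_given_no_cancer]
      n_bx[bx] <- n_bx[bx] + 1L
    }
  }

  # diagnosis: earlier of screen detection and clinical surfacing, while alive
  dx_age <- pmin(det_age, nh$surfacing_age)
  diagnosed <- is.finite(dx_age) & dx_age < nh$other_death_age & dx_age < 110
  dx_age[!diagnosed] <- Inf
  mode <- ifelse(!diagnosed, "none",
                 ifelse(det_age <= nh$surfacing_age, "screen", "clinical"))

  insitu_at_dx <- diagnosed & dx_age < nh$invasive_age
  diameter_at_dx <- rep(NA_real_, n)
  inv_dx <- which(diagnosed & !insitu_at_dx)
  diameter_at_dx[inv_dx] <- tumor_diameter(
    dx_age[inv_dx] - nh$invasive_age[inv_dx], nh$gamma[inv_dx], d0, dmax
  )
  stage_at_dx <- assign_stage(
    diameter_at_dx,
    invasive = diagnosed & !insitu_at_dx,
    nodal = diagnosed & nh$nodal_age <= dx_age,
    distant = diagnosed & nh$distant_age <= dx_age,
    stage_model = params$stage_model
  )
  stage_at_dx[!diagnosed] <- NA

  # survival: only cancers that would ever surface clinically can kill
  # (diagnosed never-surfacing cancers are the overdetection pool); the
  # anchor is the surfacing age, so screening acts through stage alone
  at_risk <- diagnosed & nh$surfacing_age <= 109
  bc_death_age <- rep(NA_real_, n)
  if (any(at_risk)) {
    bc_death_age[at_risk] <- sample_bc_death_age(
      stage_at_dx[at_risk], nh$surfacing_age[at_risk], params$survival,
      nh$u_cure[at_risk], nh$u_time[at_risk]
    )
  }
  death <- resolve_death(bc_death_age, nh$other_death_age)

  tibble::tibble(
    nh[, c("woman_id", "other_death_age", "onset_age", "starts_insitu",
           "subtype", "gamma", "invasive_age", "nodal_age", "distant_age",
           "surfacing_age")],
    attends_screening = attends,
    n_screens = n_screens,
    n_fp_recalls = n_fp,
    n_neg_biopsies = n_bx,
    mode = mode,
    age_at_dx = ifelse(diagnosed, dx_age, NA_real_),
    stage_at_dx = stage_at_dx,
    diameter_at_dx = diameter_at_dx,
    bc_death_age = bc_death_age,
    age_at_death = death$age_at_death,
    cause = death$cause
  )
}
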