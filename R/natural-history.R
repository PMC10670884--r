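# Natural history: onset, Gompertz growth, in situ -> invasive transition,
# nodal and distant spread, stage assignment.

#' Sample a cancer onset age by inverse transform
#'
#' Inverts the piecewise-constant cumulative onset hazard: with `E = -log(u)`,
#' onset falls in the first age-year where the cumulative hazard exceeds `E`,
#' placed within the year by linear interpolation on the hazard. Returns `NA`
#' when the cumulative hazard over ages 0..109 never reaches `E` (the woman
#' never develops cancer).
#'
#' @param onset_hazard Numeric vector of per-age onset rates (1/year), ages
#'   0..109.
#' @param u Uniform(0, 1) deviate(s); vectorized.
#' @return Numeric vector of continuous onset ages in \[0, 110), `NA` where
#'   no onset occurs.
#' @examples
#' sample_onset_age(rep(0.01, 110), exp(-0.5)) # 50
#' @export
sample_onset_age <- function(onset_hazard, u) {
  if (length(onset_hazard) != 110 || any(is.na(onset_hazard)) ||
      any(onset_hazard < 0)) {
    stop("onset_hazard must be 110 non-negative per-age rates", call. = FALSE)
  }
  stopifnot(all(u > 0 & u < 1))
  ch <- c(0, cumsum(onset_hazard))
  e <- -log(u)
  out <- rep(NA_real_, length(u))
  hit <- e < ch[111]
  if (any(hit)) {
    bin <- findInterval(e[hit], ch) # 1-based: age = bin - 1
    out[hit] <- (bin - 1) + (e[hit] - ch[bin]) / onset_hazard[bin]
  }
  out
}

#' Gompertz tumor diameter
#'
#' Deterministic Gompertz growth from initial diameter `d0` towards the
#' asymptote `dmax`: `d(t) = dmax * (d0 / dmax) ^ exp(-gamma * t)`, with `t`
#' the time since invasive onset. Monotone nondecreasing in both `t` and
#' `gamma`.
#'
#' @param t Years since invasive onset, `>= 0`; vectorized.
#' @param gamma Growth rate (1/year), `>= 0`.
#' @param d0 Initial diameter (mm).
#' @param dmax Asymptotic diameter (mm), `> d0`.
#' @return Diameter(s) in mm.
#' @examples
#' tumor_diameter(4, gamma = 0.5, d0 = 2, dmax = 128)
#' @export
tumor_diameter <- function(t, gamma, d0 = 2, dmax = 128) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (any(gamma < 0)) stop("gamma must be >= 0", call. = FALSE)
  stopifnot(all(d0 > 0), all(d0 < dmax))
  dmax * (d0 / dmax)^exp(-gamma * t)
}

# logistic annual spread probability, saturating at pmax
.spread_prob <- function(diameter, spread) {
  spread$pmax / (1 + exp(-spread$k * (diameter - spread$d50)))
}

#' Assign a stage from tumor state
#'
#' Decision-table staging: stage 0 while in situ; stage 4 once distant spread
#' has occurred; otherwise by diameter and nodal status with AJCC-like size
#' cut-offs (`size_t1` = 20 mm, `size_t2` = 50 mm by default): `<= size_t1`
#' node-negative is stage 1; `<= size_t1` node-positive or
#' `(size_t1, size_t2]` node-negative is 2A; `(size_t1, size_t2]`
#' node-positive is 2B; `> size_t2` is stage 3.
#'
#' @param diameter Invasive tumor diameter (mm); ignored while in situ.
#' @param invasive,nodal,distant Logical state flags; vectorized together
#'   with `diameter`.
#' @param stage_model Stage model component of a parameter set (only
#'   `size_t1` and `size_t2` are used).
#' @return Factor with levels `0, 1, 2A, 2B, 3, 4`.
#' @examples
#' p <- make_default_params()
#' assign_stage(15, invasive = TRUE, nodal = FALSE, distant = FALSE,
#'              stage_model = p$stage_model) # "1"
#' @export
assign_stage <- function(diameter, invasive, nodal, distant,
                         stage_model = make_default_params()$stage_model) {
  n <- max(length(diameter), length(invasive), length(nodal), length(distant))
  diameter <- rep_len(diameter, n)
  invasive <- rep_len(invasive, n)
  nodal <- rep_len(nodal, n)
  distant <- rep_len(distant, n)
  t1 <- stage_model$size_t1
  t2 <- stage_model$size_t2
  out <- rep("0", n)
  inv <- invasive
  out[inv & diameter <= t1 & !nodal] <- "1"
  out[inv & ((diameter <= t1 & nodal) | (diameter > t1 & diameter <= t2 &
                                           !nodal))] <- "2A"
  out[inv & diameter > t1 & diameter <= t2 & nodal] <- "2B"
  out[inv & diameter > t2] <- "3"
  out[inv & distant] <- "4"
  factor(out, levels = .stage_levels)
}

#' Collapse substages to coarse stages
#'
#' Maps the substage factor (`0, 1, 2A, 2B, 3, 4`) to the coarse reporting
#' scale (`0, 1, 2, 3, 4`), as used in stage-distribution tables.
#'
#' @param stage Substage factor from [assign_stage()].
#' @return Factor with levels `0..4`.
#' @export
coarse_stage <- function(stage) {
  map <- c("0" = "0", "1" = "1", "2A" = "2", "2B" = "2", "3" = "3", "4" = "4")
  factor(unname(map[as.character(stage)]), levels = c("0", "1", "2", "3", "4"))
}

#' One annual progression update of a tumor
#'
#' Applies, in order, the in situ to invasive transition and then the
#' diameter-dependent nodal and distant spread trials for the year ending at
#' `age`. Events are irreversible; distant spread can only follow nodal
#' spread. Intended for stepping a single tumor on the yearly grid (the
#' cohort engine applies the same rules vectorized); a diagnosed tumor is no
#' longer updated.
#'
#' @param tumor A list with fields `onset_age`, `is_insitu`, `invasive_age`,
#'   `gamma`, `d0`, `dmax`, `nodal_age`, `distant_age` (ages `NA` when the
#'   event has not occurred).
#' @param age Integer age at the end of the update year.
#' @param params Parameter set (uses `insitu_progression_prob` and
#'   `stage_model`).
#' @param u Named uniforms for the three trials: `insitu`, `nodal`,
#'   `distant`.
#' @return The updated tumor list.
#' @export
update_progression <- function(tumor, age, params,
                               u = c(insitu = 0.5, nodal = 0.5,
                                     distant = 0.5)) {
  stopifnot(all(c("insitu", "nodal", "distant") %in% names(u)))
  if (tumor$is_insitu && age > tumor$onset_age) {
    if (u[["insitu"]] < params$insitu_progression_prob) {
      tumor$is_insitu <- FALSE
      tumor$invasive_age <- tumor$onset_age +
        ceiling(age - tumor$onset_age) # annual grid offset from onset
    }
  }
  if (!tumor$is_insitu && !is.na(tumor$invasive_age) &&
      age > tumor$invasive_age) {
    d <- tumor_diameter(age - tumor$invasive_age, tumor$gamma, tumor$d0,
                        tumor$dmax)
    if (is.na(tumor$nodal_age) &&
        u[["nodal"]] < .spread_prob(d, params$stage_model$nodal)) {
      tumor$nodal_age <- tumor$invasive_age +
        ceiling(age - tumor$invasive_age)
    }
    if (!is.na(tumor$nodal_age) && is.na(tumor$distant_age) &&
        age > tumor$nodal_age &&
        u[["distant"]] < .spread_prob(d, params$stage_model$distant)) {
      tumor$distant_age <- tumor$invasive_age +
        ceiling(age - tumor$invasive_age)
    }
  }
  tumor
}

# Vectorized natural history for woman ids `ids` (0-based), regimen-free.
# Every draw is keyed by (seed, purpose, year, woman) so the result is
# identical no matter how or in what order the cohort is partitioned.
.natural_history <- function(params, ids, seed) {
  n <- length(ids)
  wkey <- .rng_wkey(ids)
  pur <- .rng_purpose
  u_of <- function(purpose, counter = 0, idx = NULL) {
    k <- if (is.null(idx)) wkey else wkey[idx]
    .rng_u_keyed(.rng_base(seed, pur[[purpose]], counter), k)
  }

  other_death_age <- sample_other_cause_death_age(
    params$life_table, u_of("other_death")
  )
  onset_age <- sample_onset_age(params$onset_hazard, u_of("onset"))
  has_ca <- !is.na(onset_age)

  sw <- params$subtype_weights
  subtype <- names(sw)[findInterval(u_of("subtype"), c(0, cumsum(sw)),
                                    rightmost.closed = TRUE)]
  subtype[!has_ca] <- NA_character_

  gamma <- stats::qlnorm(u_of("growth"), params$growth$meanlog,
                         params$growth$sdlog)
  gamma[!has_ca] <- NA_real_

  starts_insitu <- has_ca & (u_of("insitu_class") < params$insitu_fraction)

  # in situ -> invasive: yearly Bernoulli trials at onset + k, k = 1, 2, ...
  invasive_age <- ifelse(has_ca & !starts_insitu, onset_age, Inf)
  active <- which(starts_insitu)
  k <- 1L
  pp <- params$insitu_progression_prob
  while (length(active) && k <= 110L) {
    inbound <- onset_age[active] + k < 110
    active <- active[inbound]
    if (!length(active)) break
    hit <- u_of("insitu_prog", k, active) < pp
    invasive_age[active[hit]] <- onset_age[active[hit]] + k
    active <- active[!hit]
    k <- k + 1L
  }

  d0 <- params$growth$d0
  dmax <- params$growth$dmax
  inv_ids <- which(is.finite(invasive_age))

  # nodal spread: yearly trials at invasive + j on the growing diameter
  nodal_age <- rep(Inf, n)
  active <- inv_ids
  j <- 1L
  while (length(active) && j <= 110L) {
    inbound <- invasive_age[active] + j < 110
    active <- active[inbound]
    if (!length(active)) break
    d <- tumor_diameter(j, gamma[active], d0, dmax)
    hit <- u_of("nodal", j, active) < .spread_prob(d, params$stage_model$nodal)
    nodal_age[active[hit]] <- invasive_age[active[hit]] + j
    active <- active[!hit]
    j <- j + 1L
  }

  # distant spread: yearly trials, only after nodal spread
  distant_age <- rep(Inf, n)
  active <- which(is.finite(nodal_age))
  j <- 1L
  while (length(active) && j <= 110L) {
    inbound <- invasive_age[active] + j < 110
    active <- active[inbound]
    if (!length(active)) break
    idx <- active[nodal_age[active] - invasive_age[active] < j]
    if (length(idx)) {
      d <- tumor_diameter(j, gamma[idx], d0, dmax)
      hit <- u_of("distant", j, idx) < .spread_prob(d,
                                                    params$stage_model$distant)
      distant_age[idx[hit]] <- invasive_age[idx[hit]] + j
      active <- setdiff(active, idx[hit])
    }
    j <- j + 1L
  }

  # clinical surfacing: first year where the cumulative diameter-scaled
  # hazard exceeds the exponential threshold -log(u)
  surfacing_age <- rep(Inf, n)
  c0 <- params$clinical_detection$c0
  dref <- params$clinical_detection$dref
  if (length(inv_ids)) {
    thr <- -log(u_of("surfacing", 0, inv_ids))
    cum <- numeric(length(inv_ids))
    alive_idx <- seq_along(inv_ids)
    j <- 0L
    while (length(alive_idx) && j <= 110L) {
      ii <- inv_ids[alive_idx]
      inbound <- invasive_age[ii] + j < 110
      alive_idx <- alive_idx[inbound]
      if (!length(alive_idx)) break
      ii <- inv_ids[alive_idx]
      cum[alive_idx] <- cum[alive_idx] +
        c0 * tumor_diameter(j, gamma[ii], d0, dmax) / dref
      hit <- cum[alive_idx] > thr[alive_idx]
      surfacing_age[ii[hit]] <- invasive_age[ii[hit]] + j
      alive_idx <- alive_idx[!hit]
      j <- j + 1L
    }
  }

  tibble::tibble(
    woman_id = ids,
    other_death_age = other_death_age,
    onset_age = ifelse(has_ca, onset_age, Inf),
    starts_insitu = starts_insitu,
    subtype = subtype,
    gamma = gamma,
    invasive_age = invasive_age,
    nodal_age = nodal_age,
    distant_age = distant_age,
    surfacing_age = surfacing_age,
    u_cure = u_of("cure"),
    u_time = u_of("surv_time"),
    u_participation = u_of("participation")
  )
}
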