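# Synthetic life table: Gompertz-Makeham hazard on ages 0..109.

#' Build a synthetic female life table
#'
#' Constructs a period life table for ages 0..109 from a Gompertz-Makeham
#' hazard, `h(age) = a + b * exp(c * age)`. The conditional death probability
#' in each one-year age interval is `qx = 1 - exp(-h(age))`, clamped to
#' \[0, 1\], and `qx` at age 109 is forced to 1 so every simulated life ends
#' by age 110. The defaults give a life expectancy at birth in the mid-80s,
#' emulating a contemporary female population; the table is a synthetic
#' stand-in, not a fit to any national data.
#'
#' @param makeham_a Age-independent hazard component (1/year), `>= 0`.
#' @param gompertz_b Gompertz scale (1/year), `>= 0`.
#' @param gompertz_c Gompertz shape (1/year), `>= 0`.
#' @return A tibble with integer column `age` (0..109) and numeric column
#'   `qx`, the probability of death within the year conditional on survival
#'   to `age`.
#' @examples
#' lt <- make_life_table()
#' life_expectancy(lt, at_age = 40)
#' @export
make_life_table <- function(makeham_a = 5e-4, gompertz_b = 3e-5,
                            gompertz_c = 0.095) {
  if (any(c(makeham_a, gompertz_b, gompertz_c) < 0)) {
    stop("life table hazard parameters must be non-negative", call. = FALSE)
  }
  age <- 0:109
  qx <- 1 - exp(-(makeham_a + gompertz_b * exp(gompertz_c * age)))
  qx <- pmin(pmax(qx, 0), 1)
  qx[110] <- 1
  tibble::tibble(age = age, qx = qx)
}

.validate_life_table <- function(lt) {
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life_table: must have columns age and qx", call. = FALSE)
  }
  if (nrow(lt) != 110 || !identical(as.integer(lt$age), 0:109)) {
    stop("life_table: ages must be exactly 0..109", call. = FALSE)
  }
  if (any(is.na(lt$qx)) || any(lt$qx < 0 | lt$qx > 1)) {
    stop("life_table: qx must lie in [0, 1]", call. = FALSE)
  }
  if (lt$qx[110] != 1) {
    stop("life_table: qx at age 109 must equal 1", call. = FALSE)
  }
  invisible(lt)
}

# P(death in [a, a+1)) for a = 0..109, summing to 1
.death_year_probs <- function(lt) {
  surv <- cumprod(c(1, 1 - lt$qx[-110]))
  surv * lt$qx
}

#' Life expectancy from a life table
#'
#' Deterministic summation over the table, with deaths spread uniformly
#' within each one-year interval (consistent with
#' [sample_other_cause_death_age()]). With `at_age > 0` the expectation is
#' conditional on survival to `at_age`.
#'
#' @param life_table A life table from [make_life_table()] or
#'   [read_life_table()].
#' @param at_age Conditioning age in years (default 0).
#' @return Expected remaining years of life at `at_age`, in years.
#' @export
life_expectancy <- function(life_table, at_age = 0) {
  .validate_life_table(life_table)
  stopifnot(at_age >= 0, at_age <= 109)
  p <- .death_year_probs(life_table)
  keep <- life_table$age >= at_age
  p <- p[keep] / sum(p[keep])
  sum(p * (life_table$age[keep] + 0.5)) - at_age
}

#' Sample an other-cause death age from a life table
#'
#' Inverse-transform sampling on the discrete life table with a uniform
#' sub-year offset: `u` picks the death year through the table's cumulative
#' distribution and its within-bin remainder places the death inside the
#' year, so the returned age is a continuous draw from the piecewise-uniform
#' survival model implied by the table. Because `qx` at 109 is 1, the result
#' is always below 110.
#'
#' @param life_table A life table (see [make_life_table()]).
#' @param u Uniform(0, 1) deviate(s); vectorized.
#' @return Numeric vector of death ages in \[0, 110).
#' @export
sample_other_cause_death_age <- function(life_table, u) {
  .validate_life_table(life_table)
  stopifnot(all(u > 0 & u < 1))
  p <- .death_year_probs(life_table)
  cdf <- c(0, cumsum(p))
  cdf[length(cdf)] <- 1
  bin <- findInterval(u, cdf, rightmost.closed = TRUE)
  frac <- (u - cdf[bin]) / p[bin]
  life_table$age[bin] + pmin(frac, 1)
}

#' Read / write a life table as two-column CSV
#'
#' Plain-text interchange for life tables: a CSV with columns `age` (0..109)
#' and `qx`. Validation is applied on read.
#'
#' @param path File path.
#' @param life_table A life table tibble.
#' @return `read_life_table()` returns the validated life table tibble;
#'   `write_life_table()` returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  lt <- tibble::as_tibble(utils::read.csv(path))
  lt$age <- as.integer(lt$age)
  .validate_life_table(lt)
  lt
}

#' @rdname read_life_table
#' @export
write_life_table <- function(life_table, path) {
  .validate_life_table(life_table)
  utils::write.csv(life_table, path, row.names = FALSE)
  invisible(path)
}
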