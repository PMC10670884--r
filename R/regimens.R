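# Screening regimens: one or more (start, stop, interval) phases plus a
# lifetime participation fraction.

#' Define a screening regimen
#'
#' A regimen is a set of scheduled screen ages given by one or more arithmetic
#' phases `start, start + interval, ... <= stop`, plus a participation
#' fraction. `regimen()` builds a single-phase regimen;
#' `regimen_phases()` concatenates phases (e.g. annual in the 40s then
#' biennial 50-74); "no screening" is a regimen with no phases.
#'
#' @param name Short label used in outputs.
#' @param start_age,stop_age First and last eligible screen ages (years).
#' @param interval Whole years between screens, `>= 1`.
#' @param participation Fraction of women who attend screening (all-or-none
#'   over a lifetime), in \[0, 1\].
#' @param phases For `regimen_phases()`: a data frame with columns
#'   `start_age`, `stop_age`, `interval`.
#' @return A `mammosim_regimen` object.
#' @examples
#' regimen("50-74 biennial", 50, 74, 2)
#' regimen_phases(
#'   "40-49 ann, 50-74 bi",
#'   data.frame(start_age = c(40, 50), stop_age = c(49, 74), interval = c(1, 2))
#' )
#' @export
regimen <- function(name, start_age, stop_age, interval, participation = 1) {
  regimen_phases(
    name,
    tibble::tibble(
      start_age = start_age, stop_age = stop_age, interval = interval
    ),
    participation = participation
  )
}

#' @rdname regimen
#' @export
regimen_phases <- function(name, phases, participation = 1) {
  phases <- tibble::as_tibble(phases)
  stopifnot(
    all(c("start_age", "stop_age", "interval") %in% names(phases)),
    participation >= 0, participation <= 1
  )
  if (nrow(phases) > 0) {
    if (any(phases$start_age > phases$stop_age)) {
      stop("regimen: start_age must be <= stop_age", call. = FALSE)
    }
    if (any(phases$interval < 1)) {
      stop("regimen: interval must be >= 1 year", call. = FALSE)
    }
  }
  structure(
    list(name = name, phases = phases, participation = participation),
    class = "mammosim_regimen"
  )
}

#' @rdname regimen
#' @export
no_screening <- function(name = "no_screening") {
  regimen_phases(name, tibble::tibble(
    start_age = integer(), stop_age = integer(), interval = integer()
  ))
}

#' Scheduled screen ages of a regimen
#'
#' @param regimen A [regimen()] object.
#' @return Sorted integer vector of scheduled screen ages (empty for the
#'   no-screening regimen).
#' @examples
#' length(scheduled_screen_ages(regimen("biennial", 50, 74, 2))) # 13
#' @export
scheduled_screen_ages <- function(regimen) {
  stopifnot(inherits(regimen, "mammosim_regimen"))
  if (nrow(regimen$phases) == 0) return(integer())
  ages <- unlist(purrr::pmap(regimen$phases, function(start_age, stop_age,
                                                      interval) {
    seq(start_age, stop_age, by = interval)
  }))
  sort(unique(as.integer(ages)))
}

#' @export
print.mammosim_regimen <- function(x, ...) {
  ages <- scheduled_screen_ages(x)
  cat("<mammosim_regimen>", x$name, "-", length(ages), "screens",
      if (length(ages)) paste0("(", min(ages), "..", max(ages), ")") else "",
      "participation", x$participation, "\n")
  invisible(x)
}

#' Built-in screening regimens
#'
#' The six regimens commonly contrasted in Canadian screening policy
#' analyses: no screening, annual 40-49, biennial 50-74, biennial 40-74,
#' annual 40-49 with biennial 50-74 (hybrid), and annual 40-74. Ordered by
#' the number of scheduled lifetime screens.
#'
#' @param participation Participation fraction applied to every screening
#'   regimen.
#' @return Named list of [regimen()] objects.
#' @export
default_regimens <- function(participation = 1) {
  list(
    no_screening = no_screening(),
    annual_40_49 = regimen("40-49 annual", 40, 49, 1, participation),
    biennial_50_74 = regimen("50-74 biennial", 50, 74, 2, participation),
    biennial_40_74 = regimen("40-74 biennial", 40, 74, 2, participation),
    hybrid_40_74 = regimen_phases(
      "40-49 ann, 50-74 bi",
      tibble::tibble(
        start_age = c(40L, 50L), stop_age = c(49L, 74L), interval = c(1L, 2L)
      ),
      participation
    ),
    annual_40_74 = regimen("40-74 annual", 40, 74, 1, participation)
  )
}
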