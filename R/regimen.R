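#' Radiation treatment regimen
#'
#' An ordered sequence of radiation applications, each with a fraction dose
#' and the radiosensitizer plasma concentration active at that application
#' (the mean maximum concentration reached after the preceding oral dose).
#'
#' @param time application times, days; strictly increasing, >= 0.
#' @param dose fraction dose(s), Gy; recycled to `length(time)`.
#' @param conc radiosensitizer concentration(s) at each application, ug/mL;
#'   recycled.
#' @param horizon simulation end, days; defaults to 21 days after the last
#'   application (or 21 for an empty regimen).
#'
#' @return An object of class `regimen`: a data frame with columns `time`,
#'   `dose`, `conc` and a `horizon` attribute.
#' @examples
#' regimen(time = c(0, 1, 2, 3, 4), dose = 2, conc = 7)
#' fractionated_regimen(weeks = 6, fraction_dose = 2, conc = 0)
#' @export
regimen <- function(time = numeric(), dose = 2, conc = 0, horizon = NULL) {
  time <- as.numeric(time)
  n <- length(time)
  dose <- rep_len(as.numeric(dose), n)
  conc <- rep_len(as.numeric(conc), n)
  if (n && any(diff(time) <= 0)) stop("application times must be strictly increasing")
  if (n && time[1L] < 0) stop("application times must be >= 0")
  if (any(dose < 0)) stop("fraction doses must be >= 0")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (is.null(horizon)) horizon <- if (n) time[n] + 21 else 21
  if (n && horizon < time[n]) stop("'horizon' must not precede the last application")
  structure(data.frame(time = time, dose = dose, conc = conc),
            horizon = as.numeric(horizon), class = c("regimen", "data.frame"))
}

#' @describeIn regimen Monday-to-Friday fractionation: `fractions_per_week`
#'   applications on consecutive days of each week (weekend gap preserved),
#'   for `weeks` weeks, starting on day 0.
#' @param weeks number of treatment weeks.
#' @param fractions_per_week applications per week (on days 0..4 of the week).
#' @param fraction_dose dose per application, Gy.
#' @export
fractionated_regimen <- function(weeks = 6, fractions_per_week = 5,
                                 fraction_dose = 2, conc = 0, horizon = NULL) {
  regimen(time = schedule_days(weeks, fractions_per_week),
          dose = fraction_dose, conc = conc, horizon = horizon)
}

#' Fractionation day grid
#'
#' Day offsets of a Monday-to-Friday style schedule: `fractions_per_week`
#' consecutive days per 7-day week, first application on day 0.
#'
#' @inheritParams fractionated_regimen
#' @return Numeric vector of application days.
#' @export
schedule_days <- function(weeks = 6, fractions_per_week = 5) {
  stopifnot(weeks >= 1, fractions_per_week >= 1, fractions_per_week <= 7)
  sort(as.numeric(outer(0:(fractions_per_week - 1), 7 * (0:(weeks - 1)), "+")))
}

.regimen_horizon <- function(reg) attr(reg, "horizon", exact = TRUE)
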