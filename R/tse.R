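#' Stasis search problem configuration
#'
#' Defines the fractionation template, evaluation time and tolerance used by
#' the simulation-based tumor-static-exposure (TSE) searches.  The total
#' radiation dose is always split evenly over a Monday-to-Friday style
#' schedule (`fractions_per_week` consecutive days per week for `weeks`
#' weeks), matching the fractionation of the 6-week efficacy studies.
#'
#' @param weeks treatment weeks of the schedule template.
#' @param fractions_per_week applications per week.
#' @param t_star evaluation time of the volume derivative, days; must fall
#'   after the last scheduled application.  Default 60.
#' @param epsilon stasis tolerance on `dV_tot/dt`, mm^3/day.  Default 1e-4.
#' @param conc_upper,dose_upper search brackets for concentration (ug/mL)
#'   and total dose (Gy).
#' @param conc_tol,dose_tol bisection half-width tolerances.
#' @return An object of class `stasis_problem`.
#' @examples
#' stasis_problem()
#' @export
stasis_problem <- function(weeks = 6, fractions_per_week = 5, t_star = 60,
                           epsilon = 1e-4, conc_upper = 500,
                           dose_upper = 2000, conc_tol = 1e-4,
                           dose_tol = 1e-2) {
  sched <- schedule_days(weeks, fractions_per_week)
  if (t_star <= sched[length(sched)])
    stop("'t_star' must fall after the last scheduled application")
  if (epsilon <= 0) stop("'epsilon' must be > 0")
  structure(list(weeks = weeks, fractions_per_week = fractions_per_week,
                 schedule = sched, t_star = t_star, epsilon = epsilon,
                 conc_upper = conc_upper, dose_upper = dose_upper,
                 conc_tol = conc_tol, dose_tol = dose_tol),
            class = "stasis_problem")
}

#' @export
print.stasis_problem <- function(x, ...) {
  cat(sprintf(paste0("Stasis problem: %d fractions (%d/wk x %d wk), ",
                     "t* = %g d, epsilon = %g mm^3/day\n"),
              length(x$schedule), x$fractions_per_week, x$weeks, x$t_star,
              x$epsilon))
  invisible(x)
}

#' Analytical long-term TSE curve
#'
#' Closed-form total radiation dose required for tumor stasis when only the
#' long-term growth-inhibition effect is retained, for the linear
#' inhibition variant:
#' `D = s * (1 - kk/kg) / (gamma * (1 + b*C))` with `s` the gamma dose
#' scale.  The short-term linear-quadratic kill (and hence the potency
#' parameter `a`) does not appear; the simulation-based curves include it.
#'
#' @param params a [tgi_params()] object with `inhibition = "linear"`.
#' @param conc radiosensitizer concentration(s), ug/mL.
#' @return Total radiation dose(s), Gy; decreasing in `conc`.
#' @examples
#' p <- tgi_params(kg = 0.44, kk = 0.3, gamma = 0.02, b = 0.26)
#' analytic_tse(p, conc = 0)   # ~159 Gy
#' analytic_tse(p, conc = 8)
#' @export
analytic_tse <- function(params, conc = 0) {
  if (params$inhibition != "linear")
    stop("the analytical TSE curve is only available for the linear ",
         "inhibition variant")
  denom <- params$gamma * (1 + params$b * conc)
  if (any(denom <= 0)) stop("gamma * (1 + b*conc) must be positive")
  params$gamma_dose_scale * (1 - params$kk / params$kg) / denom
}

.problem_events <- function(problem, total_dose, conc) {
  n <- length(problem$schedule)
  list(time = problem$schedule, dose = rep(total_dose / n, n),
       conc = rep(conc, n))
}

#' Smallest concentration achieving stasis at a fixed total dose
#'
#' Finds the smallest radiosensitizer concentration `C >= 0` such that the
#' total-volume derivative at `t_star` is at most `epsilon`, with the total
#' dose split evenly over the problem's schedule.  The derivative is
#' monotone decreasing in `C`, so the constraint boundary is located by
#' bisection.
#'
#' @param params a [tgi_params()] object (the drug potencies `a`, `b` of
#'   the compound under study must be set).
#' @param total_dose total radiation dose, Gy.
#' @param problem a [stasis_problem()].
#' @return Concentration, ug/mL (0 when radiation alone suffices).
#' @examples
#' p <- tgi_params(kg = 0.44, kk = 0.3, alpha = 0.06, gamma = 0.02,
#'                 a = 0.65, b = 0.26, v0 = 22)
#' stasis_concentration(p, total_dose = 100, problem = stasis_problem())
#' @export
stasis_concentration <- function(params, total_dose, problem = stasis_problem()) {
  stopifnot(total_dose >= 0)
  cc <- .cpp_stasis_conc(.par_vec(params), problem$schedule, total_dose,
                         problem$t_star, problem$epsilon, problem$conc_upper,
                         problem$conc_tol)
  if (is.na(cc))
    stop(sprintf(paste0("no concentration below %g ug/mL achieves stasis at ",
                        "%g Gy; the requirement is unbounded within the ",
                        "configured bracket"), problem$conc_upper, total_dose))
  cc
}

#' Smallest total dose achieving stasis at a fixed concentration
#'
#' Dual search to [stasis_concentration()]: the smallest total radiation
#' dose (split over the problem's schedule) whose volume derivative at
#' `t_star` is at most `epsilon` for the given constant per-application
#' concentration.
#'
#' @inheritParams stasis_concentration
#' @param conc radiosensitizer concentration, ug/mL.
#' @return Total dose, Gy.
#' @export
stasis_dose <- function(params, conc = 0, problem = stasis_problem()) {
  stopifnot(conc >= 0)
  dd <- .cpp_stasis_dose(.par_vec(params), problem$schedule, conc,
                         problem$t_star, problem$epsilon, problem$dose_upper,
                         problem$dose_tol)
  if (is.na(dd))
    stop(sprintf(paste0("no total dose below %g Gy achieves stasis at ",
                        "%g ug/mL within the configured bracket"),
         problem$dose_upper, conc))
  dd
}

.new_tse_curve <- function(conc, dose, method, percentile, problem,
                           n_subjects = NA_integer_, seed = NA_integer_) {
  ok <- is.finite(conc) & is.finite(dose)
  df <- data.frame(conc = conc[ok], dose = dose[ok])
  df <- df[order(df$dose), , drop = FALSE]
  # keep a single boundary point where radiation alone suffices (conc == 0)
  zero <- df$conc <= 0
  if (sum(zero) > 1L) df <- df[!zero | seq_len(nrow(df)) == min(which(zero)), ]
  rownames(df) <- NULL
  structure(df, method = method, percentile = percentile,
            t_star = problem$t_star, epsilon = problem$epsilon,
            schedule = problem$schedule, n_subjects = n_subjects,
            seed = seed, class = c("tse_curve", "data.frame"))
}

#' Simulation-based TSE curve for the median individual
#'
#' For each total dose on a grid, finds by bisection the smallest
#' concentration keeping the median individual's tumor static at `t_star`
#' (see [stasis_concentration()]); the curve between grid points is defined
#' by monotone piecewise-linear interpolation.  Because the short-term
#' linear-quadratic kill also contributes, the curve lies at or below the
#' analytical long-term curve of [analytic_tse()].
#'
#' @inheritParams stasis_concentration
#' @param dose_grid total doses, Gy, spanning the region of interest.
#' @return A `tse_curve` data frame with columns `conc` (ug/mL) and `dose`
#'   (Gy), annotated with the problem settings.  Doses for which no
#'   concentration within the bracket achieves stasis are dropped with a
#'   warning.
#' @export
median_tse_curve <- function(params, dose_grid = seq(0, 300, by = 5),
                             problem = stasis_problem()) {
  pv <- .par_vec(params)
  conc <- vapply(dose_grid, function(D)
    .cpp_stasis_conc(pv, problem$schedule, D, problem$t_star,
                     problem$epsilon, problem$conc_upper, problem$conc_tol),
    numeric(1L))
  if (anyNA(conc))
    warning(sprintf("%d grid dose(s) dropped: stasis unreachable below %g ug/mL",
                    sum(is.na(conc)), problem$conc_upper))
  .new_tse_curve(conc, dose_grid, method = "simulated_median",
                 percentile = "median", problem = problem)
}

#' Monte-Carlo population-percentile TSE curve
#'
#' Draws `n_subjects` virtual individuals from the population model
#' (lognormal between-subject variability on `gamma`, `alpha` and `v0`),
#' solves the stasis problem for each individual at every grid dose, and
#' returns the requested empirical percentile (nearest-rank) of the
#' required concentration per dose.  Exposure pairs on the curve are
#' predicted to hold that fraction of tumors static.
#'
#' @param pop a [population_model()].
#' @param n_subjects number of virtual individuals (the headline analyses
#'   use 1000).
#' @param percentile population fraction in (0, 1), e.g. 0.95.
#' @param dose_grid total doses, Gy.
#' @param problem a [stasis_problem()].
#' @param seed integer seed making the virtual population reproducible.
#' @param study study covariate set supplying the `gamma` and `v0` medians
#'   (default 3, the most conservative gamma).
#' @param compound compound name in `pop$potency` supplying `a` and `b`,
#'   or `NULL` for radiation alone.
#' @return A `tse_curve` (see [median_tse_curve()]).  Grid doses at which
#'   the percentile concentration is unreachable are dropped with a
#'   warning.
#' @export
percentile_tse_curve <- function(pop, n_subjects = 1000, percentile = 0.95,
                                 dose_grid = seq(0, 300, by = 5),
                                 problem = stasis_problem(), seed = 1L,
                                 study = 3, compound = NULL) {
  stopifnot(n_subjects >= 1, percentile > 0, percentile < 1)
  subjects <- sample_subjects(pop, n = n_subjects, study = study,
                              compound = compound, seed = seed)
  k <- max(1L, ceiling(percentile * n_subjects))  # nearest-rank order stat
  conc <- vapply(dose_grid, function(D) {
    cs <- vapply(subjects, function(p)
      .cpp_stasis_conc(.par_vec(p), problem$schedule, D, problem$t_star,
                       problem$epsilon, problem$conc_upper, problem$conc_tol),
      numeric(1L))
    cs[is.na(cs)] <- Inf
    sort(cs)[k]
  }, numeric(1L))
  if (any(!is.finite(conc)))
    warning(sprintf("%d grid dose(s) dropped: percentile concentration above %g ug/mL",
                    sum(!is.finite(conc)), problem$conc_upper))
  .new_tse_curve(conc, dose_grid, method = "simulated_percentile",
                 percentile = percentile, problem = problem,
                 n_subjects = n_subjects, seed = seed)
}

#' Per-subject stasis doses for a virtual population
#'
#' For each virtual individual, finds by bisection the smallest total
#' radiation dose (on the problem's schedule) achieving stasis at the given
#' constant concentration.  Quantiles of the returned vector give the
#' radiation dose required for a population percentile; at `conc = 0` the
#' 95% quantile is the radiation-alone dose holding 95% of tumors static.
#'
#' @inheritParams percentile_tse_curve
#' @param conc radiosensitizer concentration, ug/mL.
#' @return Numeric vector of length `n_subjects` of total doses, Gy (`NA`
#'   where the requirement exceeds the problem's dose bracket).
#' @examples
#' pop <- published_population()
#' d <- stasis_dose_distribution(pop, conc = 0, n_subjects = 50, seed = 1)
#' quantile(d, 0.95, type = 1)
#' @export
stasis_dose_distribution <- function(pop, conc = 0, n_subjects = 1000,
                                     problem = stasis_problem(), seed = 1L,
                                     study = 3, compound = NULL) {
  subjects <- sample_subjects(pop, n = n_subjects, study = study,
                              compound = compound, seed = seed)
  vapply(subjects, function(p)
    .cpp_stasis_dose(.par_vec(p), problem$schedule, conc, problem$t_star,
                     problem$epsilon, problem$dose_upper, problem$dose_tol),
    numeric(1L))
}

#' Read a total dose off a TSE curve at a given concentration
#'
#' Monotone piecewise-linear interpolation of the curve; used to read off
#' dose-reduction numbers (e.g. the dose on the 95% curve at 8 ug/mL).
#'
#' @param curve a `tse_curve`.
#' @param conc concentration, ug/mL, within the curve's computed range.
#' @return Interpolated total dose, Gy.
#' @export
dose_at_concentration <- function(curve, conc) {
  if (conc < min(curve$conc) || conc > max(curve$conc))
    stop(sprintf("concentration %g outside the curve's range [%g, %g]",
                 conc, min(curve$conc), max(curve$conc)))
  o <- order(curve$conc)
  approx(curve$conc[o], curve$dose[o], xout = conc, ties = min)$y
}

#' Rank radiosensitizers by required radiation dose
#'
#' Orders compounds by the total radiation dose their TSE curves require at
#' a common concentration (ascending: the best compound saves the most
#' radiation dose).  All curves must have been computed for the same
#' percentile and method.
#'
#' @param curves named list of `tse_curve` objects, one per compound.
#' @param conc concentration at which to compare, ug/mL.
#' @param tie_tol doses closer than this (Gy) are flagged as tied.
#' @return A data frame with columns `compound`, `dose`, `rank`, `tied`,
#'   ordered best first.
#' @export
rank_compounds <- function(curves, conc, tie_tol = 1e-6) {
  if (is.null(names(curves)) || any(!nzchar(names(curves))))
    stop("'curves' must be a named list (one entry per compound)")
  pct <- vapply(curves, function(cv) format(attr(cv, "percentile")), "")
  mth <- vapply(curves, function(cv) attr(cv, "method"), "")
  if (length(unique(pct)) != 1L || length(unique(mth)) != 1L)
    stop("all curves must share the same percentile and method")
  dose <- vapply(curves, dose_at_concentration, numeric(1L), conc = conc)
  o <- order(dose)
  tied <- vapply(seq_along(o), function(i) {
    any(abs(dose[o][i] - dose[o][-i]) <= tie_tol)
  }, logical(1L))
  data.frame(compound = names(curves)[o], dose = unname(dose[o]),
             rank = rank(round(dose[o] / tie_tol) * tie_tol,
                         ties.method = "min"),
             tied = tied, row.names = NULL)
}

#' @export
print.tse_curve <- function(x, ...) {
  cat(sprintf("TSE curve (%s, percentile: %s): %d points, dose %g-%g Gy\n",
              attr(x, "method"), format(attr(x, "percentile")), nrow(x),
              min(x$dose), max(x$dose)))
  cat(sprintf("  t* = %g d, epsilon = %g, %d-fraction schedule\n",
              attr(x, "t_star"), attr(x, "epsilon"),
              length(attr(x, "schedule"))))
  print.data.frame(head(as.data.frame(x), 4L))
  if (nrow(x) > 4L) cat(sprintf("  ... %d more rows\n", nrow(x) - 4L))
  invisible(x)
}

#' @export
plot.tse_curve <- function(x, add = FALSE, ...) {
  if (add) {
    lines(x$conc, x$dose, ...)
  } else {
    graphics::plot(x$conc, x$dose, type = "l",
                   xlab = "concentration (ug/mL)",
                   ylab = "total radiation dose (Gy)", ...)
  }
  invisible(x)
}
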