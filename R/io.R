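#' Read model or population parameters from a JSON file
#'
#' Reads a flat key/value parameter document.  A file with per-study
#' `gamma`/`v0` blocks, potencies and variability terms yields a
#' [population_model()]; a file with scalar entries yields a single-subject
#' [tgi_params()].  Loading notes are emitted for the two unit conventions
#' that matter: the long-term `gamma` is interpreted per `gamma_dose_scale`
#' Gy of accumulated dose, and the proportional error is interpreted as a
#' fraction (0.35 means a 35% CV).
#'
#' @param path path to a JSON parameter file (see
#'   `system.file("extdata", "published_parameters.json", package =
#'   "radtse")` for the bundled published estimates).
#' @param quiet suppress the loading notes.
#' @return A [tgi_params()] or [population_model()] object.
#' @export
read_parameters <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  x <- jsonlite::fromJSON(path)
  required <- c("kg", "kk", "alpha", "gamma", "v0")
  for (f in required)
    if (is.null(x[[f]])) stop("parameter file is missing required field '", f, "'")
  scale <- if (is.null(x$gamma_dose_scale)) 10 else x$gamma_dose_scale
  if (!quiet) {
    message(sprintf(paste0("note: gamma is interpreted per %g Gy of ",
                           "accumulated dose (effective dose D_acc/%g)"),
                    scale, scale))
  }
  inh <- if (is.null(x$inhibition)) "linear" else x$inhibition
  # "Inf" marks an alpha-only linear-quadratic kill (quadratic term off)
  abr <- if (is.null(x$alpha_beta_ratio)) 10 else as.numeric(x$alpha_beta_ratio)
  id50 <- if (is.null(x$id50)) NULL else x$id50
  if (length(x$gamma) > 1L || is.list(x$gamma)) {
    for (f in c("bsv", "sigma"))
      if (is.null(x[[f]])) stop("parameter file is missing required field '", f, "'")
    if (!quiet)
      message(sprintf(paste0("note: sigma_prop = %g is interpreted as a ",
                             "fraction (%g%% CV)"),
                      x$sigma$prop, 100 * x$sigma$prop))
    conv <- if (!is.null(x$bsv$convention) && x$bsv$convention == "cv_percent")
      "cv_percent" else "sd"
    om <- c(gamma = x$bsv$gamma, alpha = x$bsv$alpha, v0 = x$bsv$v0)
    if (conv == "sd") om <- om / 100  # printed as 100 * omega
    population_model(kg = x$kg, kk = x$kk, alpha = x$alpha,
                     gamma = unlist(x$gamma), v0 = unlist(x$v0),
                     potency = lapply(x$potency, function(p)
                       c(a = p$a, b = p$b)),
                     omega = om,
                     sigma = c(prop = x$sigma$prop, add = x$sigma$add),
                     inhibition = inh, id50 = id50, alpha_beta_ratio = abr,
                     gamma_dose_scale = scale,
                     bsv_convention = if (conv == "sd") "sd" else "cv_percent")
  } else {
    tgi_params(kg = x$kg, kk = x$kk, alpha = x$alpha, gamma = x$gamma,
               a = if (is.null(x$a)) 0 else x$a,
               b = if (is.null(x$b)) 0 else x$b,
               v0 = x$v0, inhibition = inh, id50 = id50,
               alpha_beta_ratio = abr, gamma_dose_scale = scale)
  }
}

#' Write parameters to JSON
#'
#' Inverse of [read_parameters()]; `read_parameters(write_parameters(x, f))`
#' reproduces `x`.
#'
#' @param x a [tgi_params()] or [population_model()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(x, path) {
  if (inherits(x, "tgi_population")) {
    out <- list(kg = x$kg, kk = x$kk, alpha = x$alpha,
                gamma = as.list(x$gamma), v0 = as.list(x$v0),
                potency = lapply(x$potency, function(p)
                  list(a = unname(p["a"]), b = unname(p["b"]))),
                bsv = list(gamma = 100 * unname(x$omega["gamma"]),
                           alpha = 100 * unname(x$omega["alpha"]),
                           v0 = 100 * unname(x$omega["v0"]),
                           convention = "sd_times_100"),
                sigma = list(prop = unname(x$sigma["prop"]),
                             add = unname(x$sigma["add"])),
                inhibition = x$inhibition,
                alpha_beta_ratio = if (is.finite(x$alpha_beta_ratio))
                  x$alpha_beta_ratio else "Inf",
                gamma_dose_scale = x$gamma_dose_scale)
    if (!is.na(x$id50)) out$id50 <- x$id50
  } else {
    out <- list(kg = x$kg, kk = x$kk, alpha = x$alpha, gamma = x$gamma,
                a = x$a, b = x$b, v0 = x$v0, inhibition = x$inhibition,
                alpha_beta_ratio = if (is.finite(x$alpha_beta_ratio))
                  x$alpha_beta_ratio else "Inf",
                gamma_dose_scale = x$gamma_dose_scale)
    if (!is.na(x$id50)) out$id50 <- x$id50
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Published population estimates
#'
#' The population parameter estimates of the three-study joint fit, as
#' bundled with the package: global rates `kg = 0.44`, `kk = 0.3` 1/day,
#' `alpha = 0.06` 1/Gy, per-study `gamma` and `v0` medians, per-compound
#' potencies, lognormal between-subject SDs and the combined residual
#' error.
#'
#' @param quiet suppress the unit-convention loading notes (default TRUE).
#' @return A [population_model()].
#' @examples
#' pop <- published_population()
#' pop
#' @export
published_population <- function(quiet = TRUE) {
  read_parameters(system.file("extdata", "published_parameters.json",
                              package = "radtse"), quiet = quiet)
}

#' Bundled three-study designs
#'
#' The arm structure of the three xenograft efficacy studies: group sizes
#' 9-10, 1 or 6 weeks of Monday-Friday treatment at 2 Gy per fraction, and
#' the observed mean maximum radiosensitizer concentration of each arm.
#' Tumor volumes are observed twice weekly; the highest-dose 1-week arm is
#' followed for 120 days.
#'
#' @param n_per_arm optional override of every arm size (used to scale
#'   simulation studies down).
#' @return A list of [study_design()] objects.
#' @examples
#' designs <- default_study_designs()
#' designs[[1]]
#' @export
default_study_designs <- function(n_per_arm = NULL) {
  x <- jsonlite::fromJSON(system.file("extdata", "study_designs.json",
                                      package = "radtse"),
                          simplifyDataFrame = TRUE)
  lapply(seq_len(nrow(x$studies)), function(i) {
    st <- x$studies[i, ]
    arms <- st$arms[[1L]]
    arms$compound[arms$compound == ""] <- NA_character_
    names(arms)[names(arms) == "conc_ug_ml"] <- "conc"
    if (is.null(arms$horizon)) arms$horizon <- st$horizon_day
    arms$horizon[is.na(arms$horizon)] <- st$horizon_day
    if (!is.null(n_per_arm)) arms$n <- n_per_arm
    study_design(study = st$study, weeks = st$weeks, arms = arms,
                 fraction_dose = x$fraction_dose_gy,
                 fractions_per_week = x$fractions_per_week,
                 horizon = st$horizon_day)
  })
}

#' Read/write a regimen as a delimited table
#'
#' Comma-separated table with columns `time_day`, `dose_gy`, `conc_ug_ml`.
#'
#' @param path file path.
#' @param horizon simulation horizon for [read_regimen()] (default: 21 days
#'   after the last application).
#' @return [read_regimen()] returns a [regimen()]; [write_regimen()]
#'   returns `path` invisibly.
#' @export
read_regimen <- function(path, horizon = NULL) {
  df <- read.csv(path)
  need <- c("time_day", "dose_gy", "conc_ug_ml")
  if (!all(need %in% names(df)))
    stop("regimen file must have columns ", paste(need, collapse = ", "))
  regimen(time = df$time_day, dose = df$dose_gy, conc = df$conc_ug_ml,
          horizon = horizon)
}

#' @rdname read_regimen
#' @param reg a [regimen()].
#' @export
write_regimen <- function(reg, path) {
  write.csv(data.frame(time_day = reg$time, dose_gy = reg$dose,
                       conc_ug_ml = reg$conc),
            path, row.names = FALSE)
  invisible(path)
}

#' Export a simulated trajectory as a delimited table
#'
#' Comma-separated table with columns `time_day`, `v1..v4`, `u1`, `u2`,
#' `v_tot`.
#'
#' @param traj a `tgi_trajectory` from [simulate_tumor()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  out <- data.frame(time_day = traj$time, traj[, c("v1", "v2", "v3", "v4",
                                                   "u1", "u2", "v_tot")])
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read/write a TSE curve with its metadata sidecar
#'
#' The curve itself is a comma-separated table `conc_ug_ml`,
#' `total_dose_gy`; the settings that produced it (method, percentile,
#' t*, epsilon, schedule, number of subjects, seed) are stored in a JSON
#' sidecar at `paste0(path, ".json")`.
#'
#' @param curve a `tse_curve`.
#' @param path curve file path.
#' @return [read_tse_curve()] returns a `tse_curve`; [write_tse_curve()]
#'   returns `path` invisibly.
#' @export
write_tse_curve <- function(curve, path) {
  write.csv(data.frame(conc_ug_ml = curve$conc, total_dose_gy = curve$dose),
            path, row.names = FALSE)
  meta <- list(method = attr(curve, "method"),
               percentile = attr(curve, "percentile"),
               t_star = attr(curve, "t_star"),
               epsilon = attr(curve, "epsilon"),
               schedule = attr(curve, "schedule"),
               n_subjects = attr(curve, "n_subjects"),
               seed = attr(curve, "seed"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tse_curve
#' @export
read_tse_curve <- function(path) {
  df <- read.csv(path)
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  problem <- list(t_star = meta$t_star, epsilon = meta$epsilon,
                  schedule = meta$schedule)
  .new_tse_curve(df$conc_ug_ml, df$total_dose_gy, method = meta$method,
                 percentile = meta$percentile, problem = problem,
                 n_subjects = if (is.null(meta$n_subjects)) NA_integer_ else meta$n_subjects,
                 seed = if (is.null(meta$seed)) NA_integer_ else meta$seed)
}

#' Read/write a long-format observation table
#'
#' Comma-separated long format with columns `study`, `arm`, `subject`,
#' `time_day`, `volume_mm3` (plus `compound`, `conc_ug_ml` when available).
#'
#' @param ds a `tgi_dataset` (or a bare observations data frame with the
#'   same columns).
#' @param path file path.
#' @return [read_dataset()] returns the observations data frame;
#'   [write_dataset()] returns `path` invisibly.
#' @export
write_dataset <- function(ds, path) {
  obs <- if (inherits(ds, "tgi_dataset")) ds$observations else ds
  out <- data.frame(study = obs$study, arm = obs$arm,
                    compound = obs$compound, conc_ug_ml = obs$conc,
                    subject = obs$subject, time_day = obs$time,
                    volume_mm3 = obs$volume)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- read.csv(path)
  need <- c("study", "arm", "subject", "time_day", "volume_mm3")
  if (!all(need %in% names(df)))
    stop("observation file must have columns ", paste(need, collapse = ", "))
  data.frame(study = df$study, arm = df$arm,
             compound = if (is.null(df$compound)) "" else df$compound,
             conc = if (is.null(df$conc_ug_ml)) 0 else df$conc_ug_ml,
             subject = df$subject, time = df$time_day,
             volume = df$volume_mm3)
}
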