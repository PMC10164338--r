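#' Population (NLME) model of the xenograft studies
#'
#' Encodes the nonlinear mixed-effects structure estimated on the three
#' xenograft studies: global median rates, study-specific medians for the
#' long-term inhibition coefficient `gamma` and the initial proliferating
#' volume `v0` (inter-study variability as study-indexed fixed effects),
#' lognormal between-subject variability on `gamma`, `alpha` and `v0`
#' (diagonal, no correlation), per-compound potencies, and a combined
#' proportional + additive residual error.
#'
#' An individual's `gamma` is `gamma[study] * exp(eta)` with
#' `eta ~ N(0, omega_gamma^2)`; `alpha` and `v0` are analogous (with a
#' global median for `alpha`).
#'
#' @param kg,kk,alpha global median rates (see [tgi_params()]).
#' @param gamma named or unnamed numeric vector of per-study medians
#'   (length = number of studies).
#' @param v0 per-study median initial proliferating volumes, mm^3.
#' @param potency named list of compounds, each `c(a = , b = )` in mL/ug.
#' @param omega lognormal between-subject SDs,
#'   `c(gamma = , alpha = , v0 = )`.  When `bsv_convention = "cv_percent"`
#'   the supplied values are instead treated as CV% and converted with
#'   `omega = sqrt(log(1 + cv^2))`.
#' @param sigma residual error, `c(prop = , add = )`: proportional SD as a
#'   fraction and additive SD in mm^3.
#' @param inhibition,id50,alpha_beta_ratio,gamma_dose_scale see
#'   [tgi_params()].
#' @param bsv_convention how `omega` is specified: `"sd"` (default; the
#'   printed between-subject variability values divided by 100) or
#'   `"cv_percent"`.
#' @return An object of class `tgi_population`.
#' @seealso [published_population()] for the bundled published estimates.
#' @export
population_model <- function(kg = 0.44, kk = 0.3, alpha = 0.06,
                             gamma = c(study1 = 0.027, study2 = 0.044,
                                       study3 = 0.02),
                             v0 = c(study1 = 26, study2 = 44, study3 = 22),
                             potency = list(Rs1 = c(a = 0.65, b = 0.26),
                                            Rs2 = c(a = 0.2, b = 0.4),
                                            Rs3 = c(a = 0.14, b = 0.16)),
                             omega = c(gamma = 0.64, alpha = 0.5, v0 = 0.4),
                             sigma = c(prop = 0.35, add = 4.4),
                             inhibition = c("linear", "exponential",
                                            "saturating"),
                             id50 = NULL, alpha_beta_ratio = 10,
                             gamma_dose_scale = 10,
                             bsv_convention = c("sd", "cv_percent")) {
  inhibition <- match.arg(inhibition)
  bsv_convention <- match.arg(bsv_convention)
  if (length(gamma) != length(v0))
    stop("'gamma' and 'v0' must cover the same number of studies")
  if (any(gamma < 0) || any(v0 <= 0) || kg <= 0 || kk < 0 || alpha < 0)
    stop("medians must be positive (kk, alpha, gamma may be zero)")
  omega <- omega[c("gamma", "alpha", "v0")]
  sigma <- sigma[c("prop", "add")]
  if (anyNA(omega) || any(omega < 0)) stop("'omega' needs non-negative gamma/alpha/v0 entries")
  if (anyNA(sigma) || any(sigma < 0)) stop("'sigma' needs non-negative prop/add entries")
  if (bsv_convention == "cv_percent") omega <- sqrt(log(1 + (omega / 100)^2))
  if (is.null(names(gamma))) names(gamma) <- paste0("study", seq_along(gamma))
  if (is.null(names(v0))) names(v0) <- names(gamma)
  structure(list(kg = kg, kk = kk, alpha = alpha, gamma = gamma, v0 = v0,
                 potency = potency, omega = omega, sigma = sigma,
                 inhibition = inhibition,
                 id50 = if (is.null(id50)) NA_real_ else id50,
                 alpha_beta_ratio = alpha_beta_ratio,
                 gamma_dose_scale = gamma_dose_scale),
            class = "tgi_population")
}

#' @export
print.tgi_population <- function(x, ...) {
  cat("Population tumor-growth model\n")
  cat(sprintf("  kg = %.4g, kk = %.4g 1/day; alpha = %.4g 1/Gy; %s inhibition\n",
              x$kg, x$kk, x$alpha, x$inhibition))
  cat("  gamma medians:", paste(sprintf("%s = %.4g", names(x$gamma), x$gamma),
                                collapse = ", "), "\n")
  cat("  v0 medians:   ", paste(sprintf("%s = %.4g", names(x$v0), x$v0),
                                collapse = ", "), "\n")
  for (cmp in names(x$potency))
    cat(sprintf("  %s: a = %.4g, b = %.4g mL/ug\n", cmp,
                x$potency[[cmp]]["a"], x$potency[[cmp]]["b"]))
  cat(sprintf("  omega (lognormal SD): gamma %.3g, alpha %.3g, v0 %.3g\n",
              x$omega["gamma"], x$omega["alpha"], x$omega["v0"]))
  cat(sprintf("  residual error: %.3g proportional + %.3g mm^3 additive\n",
              x$sigma["prop"], x$sigma["add"]))
  invisible(x)
}

#' Subject-level parameters from a population model
#'
#' Builds a [tgi_params()] object for one individual of a given study,
#' applying multiplicative random effects `exp(eta)` to `gamma`, `alpha`
#' and `v0` (`eta = c(0, 0, 0)` gives the study median individual).
#'
#' @param pop a [population_model()].
#' @param study study index (1-based) selecting the `gamma`/`v0` medians.
#' @param compound compound name in `pop$potency`, or `NULL` for no drug.
#' @param eta numeric length-3 vector of random effects for
#'   (gamma, alpha, v0).
#' @return A [tgi_params()] object.
#' @export
subject_params <- function(pop, study = 3, compound = NULL,
                           eta = c(0, 0, 0)) {
  if (study < 1 || study > length(pop$gamma))
    stop("'study' must index one of the ", length(pop$gamma), " studies")
  ab <- c(a = 0, b = 0)
  if (!is.null(compound)) {
    if (is.null(pop$potency[[compound]]))
      stop("unknown compound: ", compound)
    ab <- pop$potency[[compound]]
  }
  tgi_params(kg = pop$kg, kk = pop$kk,
             alpha = pop$alpha * exp(eta[2L]),
             gamma = pop$gamma[[study]] * exp(eta[1L]),
             a = unname(ab["a"]), b = unname(ab["b"]),
             v0 = pop$v0[[study]] * exp(eta[3L]),
             inhibition = pop$inhibition,
             id50 = if (is.na(pop$id50)) NULL else pop$id50,
             alpha_beta_ratio = pop$alpha_beta_ratio,
             gamma_dose_scale = pop$gamma_dose_scale)
}

#' Draw virtual individuals from the population model
#'
#' Samples `eta ~ N(0, diag(omega^2))` per subject and returns the
#' corresponding individual parameter sets.  With all `omega` zero every
#' subject equals the study median.
#'
#' @inheritParams subject_params
#' @param n number of individuals.
#' @param seed optional integer seed (restores the caller's RNG state on
#'   exit); with `NULL` the current RNG stream is used.
#' @return A list of `n` [tgi_params()] objects with the drawn `eta`
#'   attached as attribute `"eta"`.
#' @export
sample_subjects <- function(pop, n, study = 3, compound = NULL,
                            seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  om <- pop$omega
  lapply(seq_len(n), function(i) {
    eta <- rnorm(3L, 0, om)
    p <- subject_params(pop, study = study, compound = compound, eta = eta)
    attr(p, "eta") <- eta
    p
  })
}

#' Apply the combined residual-error model
#'
#' Observation model `y = f * (1 + e1) + e2` with
#' `e1 ~ N(0, sigma_prop^2)`, `e2 ~ N(0, sigma_add^2)`, truncated at zero
#' (a measured volume cannot be negative).  Uses the current RNG stream.
#'
#' @param f noise-free volumes, mm^3.
#' @param pop a [population_model()] supplying `sigma`.
#' @return Observed volumes, mm^3.
#' @export
apply_residual_error <- function(f, pop) {
  stopifnot(all(f >= 0))
  y <- f * (1 + rnorm(length(f), 0, pop$sigma["prop"])) +
    rnorm(length(f), 0, pop$sigma["add"])
  pmax(y, 0)
}

#' Design of one xenograft study
#'
#' The arm structure of an efficacy study: each arm receives the listed
#' treatment 5 days a week (2 Gy per fraction for irradiated arms), with
#' the radiosensitizer given before each fraction so that its mean maximum
#' plasma concentration is the exposure driving the model.  Tumor volumes
#' are observed twice weekly.
#'
#' @param study study index.
#' @param weeks treatment weeks.
#' @param arms data frame with columns `label`, `compound` (name or `NA`),
#'   `conc` (ug/mL), `n` (subjects), `radiation` (logical) and optionally
#'   `horizon` (days; defaults to `horizon`).
#' @param fraction_dose Gy per fraction for irradiated arms.
#' @param fractions_per_week applications per week.
#' @param horizon default observation end, days.
#' @param obs_days observation days; default twice weekly (days 0 and 3 of
#'   each week) from 0 up to each arm's horizon.
#' @return An object of class `study_design`.
#' @seealso [default_study_designs()] for the bundled three-study layout.
#' @export
study_design <- function(study, weeks, arms, fraction_dose = 2,
                         fractions_per_week = 5, horizon = 80,
                         obs_days = NULL) {
  need <- c("label", "compound", "conc", "n", "radiation")
  if (!all(need %in% names(arms)))
    stop("'arms' must have columns ", paste(need, collapse = ", "))
  if (any(arms$n < 1)) stop("arm sizes must be >= 1")
  if (is.null(arms$horizon)) arms$horizon <- horizon
  structure(list(study = study, weeks = weeks, arms = arms,
                 fraction_dose = fraction_dose,
                 fractions_per_week = fractions_per_week,
                 obs_days = obs_days),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study %s design: %d week(s) of treatment, %d arm(s)\n",
              format(x$study), x$weeks, nrow(x$arms)))
  print.data.frame(x$arms)
  invisible(x)
}

# twice-weekly observation grid (days 0 and 3 of each week) up to horizon
.obs_grid <- function(horizon) {
  days <- sort(c(7 * (0:ceiling(horizon / 7)), 7 * (0:ceiling(horizon / 7)) + 3))
  days[days <= horizon]
}

.arm_regimen <- function(design, arm_row) {
  if (isTRUE(arm_row$radiation)) {
    fractionated_regimen(weeks = design$weeks,
                         fractions_per_week = design$fractions_per_week,
                         fraction_dose = design$fraction_dose,
                         conc = arm_row$conc, horizon = arm_row$horizon)
  } else {
    regimen(horizon = arm_row$horizon)
  }
}

# deterministic per-subject substream: reproducible under arm subsetting
.subject_seed <- function(master, study, arm_idx, subj_idx) {
  as.integer((as.numeric(master) + 99991 * (100 * study + arm_idx) +
                7919 * subj_idx) %% 2147483629)
}

#' Generate a fully synthetic xenograft study
#'
#' Emulates one efficacy study: for every subject of every arm, individual
#' parameters are drawn from the population model, the arm's regimen is
#' simulated, and the noise-free volumes at the twice-weekly observation
#' days are perturbed with the combined residual-error model.  Each subject
#' gets its own deterministic RNG substream derived from `seed`, so a
#' dataset is bit-reproducible and arms can be regenerated independently.
#'
#' @param pop a [population_model()].
#' @param design a [study_design()] (or list of designs for
#'   [synthesize_studies()]).
#' @param seed master integer seed.
#' @return An object of class `tgi_dataset`: a list with `observations`
#'   (study, arm, compound, conc, subject, time, volume), `subjects` (the
#'   true individual parameters), `designs`, and `seed`.
#' @examples
#' pop <- published_population()
#' ds <- synthesize_study(pop, default_study_designs()[[3]], seed = 7)
#' head(ds$observations)
#' @export
synthesize_study <- function(pop, design, seed = 1L) {
  synthesize_studies(pop, list(design), seed = seed)
}

#' @rdname synthesize_study
#' @param designs list of [study_design()] objects.
#' @export
synthesize_studies <- function(pop, designs, seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  obs_list <- list(); subj_list <- list()
  for (design in designs) {
    for (ai in seq_len(nrow(design$arms))) {
      arm <- design$arms[ai, ]
      reg <- .arm_regimen(design, arm)
      days <- if (is.null(design$obs_days)) .obs_grid(arm$horizon) else
        design$obs_days[design$obs_days <= arm$horizon]
      if (length(days) < 2L) stop("every subject needs >= 2 observations")
      cmp <- if (is.na(arm$compound)) NULL else arm$compound
      for (j in seq_len(arm$n)) {
        set.seed(.subject_seed(seed, design$study, ai, j))
        eta <- rnorm(3L, 0, pop$omega)
        p <- subject_params(pop, study = design$study, compound = cmp,
                            eta = eta)
        f <- .cpp_pred(.par_vec(p), reg$time, reg$dose, reg$conc, days)
        y <- apply_residual_error(f, pop)
        id <- sprintf("S%d_A%d_%02d", design$study, ai, j)
        obs_list[[id]] <- data.frame(
          study = design$study, arm = arm$label,
          compound = ifelse(is.na(arm$compound), "", arm$compound),
          conc = arm$conc, subject = id, time = days, volume = y)
        subj_list[[id]] <- data.frame(
          study = design$study, arm = arm$label, subject = id,
          gamma = p$gamma, alpha = p$alpha, v0 = p$v0)
      }
    }
  }
  structure(list(observations = do.call(rbind, c(obs_list, make.row.names = FALSE)),
                 subjects = do.call(rbind, c(subj_list, make.row.names = FALSE)),
                 designs = designs, seed = seed),
            class = "tgi_dataset")
}

#' @export
print.tgi_dataset <- function(x, ...) {
  cat(sprintf("Synthetic xenograft dataset: %d observations, %d subjects, %d study(ies), seed %d\n",
              nrow(x$observations), nrow(x$subjects), length(x$designs),
              x$seed))
  invisible(x)
}

#' Fraction of eradicated tumors in a simulated arm
#'
#' Simulates `n` subjects of one design arm and reports the fraction whose
#' noise-free total volume at the end of the arm's observation period is
#' below `threshold` (eradication is not defined numerically in the
#' underlying studies; 1 mm^3 on the noise-free volume is the package
#' default).
#'
#' @param pop a [population_model()].
#' @param design a [study_design()].
#' @param arm arm label within the design.
#' @param n number of simulated subjects; defaults to the arm's size.
#' @param seed master integer seed.
#' @param threshold eradication threshold, mm^3.
#' @return Fraction in `[0, 1]`.
#' @export
eradication_fraction <- function(pop, design, arm, n = NULL, seed = 1L,
                                 threshold = 1) {
  ai <- match(arm, design$arms$label)
  if (is.na(ai)) stop("unknown arm label: ", arm)
  row <- design$arms[ai, ]
  if (is.null(n)) n <- row$n
  reg <- .arm_regimen(design, row)
  cmp <- if (is.na(row$compound)) NULL else row$compound
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  end_vol <- vapply(seq_len(n), function(j) {
    set.seed(.subject_seed(seed, design$study, ai, j))
    eta <- rnorm(3L, 0, pop$omega)
    p <- subject_params(pop, study = design$study, compound = cmp, eta = eta)
    .cpp_pred(.par_vec(p), reg$time, reg$dose, reg$conc, row$horizon)
  }, numeric(1L))
  mean(end_vol < threshold)
}
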