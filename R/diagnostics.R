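#' Select the long-term inhibition function by AIC
#'
#' Fits the population model once per candidate inhibition function
#' (linear, exponential, saturating) on the same data and returns the
#' variant with the smallest AIC (`AIC = 2k - 2 lnL`); exact ties are
#' broken toward the variant with fewer estimated parameters (the
#' saturating variant carries the extra `ID50`).
#'
#' @param dataset a `tgi_dataset` (see [fit_population()]).
#' @param inits named list of [population_model()] initial values, one per
#'   variant to compare; names are the variant names.
#' @param settings a [fit_settings()] shared by all fits.
#' @return A list of class `tgi_variant_selection`: `best` (variant name),
#'   `table` (variant, df, logLik, AIC), `fits`.
#' @export
select_inhibition_variant <- function(dataset, inits,
                                      settings = fit_settings()) {
  stopifnot(length(inits) >= 2L, !is.null(names(inits)))
  fits <- lapply(inits, function(ini) {
    st <- settings
    if (ini$inhibition == "saturating" && !"id50" %in% st$free)
      st$free <- c(st$free, "id50")
    fit_population(dataset, init = ini, settings = st)
  })
  tab <- data.frame(variant = names(fits),
                    df = vapply(fits, `[[`, 0, "df"),
                    logLik = vapply(fits, `[[`, 0, "logLik"),
                    AIC = vapply(fits, `[[`, 0, "AIC"),
                    row.names = NULL)
  o <- order(tab$AIC, tab$df)
  structure(list(best = tab$variant[o[1L]], table = tab[o, ], fits = fits),
            class = "tgi_variant_selection")
}

#' @export
print.tgi_variant_selection <- function(x, ...) {
  cat("Inhibition-variant selection (smaller AIC is better):\n")
  print(transform(x$table, dAIC = AIC - min(AIC)), row.names = FALSE)
  cat("selected:", x$best, "\n")
  invisible(x)
}

#' Visual-predictive-check summary
#'
#' Simulates `n_replicates` datasets under the study designs from the
#' population model and summarises, per study, arm and observation time,
#' the distribution of the simulated median volume against the observed
#' median.  The output is numeric; `plot()` draws the bands per arm.
#'
#' @param dataset a `tgi_dataset` holding the observed data and designs.
#' @param pop the [population_model()] to simulate from.
#' @param n_replicates number of simulated replicate datasets.
#' @param seed master seed of the first replicate.
#' @param probs lower/upper band probabilities of the simulated medians
#'   (default 90% band).
#' @return Data frame of class `tgi_vpc` with columns `study`, `arm`,
#'   `time`, `obs_median`, `sim_median`, `lo`, `hi`.
#' @export
vpc_summary <- function(dataset, pop, n_replicates = 200, seed = 1L,
                        probs = c(0.05, 0.95)) {
  stopifnot(n_replicates >= 2L)
  obs <- dataset$observations
  key <- interaction(obs$study, obs$arm, obs$time, drop = TRUE)
  obs_med <- tapply(obs$volume, key, median)
  sims <- matrix(NA_real_, length(obs_med), n_replicates,
                 dimnames = list(names(obs_med), NULL))
  for (r in seq_len(n_replicates)) {
    sim <- synthesize_studies(pop, dataset$designs, seed = seed + r - 1L)
    so <- sim$observations
    skey <- interaction(so$study, so$arm, so$time, drop = TRUE)
    med <- tapply(so$volume, skey, median)
    sims[, r] <- med[rownames(sims)]
  }
  parts <- do.call(rbind, strsplit(names(obs_med), ".", fixed = TRUE))
  out <- data.frame(study = as.numeric(parts[, 1L]), arm = parts[, 2L],
                    time = as.numeric(parts[, 3L]),
                    obs_median = as.numeric(obs_med),
                    sim_median = apply(sims, 1L, median),
                    lo = apply(sims, 1L, quantile, probs = probs[1L]),
                    hi = apply(sims, 1L, quantile, probs = probs[2L]),
                    row.names = NULL)
  out <- out[order(out$study, out$arm, out$time), ]
  rownames(out) <- NULL
  class(out) <- c("tgi_vpc", "data.frame")
  out
}

#' @export
plot.tgi_vpc <- function(x, study = NULL, arm = NULL, ...) {
  df <- as.data.frame(x)
  if (is.null(study)) study <- df$study[1L]
  df <- df[df$study == study, ]
  if (is.null(arm)) arm <- df$arm[1L]
  df <- df[df$arm == arm, ]
  graphics::plot(df$time, df$obs_median, ylim = range(df[, 4:7]),
                 xlab = "time (days)", ylab = "median volume (mm^3)",
                 main = sprintf("study %s, arm %s", study, arm), ...)
  lines(df$time, df$sim_median)
  lines(df$time, df$lo, lty = 2)
  lines(df$time, df$hi, lty = 2)
  invisible(x)
}

#' Local sensitivity of the volume at the evaluation time
#'
#' Central finite-difference relative sensitivities of the median subject's
#' total volume at `t_star` with respect to each model parameter, per
#' treatment group, normalized so the largest magnitude within each group
#' is 1.  Study-specific parameters are lumped (the active `gamma`/`v0`
#' median of each group contributes to a single lumped row), and compound
#' potencies are 0 in groups without that effect; the summary columns give
#' the mean and SD of the normalized sensitivity over the groups in which
#' the parameter is present.
#'
#' @param pop a [population_model()].
#' @param designs list of [study_design()] (default the bundled designs).
#' @param t_star evaluation time, days.
#' @param perturbation relative finite-difference step.
#' @return A list of class `sensitivity_table`: `normalized` (parameter x
#'   group matrix), `mean`, `sd`, `ranking` (parameters by decreasing mean
#'   absolute normalized sensitivity).
#' @export
local_sensitivity <- function(pop, designs = default_study_designs(),
                              t_star = 60, perturbation = 0.01) {
  stopifnot(perturbation > 0)
  pars <- c("kg", "kk", "alpha", "gamma", "v0", "a", "b")
  groups <- list()
  for (d in designs)
    for (ai in seq_len(nrow(d$arms)))
      groups[[sprintf("S%d:%s", d$study, d$arms$label[ai])]] <-
        list(design = d, arm = d$arms[ai, ])
  h <- perturbation
  vol_at <- function(p, reg) {
    .cpp_pred(.par_vec(p), reg$time, reg$dose, reg$conc, t_star)
  }
  S <- matrix(0, length(pars), length(groups),
              dimnames = list(pars, names(groups)))
  present <- S > 1 # all FALSE
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    cmp <- if (is.na(g$arm$compound)) NULL else g$arm$compound
    base <- subject_params(pop, study = g$design$study, compound = cmp)
    reg <- .arm_regimen(g$design, g$arm)
    v0_val <- vol_at(base, reg)
    irradiated <- isTRUE(g$arm$radiation)
    for (pn in pars) {
      if (pn %in% c("a", "b") && (is.null(cmp) || !irradiated)) next
      if (pn %in% c("gamma", "alpha") && !irradiated) next
      up <- base; up[[pn]] <- base[[pn]] * (1 + h)
      dn <- base; dn[[pn]] <- base[[pn]] * (1 - h)
      S[pn, gi] <- (vol_at(up, reg) - vol_at(dn, reg)) / (2 * h * v0_val)
      present[pn, gi] <- TRUE
    }
    mx <- max(abs(S[, gi]))
    if (mx > 0) S[, gi] <- S[, gi] / mx
  }
  mn <- vapply(pars, function(pn) mean(abs(S[pn, present[pn, ]])), 0)
  sdev <- vapply(pars, function(pn) {
    v <- abs(S[pn, present[pn, ]])
    if (length(v) > 1L) stats::sd(v) else NA_real_
  }, 0)
  structure(list(normalized = S, mean = mn, sd = sdev,
                 ranking = names(sort(mn, decreasing = TRUE)),
                 t_star = t_star, perturbation = perturbation),
            class = "sensitivity_table")
}

#' @export
print.sensitivity_table <- function(x, ...) {
  cat(sprintf("Normalized local sensitivities of V_tot(t* = %g d)\n",
              x$t_star))
  tab <- data.frame(mean_abs = round(x$mean, 3), sd = round(x$sd, 3))
  print(tab[order(-tab$mean_abs), ])
  cat("ranking:", paste(x$ranking, collapse = " > "), "\n")
  invisible(x)
}
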