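#' Settings for the population fit
#'
#' @param free parameters to estimate.  Group names expand to their
#'   elements: `"gamma"`/`"v0"` to all per-study medians, `"a"`/`"b"` to
#'   all per-compound potencies, `"omega"` and `"sigma"` to their
#'   components.  Exact element names (e.g. `"gamma_3"`, `"a_Rs1"`) are
#'   also accepted.
#' @param n_starts number of optimizer starts; starts after the first are
#'   log-perturbed copies of the initial values.
#' @param start_sd SD of the lognormal start perturbation.
#' @param maxit maximum outer iterations per start.
#' @param rel_tol relative objective-change convergence tolerance.
#' @param compute_rse compute relative standard errors from the observed
#'   information at the optimum (adds a numerical Hessian; switch off for
#'   large simulation studies).
#' @param seed seed for the start perturbations.
#' @return A list of class `fit_settings`.
#' @export
fit_settings <- function(free = c("kg", "kk", "alpha", "gamma", "v0",
                                  "a", "b", "omega", "sigma"),
                         n_starts = 5, start_sd = 0.2, maxit = 200,
                         rel_tol = 1e-6, compute_rse = TRUE, seed = 1L) {
  structure(list(free = free, n_starts = n_starts, start_sd = start_sd,
                 maxit = maxit, rel_tol = rel_tol,
                 compute_rse = compute_rse, seed = seed),
            class = "fit_settings")
}

# per-subject fitting units: observation vectors plus the arm's regimen
.prep_subjects <- function(dataset) {
  obs <- dataset$observations
  designs <- dataset$designs
  dmap <- list()
  for (d in designs) dmap[[as.character(d$study)]] <- d
  ids <- unique(obs$subject)
  lapply(ids, function(id) {
    o <- obs[obs$subject == id, , drop = FALSE]
    o <- o[order(o$time), , drop = FALSE]
    d <- dmap[[as.character(o$study[1L])]]
    if (is.null(d)) stop("no design found for study ", o$study[1L])
    ai <- match(o$arm[1L], d$arms$label)
    if (is.na(ai)) stop("no arm '", o$arm[1L], "' in study ", d$study)
    reg <- .arm_regimen(d, d$arms[ai, ])
    cmp <- o$compound[1L]
    list(subject = id, study = o$study[1L],
         compound = if (is.na(cmp) || cmp == "") NULL else cmp,
         time = reg$time, dose = reg$dose, conc = reg$conc,
         obs_t = o$time, obs_y = o$volume)
  })
}

# full named parameter vector of a population model (theta scale)
.pop_theta <- function(pop) {
  th <- c(kg = pop$kg, kk = pop$kk, alpha = pop$alpha)
  K <- length(pop$gamma)
  th <- c(th, setNames(as.numeric(pop$gamma), paste0("gamma_", seq_len(K))),
          setNames(as.numeric(pop$v0), paste0("v0_", seq_len(K))))
  for (cmp in names(pop$potency))
    th <- c(th, setNames(as.numeric(pop$potency[[cmp]][c("a", "b")]),
                         paste0(c("a_", "b_"), cmp)))
  if (pop$inhibition == "saturating") th <- c(th, id50 = pop$id50)
  c(th,
    omega_gamma = unname(pop$omega["gamma"]),
    omega_alpha = unname(pop$omega["alpha"]),
    omega_v0 = unname(pop$omega["v0"]),
    sigma_prop = unname(pop$sigma["prop"]),
    sigma_add = unname(pop$sigma["add"]))
}

.theta_pop <- function(th, template) {
  K <- length(template$gamma)
  pot <- template$potency
  for (cmp in names(pot))
    pot[[cmp]] <- c(a = unname(th[paste0("a_", cmp)]),
                    b = unname(th[paste0("b_", cmp)]))
  population_model(kg = unname(th["kg"]), kk = min(unname(th["kk"]), unname(th["kg"])),
                   alpha = unname(th["alpha"]),
                   gamma = setNames(unname(th[paste0("gamma_", seq_len(K))]),
                                    names(template$gamma)),
                   v0 = setNames(unname(th[paste0("v0_", seq_len(K))]),
                                 names(template$v0)),
                   potency = pot,
                   omega = c(gamma = unname(th["omega_gamma"]),
                             alpha = unname(th["omega_alpha"]),
                             v0 = unname(th["omega_v0"])),
                   sigma = c(prop = unname(th["sigma_prop"]),
                             add = unname(th["sigma_add"])),
                   inhibition = template$inhibition,
                   id50 = if (template$inhibition == "saturating")
                     unname(th["id50"]) else NULL,
                   alpha_beta_ratio = template$alpha_beta_ratio,
                   gamma_dose_scale = template$gamma_dose_scale)
}

.expand_free <- function(free, theta_names) {
  out <- character()
  for (f in free) {
    hit <- switch(f,
                  gamma = grep("^gamma_", theta_names, value = TRUE),
                  v0 = grep("^v0_", theta_names, value = TRUE),
                  a = grep("^a_", theta_names, value = TRUE),
                  b = grep("^b_", theta_names, value = TRUE),
                  omega = grep("^omega_", theta_names, value = TRUE),
                  sigma = grep("^sigma_", theta_names, value = TRUE),
                  f)
    out <- c(out, hit)
  }
  out <- intersect(unique(out), theta_names)
  if (!length(out)) stop("no free parameters selected")
  out
}

# numeric parameter vector for one subject given the full theta vector
.subject_parvec <- function(th, s, kind, abr, dscale) {
  gk <- th[[paste0("gamma_", s$study)]]
  vk <- th[[paste0("v0_", s$study)]]
  if (is.null(s$compound)) { a <- 0; b <- 0 } else {
    a <- th[[paste0("a_", s$compound)]]
    b <- th[[paste0("b_", s$compound)]]
  }
  id50 <- if (kind == 2L) th[["id50"]] else 1
  c(th[["kg"]], th[["kk"]], th[["alpha"]], abr, gk, id50, a, b, vk, kind,
    dscale)
}

#' Fit the population model to longitudinal tumor-volume data
#'
#' Maximizes a Laplace (FOCE-type) approximation to the marginal likelihood
#' of the nonlinear mixed-effects model: lognormal random effects on
#' `gamma`, `alpha` and `v0` (diagonal covariance), study-specific medians
#' for `gamma` and `v0`, and the combined proportional + additive residual
#' error.  Each subject's random-effect mode is located by damped
#' Gauss-Newton; the marginal contribution uses the Gauss-Newton
#' (expected-information) Hessian at the mode.  All parameters are
#' estimated on the log scale; relative standard errors come from the
#' inverse observed information at the optimum (delta method on the log
#' scale).
#'
#' @param dataset a `tgi_dataset` from [synthesize_study()], or any list
#'   with `observations` (columns `study`, `arm`, `compound`, `subject`,
#'   `time`, `volume`) and `designs` (list of [study_design()]).
#' @param init a [population_model()] holding initial values (and the
#'   values of fixed parameters).
#' @param settings a [fit_settings()] list.
#' @return An object of class `tgi_fit` with methods [print()],
#'   [summary()], [coef()], [logLik()], [predict.tgi_fit()],
#'   [residuals.tgi_fit()] and [simulate.tgi_fit()].
#' @examples
#' \donttest{
#' pop <- published_population()
#' ds <- synthesize_study(pop, default_study_designs(n_per_arm = 3)[[3]],
#'                        seed = 42)
#' fit <- fit_population(ds, init = pop,
#'                       settings = fit_settings(free = c("gamma", "alpha", "v0"),
#'                                               n_starts = 1,
#'                                               compute_rse = FALSE))
#' coef(fit)
#' }
#' @export
fit_population <- function(dataset, init = published_population(),
                           settings = fit_settings()) {
  subs <- .prep_subjects(dataset)
  studies <- unique(vapply(subs, `[[`, numeric(1L), "study"))
  if (length(studies) > 1L &&
      any(table(vapply(subs, `[[`, numeric(1L), "study")) < 2L))
    stop("each represented study needs at least 2 subjects")
  theta0 <- .pop_theta(init)
  free <- .expand_free(settings$free, names(theta0))
  # parameters of studies/compounds not represented in the data are flat
  # directions; drop them from the free set
  present_studies <- sort(unique(vapply(subs, `[[`, numeric(1L), "study")))
  present_cmp <- unique(unlist(lapply(subs, `[[`, "compound")))
  K <- length(init$gamma)
  drop <- c(paste0("gamma_", setdiff(seq_len(K), present_studies)),
            paste0("v0_", setdiff(seq_len(K), present_studies)))
  for (cmp in names(init$potency))
    if (!cmp %in% present_cmp) drop <- c(drop, paste0(c("a_", "b_"), cmp))
  free <- setdiff(free, drop)
  if (!length(free)) stop("no free parameters are informed by the data")
  kind <- match(init$inhibition, c("linear", "exponential", "saturating")) - 1L
  abr <- init$alpha_beta_ratio; dscale <- init$gamma_dose_scale

  # zero initial values cannot be log-perturbed; nudge free ones
  th_work <- theta0
  th_work[free][th_work[free] <= 0] <- 0.05
  phi0 <- log(th_work[free])

  n <- length(subs)
  eta_hat <- matrix(0, n, 3L)
  # the inner modes are always located from eta = 0 so the objective is a
  # deterministic function of phi (finite-difference outer gradients need
  # this); set collect = TRUE to harvest the empirical Bayes estimates
  obj <- function(phi, collect = FALSE) {
    th <- th_work
    th[free] <- exp(phi)
    om <- c(th[["omega_gamma"]], th[["omega_alpha"]], th[["omega_v0"]])
    sp <- th[["sigma_prop"]]; sa <- th[["sigma_add"]]
    nll <- 0
    for (i in seq_len(n)) {
      s <- subs[[i]]
      pv <- .subject_parvec(th, s, kind, abr, dscale)
      res <- .cpp_laplace_subject(pv, s$time, s$dose, s$conc, s$obs_t,
                                  s$obs_y, sp, sa, om, c(0, 0, 0))
      if (collect) eta_hat[i, ] <<- res$eta
      nll <- nll + res$nll
    }
    if (!is.finite(nll)) 1e10 else nll
  }

  best <- NULL
  for (srt in seq_len(settings$n_starts)) {
    phi_s <- phi0
    if (srt > 1L) {
      set.seed(settings$seed + srt)
      phi_s <- phi0 + rnorm(length(phi0), 0, settings$start_sd)
    }
    opt <- tryCatch(
      nlminb(phi_s, obj,
             lower = phi0 - 4, upper = phi0 + 4,
             control = list(iter.max = settings$maxit,
                            eval.max = 4L * settings$maxit,
                            rel.tol = settings$rel_tol)),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e), par = phi_s))
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }

  th_hat <- th_work
  th_hat[free] <- exp(best$par)
  # final pass at the optimum: EBEs and the converged objective
  nll <- obj(best$par, collect = TRUE)
  eta <- eta_hat
  rownames(eta) <- vapply(subs, `[[`, "", "subject")
  colnames(eta) <- c("gamma", "alpha", "v0")

  rse <- setNames(rep(NA_real_, length(free)), free)
  if (isTRUE(settings$compute_rse)) {
    H <- .num_hessian(obj, best$par)
    cv <- tryCatch(solve(H), error = function(e) NULL)
    if (is.null(cv) || any(diag(cv) <= 0)) {
      warning("observed information is singular; RSE unavailable")
    } else {
      rse <- setNames(100 * sqrt(diag(cv)), free)  # log-scale SE = RSE/100
    }
  }

  om_hat <- c(gamma = th_hat[["omega_gamma"]], alpha = th_hat[["omega_alpha"]],
              v0 = th_hat[["omega_v0"]])
  shrink <- setNames(rep(NA_real_, 3L), c("gamma", "alpha", "v0"))
  for (k in 1:3) if (om_hat[k] > 0)
    shrink[k] <- 1 - stats::sd(eta[, k]) / om_hat[k]

  k_free <- length(free)
  structure(list(estimates = th_hat, free = free, rse = rse,
                 logLik = -nll, AIC = 2 * k_free + 2 * nll, df = k_free,
                 eta = eta, shrinkage = shrink,
                 convergence = best$convergence,
                 message = if (is.null(best$message)) "" else best$message,
                 population = .theta_pop(th_hat, init), init = init,
                 settings = settings, subjects = subs,
                 n_obs = sum(vapply(subs, function(s) length(s$obs_y), 0L)),
                 n_subjects = n, dataset = dataset),
            class = "tgi_fit")
}

.num_hessian <- function(f, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    for (j in i:p) {
      if (i == j) {
        xp <- x; xp[i] <- x[i] + h
        xm <- x; xm[i] <- x[i] - h
        H[i, i] <- (f(xp) - 2 * f0 + f(xm)) / h^2
      } else {
        xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + h
        xpm <- x; xpm[i] <- x[i] + h; xpm[j] <- x[j] - h
        xmp <- x; xmp[i] <- x[i] - h; xmp[j] <- x[j] + h
        xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - h
        H[i, j] <- H[j, i] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * h^2)
      }
    }
  }
  H
}

#' @export
print.tgi_fit <- function(x, ...) {
  cat(sprintf("Population fit (Laplace/FOCE-type): %d subjects, %d observations\n",
              x$n_subjects, x$n_obs))
  cat(sprintf("  -2LL = %.2f, AIC = %.2f (%d estimated parameters)\n",
              -2 * x$logLik, x$AIC, x$df))
  cat(sprintf("  convergence code %d %s\n", x$convergence,
              if (nzchar(x$message)) paste0("(", x$message, ")") else ""))
  invisible(x)
}

#' @export
summary.tgi_fit <- function(object, ...) {
  est <- object$estimates[object$free]
  tab <- data.frame(estimate = unname(est),
                    rse_percent = unname(object$rse[object$free]),
                    row.names = object$free)
  out <- list(table = tab, shrinkage = object$shrinkage, AIC = object$AIC,
              logLik = object$logLik, df = object$df,
              convergence = object$convergence,
              n_subjects = object$n_subjects, n_obs = object$n_obs)
  class(out) <- "summary.tgi_fit"
  out
}

#' @export
print.summary.tgi_fit <- function(x, ...) {
  cat(sprintf("Population fit: %d subjects, %d observations, AIC = %.2f\n",
              x$n_subjects, x$n_obs, x$AIC))
  print(round(x$table, 4))
  cat("Random-effect shrinkage (1 - SD(EBE)/omega):\n")
  print(round(x$shrinkage, 3))
  invisible(x)
}

#' @export
coef.tgi_fit <- function(object, ...) object$estimates

#' @export
logLik.tgi_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, nobs = object$n_obs,
            class = "logLik")
}

#' Model predictions for the fitted subjects
#'
#' @param object a `tgi_fit`.
#' @param level `"individual"` (empirical-Bayes random effects, default) or
#'   `"population"` (random effects at zero).
#' @param ... unused.
#' @return The observations data frame with a `pred` column appended.
#' @export
predict.tgi_fit <- function(object, level = c("individual", "population"),
                            ...) {
  level <- match.arg(level)
  th <- object$estimates
  init <- object$init
  kind <- match(init$inhibition, c("linear", "exponential", "saturating")) - 1L
  rows <- lapply(seq_along(object$subjects), function(i) {
    s <- object$subjects[[i]]
    pv <- .subject_parvec(th, s, kind, init$alpha_beta_ratio,
                          init$gamma_dose_scale)
    if (level == "individual") {
      e <- object$eta[i, ]
      pv[5] <- pv[5] * exp(e[1L]); pv[3] <- pv[3] * exp(e[2L])
      pv[9] <- pv[9] * exp(e[3L])
    }
    data.frame(subject = s$subject, time = s$obs_t, observed = s$obs_y,
               pred = .cpp_pred(pv, s$time, s$dose, s$conc, s$obs_t))
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Individual weighted residuals
#'
#' `(y - f) / sqrt((sigma_prop * f)^2 + sigma_add^2)` at the
#' empirical-Bayes individual predictions.
#'
#' @param object a `tgi_fit`.
#' @param ... unused.
#' @return Numeric vector of weighted residuals.
#' @export
residuals.tgi_fit <- function(object, ...) {
  pr <- predict(object, level = "individual")
  sp <- object$estimates[["sigma_prop"]]
  sa <- object$estimates[["sigma_add"]]
  (pr$observed - pr$pred) / sqrt((sp * pr$pred)^2 + sa^2)
}

#' Simulate replicate datasets from a fitted population model
#'
#' @param object a `tgi_fit`.
#' @param nsim number of replicate datasets.
#' @param seed master seed of the first replicate.
#' @param ... unused.
#' @return A list of `tgi_dataset` objects.
#' @export
simulate.tgi_fit <- function(object, nsim = 1, seed = 1L, ...) {
  lapply(seq_len(nsim), function(r)
    synthesize_studies(object$population, object$dataset$designs,
                       seed = seed + r - 1L))
}

#' @export
plot.tgi_fit <- function(x, ...) {
  pr <- predict(x, level = "individual")
  graphics::plot(pr$pred, pr$observed, log = "xy",
                 xlab = "individual prediction (mm^3)",
                 ylab = "observed (mm^3)", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' Maximum-likelihood fit of a single subject
#'
#' Maximizes the Gaussian likelihood of one subject's volumes under the
#' combined proportional + additive error model over the subject's free
#' parameters (`gamma`, `alpha`, `v0` by default, on the log scale).  For a
#' radiation-free regimen `gamma` and `alpha` carry no information; they
#' are flagged as unidentifiable and the fit falls back to `v0` and the net
#' growth rate (via `kg` with `kk` held fixed).
#'
#' @param observations data frame with columns `time` (days) and `volume`
#'   (mm^3); at least 4 observations.
#' @param regimen the subject's [regimen()].
#' @param init a [tgi_params()] with initial values (fixed parameters keep
#'   these values).
#' @param sigma residual error `c(prop = , add = )` (known error model).
#' @param free parameters to estimate.
#' @return A list of class `tgi_ifit`: `params` (fitted [tgi_params()]),
#'   `objective` (negative log-likelihood), `convergence`,
#'   `unidentifiable`.
#' @export
fit_individual <- function(observations, regimen, init,
                           sigma = c(prop = 0.35, add = 4.4),
                           free = c("gamma", "alpha", "v0")) {
  if (nrow(observations) < 4L)
    stop("at least 4 observations are required")
  o <- observations[order(observations$time), , drop = FALSE]
  unident <- character()
  if (!nrow(regimen) || all(regimen$dose == 0)) {
    unident <- intersect(free, c("gamma", "alpha"))
    free <- c(setdiff(free, c("gamma", "alpha")), "kg")
  }
  sp <- sigma[["prop"]]; sa <- sigma[["add"]]
  nll_fun <- function(phi) {
    p <- init
    for (k in seq_along(free)) p[[free[k]]] <- exp(phi[k])
    f <- .cpp_pred(.par_vec(p), regimen$time, regimen$dose, regimen$conc,
                   o$time)
    v <- pmax((sp * o$volume)^2 + sa^2, 1e-12)
    val <- 0.5 * sum((o$volume - f)^2 / v + log(2 * pi * v))
    if (!is.finite(val)) 1e10 else val
  }
  phi0 <- log(vapply(free, function(k) max(init[[k]], 1e-6), numeric(1L)))
  opt <- nlminb(phi0, nll_fun,
                control = list(iter.max = 500L, rel.tol = 1e-12,
                               eval.max = 2000L))
  params <- init
  for (k in seq_along(free)) params[[free[k]]] <- unname(exp(opt$par[k]))
  structure(list(params = params, objective = opt$objective,
                 convergence = opt$convergence, free = free,
                 unidentifiable = unident),
            class = "tgi_ifit")
}

#' @export
print.tgi_ifit <- function(x, ...) {
  cat("Individual fit: -LL =", format(x$objective), "\n")
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  if (length(x$unidentifiable))
    cat("  unidentifiable (no radiation in regimen):",
        paste(x$unidentifiable, collapse = ", "), "\n")
  est <- vapply(x$free, function(k) x$params[[k]], numeric(1L))
  print(signif(est, 5))
  invisible(x)
}
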