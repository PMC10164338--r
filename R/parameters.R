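#' Structural parameters for one subject
#'
#' Bundles the tumor growth, radiation and radiosensitizer-potency
#' parameters of the cell-kill / growth-inhibition model for a single
#' subject, together with the chosen long-term inhibition function.
#'
#' The model splits the tumor into proliferating cells `V1`, three transit
#' compartments of dying cells `V2..V4`, and two compartments of
#' radiation-damaged cells `U1`, `U2`.  Radiation has a short-term effect
#' (an instantaneous linear-quadratic kill moving cells from `V1` to `U1`
#' at each fraction) and a long-term effect (inhibition of the growth rate
#' by the accumulated dose).  A radiosensitizer at concentration `C`
#' potentiates the short-term effect by `(1 + a*C)` and the long-term
#' effect by scaling the accumulated dose by `(1 + b*C)`.
#'
#' The long-term inhibition parameter `gamma` is expressed per
#' `gamma_dose_scale` Gy of accumulated dose (default 10 Gy), i.e. the
#' linear variant reads `I = 1 - gamma * D_acc * (1 + b*C) / gamma_dose_scale`.
#' With the default scale the published estimates reproduce the reported
#' growth-rate inhibition percentages (16% and 26% at 60 Gy for the first
#' two study medians).
#'
#' @param kg proliferation rate of `V1` cells, 1/day (> 0).
#' @param kk natural kill rate feeding the transit chain, 1/day
#'   (`0 <= kk <= kg`).
#' @param alpha linear coefficient of the linear-quadratic kill, 1/Gy.
#' @param gamma long-term growth-inhibition coefficient, per
#'   `gamma_dose_scale` Gy (dimensionless for the saturating variant).
#' @param a short-term radiosensitizer potency, mL/ug.
#' @param b long-term radiosensitizer potency, mL/ug.
#' @param v0 initial volume of proliferating cells, mm^3 (> 0).
#' @param inhibition long-term inhibition function: `"linear"` (default,
#'   selected by AIC on the original data), `"exponential"`, or
#'   `"saturating"`.
#' @param id50 half-maximal accumulated dose of the saturating variant, Gy
#'   (required when `inhibition = "saturating"`).
#' @param alpha_beta_ratio alpha/beta ratio of the linear-quadratic model,
#'   Gy; `beta = alpha / alpha_beta_ratio`.  Default 10 Gy.
#' @param gamma_dose_scale dose scale of the long-term inhibition argument,
#'   Gy.  Default 10.
#'
#' @return An object of class `tgi_params`.
#' @examples
#' p <- tgi_params(kg = 0.44, kk = 0.3, alpha = 0.06, gamma = 0.027, v0 = 26)
#' p
#' initial_state(p)
#' @export
tgi_params <- function(kg = 0.44, kk = 0.3, alpha = 0.06, gamma = 0.02,
                       a = 0, b = 0, v0 = 22,
                       inhibition = c("linear", "exponential", "saturating"),
                       id50 = NULL, alpha_beta_ratio = 10,
                       gamma_dose_scale = 10) {
  inhibition <- match.arg(inhibition)
  stopifnot(is.numeric(kg), length(kg) == 1L, is.finite(kg))
  if (kg <= 0) stop("'kg' must be > 0")
  if (kk < 0) stop("'kk' must be >= 0")
  if (kk > kg) stop("'kk' must not exceed 'kg' (untreated net growth non-negative)")
  if (alpha < 0) stop("'alpha' must be >= 0")
  if (gamma < 0) stop("'gamma' must be >= 0")
  if (a < 0 || b < 0) stop("potency parameters 'a' and 'b' must be >= 0")
  if (v0 <= 0) stop("'v0' must be > 0")
  if (alpha_beta_ratio <= 0) stop("'alpha_beta_ratio' must be > 0")
  if (gamma_dose_scale <= 0) stop("'gamma_dose_scale' must be > 0")
  if (inhibition == "saturating") {
    if (is.null(id50) || !is.finite(id50) || id50 <= 0)
      stop("'id50' must be a positive dose (Gy) for the saturating variant")
  } else id50 <- NA_real_
  structure(list(kg = kg, kk = kk, alpha = alpha, gamma = gamma,
                 a = a, b = b, v0 = v0, inhibition = inhibition,
                 id50 = id50, alpha_beta_ratio = alpha_beta_ratio,
                 gamma_dose_scale = gamma_dose_scale),
            class = "tgi_params")
}

#' @export
print.tgi_params <- function(x, ...) {
  cat("Tumor growth / radiation model parameters\n")
  cat(sprintf("  kg = %.4g 1/day, kk = %.4g 1/day (net growth %.4g 1/day)\n",
              x$kg, x$kk, x$kg - x$kk))
  cat(sprintf("  alpha = %.4g 1/Gy (alpha/beta = %g Gy)\n",
              x$alpha, x$alpha_beta_ratio))
  cat(sprintf("  inhibition: %s, gamma = %.4g per %g Gy accumulated dose",
              x$inhibition, x$gamma, x$gamma_dose_scale))
  if (x$inhibition == "saturating") cat(sprintf(", ID50 = %g Gy", x$id50))
  cat("\n")
  cat(sprintf("  radiosensitizer potency: a = %.4g, b = %.4g mL/ug\n", x$a, x$b))
  cat(sprintf("  v0 = %.4g mm^3 proliferating\n", x$v0))
  invisible(x)
}

# numeric parameter vector consumed by the compiled core
.par_vec <- function(p) {
  kind <- match(p$inhibition, c("linear", "exponential", "saturating")) - 1L
  c(p$kg, p$kk, p$alpha, p$alpha_beta_ratio, p$gamma,
    if (is.na(p$id50)) 1 else p$id50, p$a, p$b, p$v0, kind,
    p$gamma_dose_scale)
}

.modify_params <- function(p, ...) {
  upd <- list(...)
  for (nm in names(upd)) p[[nm]] <- upd[[nm]]
  p
}
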