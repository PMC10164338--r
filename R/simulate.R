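#' Initial compartment state
#'
#' Initial conditions placing the transit chain in the proportions of
#' untreated steady growth, so that without treatment the total volume grows
#' strictly exponentially at rate `kg - kk`: `V_i(0) = v0 * (kk/kg)^(i-1)`
#' for `i = 1..4`, with the damaged compartments `U1`, `U2` empty.
#'
#' @param params a [tgi_params()] object.
#' @return A named numeric vector of class `tumor_state` with elements
#'   `v1..v4`, `u1`, `u2` (mm^3) and `d_acc` (accumulated dose, Gy).
#' @examples
#' s <- initial_state(tgi_params(v0 = 44, kg = 0.44, kk = 0.3))
#' total_volume(s)
#' @export
initial_state <- function(params) {
  r <- params$kk / params$kg
  structure(c(v1 = params$v0, v2 = params$v0 * r, v3 = params$v0 * r^2,
              v4 = params$v0 * r^3, u1 = 0, u2 = 0, d_acc = 0),
            class = "tumor_state")
}

#' @describeIn initial_state Total tumor volume of a state (sum of all six
#'   compartments), mm^3.
#' @param state a `tumor_state` vector.
#' @export
total_volume <- function(state) {
  unname(sum(state[c("v1", "v2", "v3", "v4", "u1", "u2")]))
}

#' Long-term growth-inhibition factor
#'
#' The factor `I` multiplying the proliferation rate `kg`, as a function of
#' the accumulated radiation dose and the radiosensitizer concentration.
#' The drug scales the accumulated dose by `(1 + b*C)`; the dose argument of
#' the linear and exponential variants is expressed per
#' `gamma_dose_scale` Gy.  `I(0) = 1` for all variants; the linear variant
#' may become negative at large accumulated doses (net tumor shrinkage).
#'
#' @param d_acc accumulated radiation dose, Gy (vectorised).
#' @param conc radiosensitizer concentration, ug/mL (vectorised).
#' @param params a [tgi_params()] object.
#' @return Dimensionless factor(s) in `(-Inf, 1]`.
#' @examples
#' p <- tgi_params(gamma = 0.027, inhibition = "linear")
#' 1 - inhibition_factor(60, 0, p)   # 16.2% growth-rate inhibition
#' @export
inhibition_factor <- function(d_acc, conc = 0, params) {
  stopifnot(all(d_acc >= 0), all(conc >= 0))
  deff <- d_acc * (1 + params$b * conc)
  switch(params$inhibition,
         linear = 1 - params$gamma * deff / params$gamma_dose_scale,
         exponential = exp(-params$gamma * deff / params$gamma_dose_scale),
         saturating = 1 - params$gamma * deff / (params$id50 + deff),
         stop("unknown inhibition variant: ", params$inhibition))
}

#' Fraction of proliferating cells killed by one radiation application
#'
#' Linear-quadratic cell kill with radiosensitizer potentiation:
#' `F = 1 - exp(-(1 + a*C) * (alpha*D + beta*D^2))` with
#' `beta = alpha / alpha_beta_ratio`.
#'
#' @param dose fraction dose, Gy (vectorised).
#' @param conc radiosensitizer concentration at the application, ug/mL.
#' @param params a [tgi_params()] object.
#' @return Killed fraction(s) in `[0, 1)`.
#' @examples
#' p <- tgi_params(alpha = 0.06)
#' fraction_killed(2, 0, p)          # 0.134 at 2 Gy
#' fraction_killed(2, 7, p)          # unchanged: a = 0 for an inert drug
#' @export
fraction_killed <- function(dose, conc = 0, params) {
  stopifnot(all(dose >= 0), all(conc >= 0))
  beta <- params$alpha / params$alpha_beta_ratio
  1 - exp(-(1 + params$a * conc) * (params$alpha * dose + beta * dose^2))
}

#' Apply one instantaneous radiation impulse to a state
#'
#' Moves the linear-quadratic killed fraction of `v1` into `u1` and
#' increments the accumulated dose; all other compartments are unchanged,
#' so total volume is conserved across the impulse.
#'
#' @param state a `tumor_state` vector (see [initial_state()]).
#' @param dose fraction dose, Gy.
#' @param conc radiosensitizer concentration at the application, ug/mL.
#' @param params a [tgi_params()] object.
#' @return The post-impulse `tumor_state`.
#' @export
apply_impulse <- function(state, dose, conc = 0, params) {
  f <- fraction_killed(dose, conc, params)
  moved <- f * state[["v1"]]
  state[["v1"]] <- state[["v1"]] - moved
  state[["u1"]] <- state[["u1"]] + moved
  state[["d_acc"]] <- state[["d_acc"]] + dose
  state
}

#' Simulate a tumor volume trajectory under a radiation regimen
#'
#' Integrates the six-compartment system with instantaneous impulses at the
#' radiation application times.  Between applications the system is linear
#' with constant coefficients, so the default method propagates each segment
#' exactly with a matrix exponential; `method = "ode"` integrates the same
#' piecewise system with a general-purpose stiff solver
#' ([deSolve::lsoda()]) as an independent numerical route.
#'
#' The long-term inhibition factor is re-evaluated after each impulse from
#' the updated accumulated dose and the concentration of the most recent
#' application, and held at its final value after the last fraction.
#' Requested output exactly at an application time returns the post-impulse
#' state; the pre-impulse (left-limit) states at every application are kept
#' in the `left_states` attribute.
#'
#' @param params a [tgi_params()] object.
#' @param regimen a [regimen()] object.
#' @param times output times, days, within `[0, horizon]`; default a grid of
#'   201 points over the horizon.
#' @param method `"matexp"` (exact piecewise propagation, default) or
#'   `"ode"` (general integrator).
#' @param rtol,atol relative/absolute tolerance for `method = "ode"`.
#' @return A `tgi_trajectory`: a data frame with columns `time`, `v1..v4`,
#'   `u1`, `u2`, `d_acc`, `v_tot` and attributes `left_states` (pre-impulse
#'   states at application times) and `deriv` (dVtot/dt at the output
#'   times).
#' @examples
#' p <- tgi_params(gamma = 0.027, v0 = 26)
#' reg <- fractionated_regimen(weeks = 6, fraction_dose = 2, conc = 0,
#'                             horizon = 80)
#' tr <- simulate_tumor(p, reg)
#' head(tr)
#' @export
simulate_tumor <- function(params, regimen, times = NULL,
                           method = c("matexp", "ode"),
                           rtol = 1e-10, atol = 1e-10) {
  method <- match.arg(method)
  horizon <- .regimen_horizon(regimen)
  if (is.null(times)) times <- seq(0, horizon, length.out = 201L)
  times <- as.numeric(times)
  if (is.unsorted(times)) times <- sort(times)
  if (any(times < 0) || any(times > horizon))
    stop("output times must lie within [0, horizon]")
  if (method == "matexp") {
    sim <- .cpp_simulate(.par_vec(params), regimen$time, regimen$dose,
                         regimen$conc, times)
    states <- sim$states
    deriv <- sim$deriv
    left <- sim$left
  } else {
    out <- .simulate_ode(params, regimen, times, rtol = rtol, atol = atol)
    states <- out$states
    deriv <- out$deriv
    left <- out$left
  }
  colnames(states) <- c("v1", "v2", "v3", "v4", "u1", "u2", "d_acc")
  df <- data.frame(time = times, states[, c(1:6, 7), drop = FALSE])
  df$v_tot <- rowSums(states[, 1:6, drop = FALSE])
  left_df <- NULL
  if (nrow(regimen)) {
    colnames(left) <- c("v1", "v2", "v3", "v4", "u1", "u2", "d_acc")
    left_df <- data.frame(time = regimen$time, left)
    left_df$v_tot <- rowSums(left[, 1:6, drop = FALSE])
  }
  structure(df, left_states = left_df, deriv = as.numeric(deriv),
            params = params, regimen = regimen,
            class = c("tgi_trajectory", "data.frame"))
}

# piecewise lsoda integration of the same system
.simulate_ode <- function(params, regimen, times, rtol, atol) {
  rhs <- function(t, y, parms) {
    kg <- params$kg; kk <- params$kk; I <- parms$I
    list(c(v1 = (kg * I - kk) * y[1],
           v2 = kk * (y[1] + y[5] + y[6]) - kk * y[2],
           v3 = kk * (y[2] - y[3]),
           v4 = kk * (y[3] - y[4]),
           u1 = -(kg + kk) * y[5],
           u2 = 2 * kg * y[5] - kk * y[6]))
  }
  s <- unclass(initial_state(params))[1:6]
  d_acc <- 0; I <- 1; t_cur <- 0
  ne <- nrow(regimen)
  states <- matrix(NA_real_, length(times), 7)
  left <- matrix(NA_real_, ne, 7)
  ie <- 1L
  run_seg <- function(s, from, to, I, record_at = NULL) {
    if (to <= from) return(list(s = s, rec = NULL))
    tt <- sort(unique(c(from, record_at, to)))
    sol <- deSolve::lsoda(y = s, times = tt, func = rhs, parms = list(I = I),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1L] < 0)
      stop(sprintf("ODE integration failed on segment [%g, %g]", from, to))
    list(s = as.numeric(sol[nrow(sol), -1L]),
         rec = sol[match(record_at, sol[, 1L]), -1L, drop = FALSE])
  }
  io <- 1L
  while (io <= length(times)) {
    tt <- times[io]
    while (ie <= ne && regimen$time[ie] <= tt) {
      seg <- run_seg(s, t_cur, regimen$time[ie], I)
      s <- seg$s; t_cur <- regimen$time[ie]
      left[ie, ] <- c(s, d_acc)
      f <- fraction_killed(regimen$dose[ie], regimen$conc[ie], params)
      moved <- f * s[1]
      s[1] <- s[1] - moved; s[5] <- s[5] + moved
      d_acc <- d_acc + regimen$dose[ie]
      I <- inhibition_factor(d_acc, regimen$conc[ie], params)
      ie <- ie + 1L
    }
    seg <- run_seg(s, t_cur, tt, I)
    s <- seg$s; t_cur <- max(t_cur, tt)
    states[io, ] <- c(s, d_acc)
    io <- io + 1L
  }
  while (ie <= ne) { # left limits at applications beyond the last output
    seg <- run_seg(s, t_cur, regimen$time[ie], I)
    s <- seg$s; t_cur <- regimen$time[ie]
    left[ie, ] <- c(s, d_acc)
    f <- fraction_killed(regimen$dose[ie], regimen$conc[ie], params)
    moved <- f * s[1]
    s[1] <- s[1] - moved; s[5] <- s[5] + moved
    d_acc <- d_acc + regimen$dose[ie]
    I <- inhibition_factor(d_acc, regimen$conc[ie], params)
    ie <- ie + 1L
  }
  deriv <- numeric(length(times))
  # per-row derivative with the inhibition factor active at each time
  for (i in seq_along(times)) {
    past <- regimen$time <= times[i]
    I_i <- if (any(past)) {
      inhibition_factor(sum(regimen$dose[past]),
                        regimen$conc[max(which(past))], params)
    } else 1
    deriv[i] <- params$kg * I_i * states[i, 1] + params$kg * states[i, 5] -
      params$kk * states[i, 4]
  }
  list(states = states, deriv = deriv, left = left)
}

#' @export
print.tgi_trajectory <- function(x, ...) {
  cat(sprintf("Tumor trajectory: %d time points over [%g, %g] days\n",
              nrow(x), min(x$time), max(x$time)))
  reg <- attr(x, "regimen", exact = TRUE)
  cat(sprintf("  %d radiation applications, final accumulated dose %g Gy\n",
              nrow(reg), sum(reg$dose)))
  cat(sprintf("  V_tot: %.3g -> %.3g mm^3\n", x$v_tot[1L], x$v_tot[nrow(x)]))
  invisible(x)
}

#' @export
plot.tgi_trajectory <- function(x, log = "y", ...) {
  graphics::plot(x$time, x$v_tot, type = "l", log = log,
                 xlab = "time (days)", ylab = expression(V[tot] ~ (mm^3)),
                 ...)
  reg <- attr(x, "regimen", exact = TRUE)
  if (nrow(reg)) graphics::rug(reg$time)
  invisible(x)
}

#' Instantaneous rate of change of total tumor volume
#'
#' Evaluates `dV_tot/dt` on the simulated state at `t_star`, summing the
#' right-hand sides of all compartments (which collapses to
#' `kg*I*V1 + kg*U1 - kk*V4`).  The tumor-static exposure machinery
#' searches for exposures making this quantity vanish at the evaluation
#' time.
#'
#' @param params a [tgi_params()] object.
#' @param regimen a [regimen()] object.
#' @param t_star evaluation time(s), days, within `[0, horizon]`.
#' @return `dV_tot/dt` in mm^3/day (vectorised over `t_star`).
#' @examples
#' p <- tgi_params()
#' volume_derivative(p, regimen(horizon = 30), t_star = 10)  # untreated: > 0
#' @export
volume_derivative <- function(params, regimen, t_star) {
  horizon <- .regimen_horizon(regimen)
  if (any(t_star < 0) || any(t_star > horizon))
    stop("'t_star' must lie within [0, horizon]")
  pv <- .par_vec(params)
  vapply(as.numeric(t_star), function(tt)
    .cpp_deriv_at(pv, regimen$time, regimen$dose, regimen$conc, tt),
    numeric(1L))
}
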