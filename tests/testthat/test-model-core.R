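test_that("initial conditions place the transit chain in exponential-growth proportions", {
  p <- base_params(v0 = 44, kg = 0.44, kk = 0.3)
  s <- initial_state(p)
  r <- 0.3 / 0.44
  expect_equal(unname(s[c("v1", "v2", "v3", "v4")]),
               44 * r^(0:3), tolerance = 1e-12)
  expect_equal(unname(s[c("u1", "u2", "d_acc")]), c(0, 0, 0))
  expect_equal(total_volume(s), 44 * sum(r^(0:3)), tolerance = 1e-12)
  expect_equal(round(total_volume(s), 1), 108.4)
  # no natural death: all mass proliferating
  s0 <- initial_state(base_params(v0 = 44, kk = 0))
  expect_equal(unname(s0[1:6]), c(44, 0, 0, 0, 0, 0))
  # smaller initial volume
  expect_equal(round(total_volume(initial_state(base_params(v0 = 26))), 1),
               64.1)
})

test_that("parameter validation rejects inadmissible values", {
  expect_error(tgi_params(kg = 0), "'kg'")
  expect_error(tgi_params(kk = -1), "'kk'")
  expect_error(tgi_params(kk = 0.5, kg = 0.4), "'kk'")
  expect_error(tgi_params(v0 = 0), "'v0'")
  expect_error(tgi_params(inhibition = "saturating"), "id50")
  expect_s3_class(tgi_params(inhibition = "saturating", id50 = 30),
                  "tgi_params")
})

test_that("long-term inhibition reproduces the published worked percentages", {
  p1 <- base_params(gamma = 0.027, b = 0.26)
  # 60 Gy accumulated, no drug: 16.2% growth-rate inhibition
  expect_equal(1 - inhibition_factor(60, 0, p1), 0.162, tolerance = 1e-12)
  # with 1 ug/mL of the long-term potentiator: 20.4%
  expect_equal(1 - inhibition_factor(60, 1, p1), 0.162 * 1.26,
               tolerance = 1e-12)
  # I(0) = 1 for every variant
  for (v in c("linear", "exponential", "saturating")) {
    pv <- base_params(inhibition = v, id50 = if (v == "saturating") 30)
    expect_equal(inhibition_factor(0, 5, pv), 1)
  }
  # exponential and saturating variants behave as their functional forms
  pe <- base_params(gamma = 0.027, inhibition = "exponential")
  expect_equal(inhibition_factor(60, 0, pe), exp(-0.162), tolerance = 1e-12)
  ps <- base_params(gamma = 0.5, inhibition = "saturating", id50 = 60)
  expect_equal(inhibition_factor(60, 0, ps), 1 - 0.5 * 60 / 120,
               tolerance = 1e-12)
})

test_that("linear-quadratic kill matches direct evaluation and is monotone", {
  p <- base_params(alpha = 0.06, a = 0.65)
  expect_equal(fraction_killed(0, 0, p), 0)
  expect_equal(fraction_killed(2, 0, p), 1 - exp(-(0.06 * 2 + 0.006 * 4)))
  expect_equal(round(fraction_killed(2, 0, p), 4), 0.1341)
  expect_equal(round(fraction_killed(2, 7, p), 4), 0.5503)
  doses <- seq(0, 10, by = 0.5)
  expect_true(all(diff(fraction_killed(doses, 0, p)) > 0))
  concs <- seq(0, 10, by = 0.5)
  expect_true(all(diff(fraction_killed(2, concs, p)) > 0))
  expect_true(all(fraction_killed(c(0, 1, 50), 3, p) <= 1))
  expect_lt(fraction_killed(8, 3, p), 1)
})

test_that("radiation impulses transfer mass without destroying volume", {
  p <- base_params(alpha = 0.06, v0 = 100, kk = 0)
  s <- initial_state(p)  # v1 = 100
  s2 <- apply_impulse(s, dose = 2, conc = 0, params = p)
  expect_equal(unname(s2["v1"]), 100 * (1 - 0.1341123), tolerance = 1e-6)
  expect_equal(unname(s2["u1"]), 100 * 0.1341123, tolerance = 1e-6)
  expect_equal(total_volume(s2), total_volume(s))
  expect_equal(unname(s2["d_acc"]), 2)
  # zero dose only advances the dose counter
  s3 <- apply_impulse(s, dose = 0, conc = 3, params = p)
  expect_equal(unname(s3[1:6]), unname(s[1:6]))
  # an overwhelming short-term effect empties v1
  pbig <- base_params(alpha = 0.06, a = 1e8)
  s4 <- apply_impulse(initial_state(pbig), dose = 2, conc = 10,
                      params = pbig)
  expect_lt(unname(s4["v1"]), 1e-6)
})

test_that("untreated growth is strictly exponential with preserved proportions", {
  p <- base_params(v0 = 44)
  tt <- c(0, 1, 2.5, 5, 10, 20)
  tr <- simulate_tumor(p, regimen(horizon = 20), times = tt)
  expect_equal(tr$v_tot, total_volume(initial_state(p)) * exp(0.14 * tt),
               tolerance = 1e-6)
  expect_equal(tr$v_tot[tt == 10] / tr$v_tot[1], exp(1.4), tolerance = 1e-6)
  # all six compartments keep the initial-condition proportions
  prop <- as.matrix(tr[, c("v1", "v2", "v3", "v4")]) / tr$v_tot
  expect_lt(max(abs(sweep(prop, 2, prop[1, ]))), 1e-9)
  expect_true(all(tr$u1 == 0 & tr$u2 == 0))
  # doubling time of the published rates is close to five days
  td <- log(2) / (p$kg - p$kk)
  expect_equal(td, 4.951, tolerance = 1e-3)
  tr2 <- simulate_tumor(p, regimen(horizon = 20), times = c(0, td))
  expect_equal(tr2$v_tot[2] / tr2$v_tot[1], 2, tolerance = 1e-6)
})

test_that("volume is continuous across impulses and output at an event is post-impulse", {
  p <- base_params(a = 0.3, b = 0.2)
  reg <- fractionated_regimen(weeks = 1, fraction_dose = 3, conc = 2,
                              horizon = 12)
  tr <- simulate_tumor(p, reg, times = sort(unique(c(0:12, reg$time))))
  left <- attr(tr, "left_states")
  for (i in seq_len(nrow(reg))) {
    row <- tr[tr$time == reg$time[i], ]
    # continuity of total volume
    expect_equal(left$v_tot[i], row$v_tot, tolerance = 1e-10)
    # post-impulse convention: v1 dropped, u1 gained, dose counted
    expect_lt(row$v1, left$v1[i])
    expect_gt(row$u1, left$u1[i])
    expect_equal(row$d_acc, left$d_acc[i] + reg$dose[i])
  }
})

test_that("matrix-exponential propagation agrees with the general integrator", {
  for (p in draw_params(4, seed = 7)) {
    set.seed(p$v0)
    times <- sort(c(0, runif(3, 0, 25), 25))
    ev <- sort(runif(5, 0.5, 18))
    reg <- regimen(time = ev, dose = runif(5, 0.5, 6),
                   conc = runif(5, 0, 8), horizon = 25)
    t1 <- simulate_tumor(p, reg, times, method = "matexp")
    t2 <- simulate_tumor(p, reg, times, method = "ode",
                         rtol = 1e-12, atol = 1e-12)
    expect_lt(max(abs(t1$v_tot - t2$v_tot) / t2$v_tot), 1e-8)
  }
})

test_that("a single segment matches an independent matrix exponential", {
  skip_if_not_installed("Matrix")
  p <- base_params(gamma = 0.03)
  reg <- regimen(time = 2, dose = 4, conc = 1, horizon = 30)
  tr <- simulate_tumor(p, reg, times = c(2, 17))
  I <- inhibition_factor(4, 1, p)
  kg <- p$kg; kk <- p$kk
  A <- rbind(c(kg * I - kk, 0, 0, 0, 0, 0),
             c(kk, -kk, 0, 0, kk, kk),
             c(0, kk, -kk, 0, 0, 0),
             c(0, 0, kk, -kk, 0, 0),
             c(0, 0, 0, 0, -(kg + kk), 0),
             c(0, 0, 0, 0, 2 * kg, -kk))
  s2 <- as.numeric(Matrix::expm(A * 15) %*%
                     as.numeric(unlist(tr[1, c("v1", "v2", "v3", "v4",
                                               "u1", "u2")])))
  expect_equal(as.numeric(unlist(tr[2, c("v1", "v2", "v3", "v4",
                                         "u1", "u2")])),
               s2, tolerance = 1e-10)
})

test_that("compartments stay non-negative and efficacy is monotone in exposure", {
  for (p in draw_params(4, seed = 21)) {
    reg0 <- fractionated_regimen(weeks = 2, fraction_dose = 2, conc = 0,
                                 horizon = 40)
    tt <- seq(0, 40, by = 2)
    prev <- NULL
    for (cc in c(0, 2, 6)) {
      reg <- fractionated_regimen(weeks = 2, fraction_dose = 2, conc = cc,
                                  horizon = 40)
      tr <- simulate_tumor(p, reg, tt)
      expect_true(all(as.matrix(tr[, c("v1", "v2", "v3", "v4", "u1",
                                       "u2")]) >= -1e-10))
      if (!is.null(prev)) # higher concentration, same schedule: never larger
        expect_true(all(tr$v_tot <= prev + 1e-9))
      prev <- tr$v_tot
    }
    # higher fraction dose: never larger after treatment start
    lo <- simulate_tumor(p, reg0, tt)$v_tot
    hi <- simulate_tumor(p, fractionated_regimen(weeks = 2,
                                                 fraction_dose = 4,
                                                 conc = 0, horizon = 40),
                         tt)$v_tot
    expect_true(all(hi <= lo + 1e-9))
  }
})

test_that("the total-volume derivative behaves as the stasis machinery requires", {
  p <- base_params()
  reg <- regimen(horizon = 30)
  d <- volume_derivative(p, reg, t_star = 10)
  expect_equal(d, (p$kg - p$kk) * total_volume(initial_state(p)) *
                 exp(0.14 * 10), tolerance = 1e-8)
  expect_gt(d, 0)
  expect_error(volume_derivative(p, reg, t_star = 31), "horizon")
  # decreasing in concentration and dose while positive, and once the
  # derivative drops below zero it stays there (single sign change, which
  # is what the bisection searches rely on)
  pr <- base_params(gamma = 0.02, a = 0.65, b = 0.26)
  dv_conc <- vapply(seq(0, 8, by = 1), function(cc)
    volume_derivative(pr, fractionated_regimen(2, 5, 4, cc, horizon = 30),
                      25), numeric(1))
  pos <- dv_conc > 0
  expect_true(all(diff(dv_conc[pos]) < 0))
  expect_true(all(dv_conc[cumsum(!pos) > 0] <= 0))
  dv_dose <- vapply(c(1, 2, 4, 6), function(dd)
    volume_derivative(pr, fractionated_regimen(2, 5, dd, 0, horizon = 30),
                      25), numeric(1))
  pos <- dv_dose > 0
  expect_true(all(diff(dv_dose[pos]) < 0))
  expect_true(all(dv_dose[cumsum(!pos) > 0] <= 0))
})

test_that("regimen construction validates its inputs", {
  expect_error(regimen(time = c(1, 1)), "strictly increasing")
  expect_error(regimen(time = 2, dose = -1), "doses")
  expect_error(regimen(time = 2, conc = -1), "concentrations")
  expect_error(regimen(time = 5, horizon = 3), "horizon")
  r <- fractionated_regimen(weeks = 6)
  expect_equal(nrow(r), 30)
  expect_equal(r$time[1:6], c(0, 1, 2, 3, 4, 7))  # weekend gap preserved
  expect_equal(max(r$time), 39)
})
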