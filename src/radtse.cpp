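// Core propagator for the radiation + radiosensitizer tumor model.
//
// Between radiation applications the six-compartment system
// (V1..V4, U1, U2) is linear with constant coefficients, so segments are
// propagated exactly with a matrix exponential (scaling and squaring).
// Radiation applications are instantaneous impulses that move a
// linear-quadratic fraction of V1 into U1 and increment the accumulated
// dose.  The long-term inhibition factor I is piecewise constant: it is
// re-evaluated after each impulse from the updated accumulated dose and the
// concentration of the most recent application, and held at its final value
// after the last fraction.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Model {
  double kg, kk, alpha, abr, gamma, id50, a, b, v0, dscale;
  int kind; // 0 linear, 1 exponential, 2 saturating
};

Model unpack(const Rcpp::NumericVector &par) {
  Model m;
  m.kg = par[0]; m.kk = par[1]; m.alpha = par[2]; m.abr = par[3];
  m.gamma = par[4]; m.id50 = par[5]; m.a = par[6]; m.b = par[7];
  m.v0 = par[8]; m.kind = (int)par[9]; m.dscale = par[10];
  return m;
}

double inhib(const Model &m, double dacc, double conc) {
  const double deff = dacc * (1.0 + m.b * conc);
  switch (m.kind) {
  case 1: return std::exp(-m.gamma * deff / m.dscale);
  case 2: return 1.0 - m.gamma * deff / (m.id50 + deff);
  default: return 1.0 - m.gamma * deff / m.dscale;
  }
}

double fkill(const Model &m, double dose, double conc) {
  const double beta = m.alpha / m.abr;
  const double e = (1.0 + m.a * conc) * (m.alpha * dose + beta * dose * dose);
  return 1.0 - std::exp(-e);
}

// dVtot/dt = kg*I*V1 + kg*U1 - kk*V4 (sum of all compartment RHS terms)
double vtot_deriv(const Model &m, const vec &s, double I) {
  return m.kg * I * s(0) + m.kg * s(4) - m.kk * s(3);
}

mat66 sysmat(const Model &m, double I) {
  mat66 A(fill::zeros);
  const double kg = m.kg, kk = m.kk;
  A(0, 0) = kg * I - kk;                       // V1
  A(1, 0) = kk; A(1, 1) = -kk;                 // V2 <- V1,U1,U2
  A(1, 4) = kk; A(1, 5) = kk;
  A(2, 1) = kk; A(2, 2) = -kk;                 // V3
  A(3, 2) = kk; A(3, 3) = -kk;                 // V4
  A(4, 4) = -(kg + kk);                        // U1
  A(5, 4) = 2.0 * kg; A(5, 5) = -kk;           // U2
  return A;
}

// exp(A*dt) by scaling-and-squaring with a truncated Taylor series; the
// segment generator has infinity-norm of order 1/day so a handful of terms
// suffice after scaling.
typedef arma::mat::fixed<6, 6> mat66;

// scaling-and-squaring truncated Taylor series; segment generators have
// infinity-norm of order 1/day so a dozen terms suffice after scaling
mat66 expm6(const mat66 &A) {
  const double nrm = norm(A, "inf");
  int s = 0;
  if (nrm > 0.5) s = (int)std::ceil(std::log2(nrm / 0.5));
  mat66 B = A / std::pow(2.0, s);
  mat66 E(fill::eye), T(fill::eye);
  for (int k = 1; k <= 30; ++k) {
    T = T * B / (double)k;
    E += T;
    if (norm(T, "inf") < 1e-16) break;
  }
  for (int i = 0; i < s; ++i) E = E * E;
  return E;
}

vec init_state(const Model &m) {
  vec s(6, fill::zeros);
  const double r = m.kk / m.kg;
  s(0) = m.v0; s(1) = m.v0 * r; s(2) = m.v0 * r * r; s(3) = m.v0 * r * r * r;
  return s;
}

void impulse(const Model &m, vec &s, double dose, double conc, double &dacc) {
  const double F = fkill(m, dose, conc);
  const double moved = F * s(0);
  s(0) -= moved;
  s(4) += moved;
  dacc += dose;
}

// Walk the piecewise-linear system.  Events must be strictly increasing in
// time; out_t must be sorted.  Records post-impulse states at output times
// coinciding with an event.  Optionally records pre-impulse (left) states.
void walk(const Model &m,
          const Rcpp::NumericVector &ev_t, const Rcpp::NumericVector &ev_d,
          const Rcpp::NumericVector &ev_c, const Rcpp::NumericVector &out_t,
          mat *out_states, vec *out_deriv, mat *left_states) {
  vec s = init_state(m);
  double dacc = 0.0, conc = 0.0, t = 0.0, I = 1.0;
  const int ne = ev_t.size(), no = out_t.size();
  int ie = 0;
  for (int io = 0; io < no; ++io) {
    const double tt = out_t[io];
    while (ie < ne && ev_t[ie] <= tt) {
      const double dt = ev_t[ie] - t;
      if (dt > 0) s = expm6(sysmat(m, I) * dt) * s;
      t = ev_t[ie];
      if (left_states) {
        left_states->row(ie).cols(0, 5) = s.t();
        (*left_states)(ie, 6) = dacc;
      }
      impulse(m, s, ev_d[ie], ev_c[ie], dacc);
      conc = ev_c[ie];
      I = inhib(m, dacc, conc);
      ++ie;
    }
    if (tt > t) {
      s = expm6(sysmat(m, I) * (tt - t)) * s;
      t = tt;
    }
    if (out_states) {
      out_states->row(io).cols(0, 5) = s.t();
      (*out_states)(io, 6) = dacc;
    }
    if (out_deriv) (*out_deriv)(io) = vtot_deriv(m, s, I);
  }
  // finish remaining events only when a caller needs left states for all
  while (left_states && ie < ne) {
    const double dt = ev_t[ie] - t;
    if (dt > 0) s = expm6(sysmat(m, I) * dt) * s;
    t = ev_t[ie];
    left_states->row(ie).cols(0, 5) = s.t();
    (*left_states)(ie, 6) = dacc;
    impulse(m, s, ev_d[ie], ev_c[ie], dacc);
    conc = ev_c[ie];
    I = inhib(m, dacc, conc);
    ++ie;
  }
}

// total volume at sorted times (prediction function for fitting)
vec pred_vtot(const Model &m,
              const Rcpp::NumericVector &ev_t, const Rcpp::NumericVector &ev_d,
              const Rcpp::NumericVector &ev_c, const Rcpp::NumericVector &out_t) {
  mat st(out_t.size(), 7);
  walk(m, ev_t, ev_d, ev_c, out_t, &st, nullptr, nullptr);
  return sum(st.cols(0, 5), 1);
}

double deriv_at(const Model &m,
                const Rcpp::NumericVector &ev_t, const Rcpp::NumericVector &ev_d,
                const Rcpp::NumericVector &ev_c, double tstar) {
  Rcpp::NumericVector tt(1); tt[0] = tstar;
  vec d(1);
  walk(m, ev_t, ev_d, ev_c, tt, nullptr, &d, nullptr);
  return d(0);
}

} // namespace

// [[Rcpp::export(name = ".cpp_simulate")]]
Rcpp::List cpp_simulate(Rcpp::NumericVector par,
                        Rcpp::NumericVector ev_t, Rcpp::NumericVector ev_d,
                        Rcpp::NumericVector ev_c, Rcpp::NumericVector out_t) {
  const Model m = unpack(par);
  mat st(out_t.size(), 7);
  vec dv(out_t.size());
  mat left(ev_t.size(), 7);
  walk(m, ev_t, ev_d, ev_c, out_t, &st, &dv, &left);
  if (!st.is_finite())
    Rcpp::stop("trajectory integration produced non-finite compartment values");
  return Rcpp::List::create(Rcpp::Named("states") = st,
                            Rcpp::Named("deriv") = dv,
                            Rcpp::Named("left") = left);
}

// [[Rcpp::export(name = ".cpp_pred")]]
Rcpp::NumericVector cpp_pred(Rcpp::NumericVector par,
                             Rcpp::NumericVector ev_t, Rcpp::NumericVector ev_d,
                             Rcpp::NumericVector ev_c, Rcpp::NumericVector out_t) {
  const Model m = unpack(par);
  return Rcpp::wrap(pred_vtot(m, ev_t, ev_d, ev_c, out_t));
}

// [[Rcpp::export(name = ".cpp_deriv_at")]]
double cpp_deriv_at(Rcpp::NumericVector par,
                    Rcpp::NumericVector ev_t, Rcpp::NumericVector ev_d,
                    Rcpp::NumericVector ev_c, double tstar) {
  return deriv_at(unpack(par), ev_t, ev_d, ev_c, tstar);
}

// Smallest concentration C >= 0 such that dVtot/dt at tstar <= eps, for a
// fixed fractionated schedule (total dose split evenly over sched days).
// The derivative is monotone decreasing in C.  Returns NA when even c_hi
// does not satisfy the constraint.
// [[Rcpp::export(name = ".cpp_stasis_conc")]]
double cpp_stasis_conc(Rcpp::NumericVector par, Rcpp::NumericVector sched_t,
                       double total_dose, double tstar, double eps,
                       double c_hi, double tol) {
  const Model m = unpack(par);
  const int n = sched_t.size();
  Rcpp::NumericVector d(n, total_dose / n), c(n);
  auto h = [&](double cc) {
    std::fill(c.begin(), c.end(), cc);
    return deriv_at(m, sched_t, d, c, tstar) - eps;
  };
  if (h(0.0) <= 0.0) return 0.0;
  if (h(c_hi) > 0.0) return NA_REAL;
  double lo = 0.0, hi = c_hi;
  while (hi - lo > tol) {
    const double mid = 0.5 * (lo + hi);
    if (h(mid) <= 0.0) hi = mid; else lo = mid;
  }
  return hi;
}

// Smallest total dose whose derivative at tstar is <= eps at fixed
// concentration; monotone decreasing in dose.
// [[Rcpp::export(name = ".cpp_stasis_dose")]]
double cpp_stasis_dose(Rcpp::NumericVector par, Rcpp::NumericVector sched_t,
                       double conc, double tstar, double eps,
                       double d_hi, double tol) {
  const Model m = unpack(par);
  const int n = sched_t.size();
  Rcpp::NumericVector c(n, conc), d(n);
  auto h = [&](double D) {
    std::fill(d.begin(), d.end(), D / n);
    return deriv_at(m, sched_t, d, c, tstar) - eps;
  };
  if (h(0.0) <= 0.0) return 0.0;
  if (h(d_hi) > 0.0) return NA_REAL;
  double lo = 0.0, hi = d_hi;
  while (hi - lo > tol) {
    const double mid = 0.5 * (lo + hi);
    if (h(mid) <= 0.0) hi = mid; else lo = mid;
  }
  return hi;
}

// ---------------------------------------------------------------------------
// Laplace (FOCE-type) subject contribution.
//
// Random effects eta act multiplicatively (lognormal) on gamma, alpha, v0.
// The conditional mode is located by damped Gauss-Newton using the expected
// information of the combined (proportional + additive) error model; the
// marginal likelihood contribution uses the same Gauss-Newton Hessian.
// Dimensions with omega = 0 are fixed at eta = 0 and excluded.

namespace {

vec subject_pred(const Model &base, const vec &eta,
                 const Rcpp::NumericVector &ev_t, const Rcpp::NumericVector &ev_d,
                 const Rcpp::NumericVector &ev_c, const Rcpp::NumericVector &obs_t) {
  Model m = base;
  m.gamma = base.gamma * std::exp(eta(0));
  m.alpha = base.alpha * std::exp(eta(1));
  m.v0 = base.v0 * std::exp(eta(2));
  return pred_vtot(m, ev_t, ev_d, ev_c, obs_t);
}

// Residual variance of the combined error model at the model prediction
// (FOCE-with-interaction convention: the variance follows the individual
// prediction, which keeps the likelihood bounded when eradicated tumors
// produce observed volumes truncated at zero).
double pred_var(double f, double sp, double sa) {
  double v = sp * sp * f * f + sa * sa;
  return v < 1e-12 ? 1e-12 : v;
}

double data_nll(const vec &f, const Rcpp::NumericVector &y,
                double sp, double sa) {
  double nll = 0.0;
  for (int i = 0; i < y.size(); ++i) {
    const double v = pred_var(f(i), sp, sa);
    const double r = y[i] - f(i);
    nll += 0.5 * (r * r / v + std::log(2.0 * M_PI * v));
  }
  return nll;
}

} // namespace

// [[Rcpp::export(name = ".cpp_laplace_subject")]]
Rcpp::List cpp_laplace_subject(Rcpp::NumericVector par,
                               Rcpp::NumericVector ev_t, Rcpp::NumericVector ev_d,
                               Rcpp::NumericVector ev_c,
                               Rcpp::NumericVector obs_t, Rcpp::NumericVector obs_y,
                               double sp, double sa,
                               Rcpp::NumericVector omega,
                               Rcpp::NumericVector eta_start) {
  const Model base = unpack(par);
  const double LOG2PI = std::log(2.0 * M_PI);

  std::vector<int> free;
  for (int k = 0; k < 3; ++k) if (omega[k] > 0) free.push_back(k);
  const int d = (int)free.size();

  vec eta(3, fill::zeros);
  for (int k = 0; k < 3; ++k) if (omega[k] > 0) eta(k) = eta_start[k];

  auto qfun = [&](const vec &e, vec &f) {
    f = subject_pred(base, e, ev_t, ev_d, ev_c, obs_t);
    double q = data_nll(f, obs_y, sp, sa);
    for (int k : free)
      q += 0.5 * e(k) * e(k) / (omega[k] * omega[k]) +
           std::log(omega[k]) + 0.5 * LOG2PI;
    return q;
  };

  vec f;
  double q = qfun(eta, f);
  if (d == 0)
    return Rcpp::List::create(Rcpp::Named("nll") = q,
                              Rcpp::Named("eta") = Rcpp::wrap(eta));

  const double h = 1e-4;
  mat H(d, d);
  const int no = obs_y.size();
  int it;
  for (it = 0; it < 40; ++it) {
    // Jacobian of f wrt free etas: eta_v0 column is analytic (f scales with
    // exp(eta3)); gamma/alpha columns by central differences.
    mat J(no, d);
    for (int j = 0; j < d; ++j) {
      const int k = free[j];
      if (k == 2) { J.col(j) = f; continue; }
      vec ep = eta;
      ep(k) += h;
      const vec fp = subject_pred(base, ep, ev_t, ev_d, ev_c, obs_t);
      J.col(j) = (fp - f) / h;
    }
    vec g(d, fill::zeros);
    H.zeros();
    for (int i = 0; i < no; ++i) {
      const double v = pred_var(f(i), sp, sa);
      const double r = obs_y[i] - f(i);
      const double dv = 2.0 * sp * sp * f(i);
      const double dnll_df = -r / v + 0.5 * dv * (1.0 / v - r * r / (v * v));
      const double w = 1.0 / v + 0.5 * (dv / v) * (dv / v);
      for (int j = 0; j < d; ++j) {
        g(j) += dnll_df * J(i, j);
        for (int l = 0; l <= j; ++l) H(j, l) += w * J(i, j) * J(i, l);
      }
    }
    for (int j = 0; j < d; ++j)
      for (int l = j + 1; l < d; ++l) H(j, l) = H(l, j);
    for (int j = 0; j < d; ++j) {
      const int k = free[j];
      g(j) += eta(k) / (omega[k] * omega[k]);
      H(j, j) += 1.0 / (omega[k] * omega[k]);
    }
    vec step;
    if (!solve(step, H, g, solve_opts::likely_sympd))
      step = g / (norm(g) + 1.0);
    if (norm(step, "inf") > 2.0) step *= 2.0 / norm(step, "inf");
    // damped update
    double lam = 1.0;
    vec eta_new, f_new;
    double q_new = q;
    bool ok = false;
    for (int half = 0; half < 8; ++half) {
      eta_new = eta;
      for (int j = 0; j < d; ++j) eta_new(free[j]) -= lam * step(j);
      q_new = qfun(eta_new, f_new);
      if (q_new <= q + 1e-12) { ok = true; break; }
      lam *= 0.5;
    }
    if (!ok) break;
    const double dq = q - q_new;
    eta = eta_new; f = f_new; q = q_new;
    if (norm(step, "inf") * lam < 1e-8 || dq < 1e-11) break;
  }

  double ldet, sign;
  log_det(ldet, sign, H);
  const double nll = q - 0.5 * d * LOG2PI + 0.5 * ldet;
  return Rcpp::List::create(Rcpp::Named("nll") = nll,
                            Rcpp::Named("eta") = Rcpp::wrap(eta),
                            Rcpp::Named("iterations") = it + 1);
}
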