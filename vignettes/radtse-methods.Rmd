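---
title: "Tumor growth, radiosensitizers and Tumor Static Exposure: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor growth, radiosensitizers and Tumor Static Exposure: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radtse)
```

## The model

`radtse` implements a pharmacodynamic model of xenograft tumor response to
fractionated radiotherapy combined with a radiosensitizing agent (here, ATM
inhibitors given orally shortly before each radiation fraction, so that the
drug's mean maximum plasma concentration $C$ is the exposure active at the
fraction).

The total tumor volume is split into six compartments: proliferating cells
$V_1$; three transit compartments $V_2,V_3,V_4$ of cells undergoing natural
death; and two compartments $U_1,U_2$ of lethally radiation-damaged cells
($U_1$ cells may divide once, their daughters $U_2$ cannot). Between
radiation applications

$$
\begin{aligned}
\dot V_1 &= \bigl(k_g\,I(D_{acc},C) - k_k\bigr)V_1, &
\dot U_1 &= -(k_g+k_k)U_1, &
\dot U_2 &= 2k_g U_1 - k_k U_2,\\
\dot V_2 &= k_k (V_1+U_1+U_2) - k_k V_2, &
\dot V_3 &= k_k(V_2-V_3), &
\dot V_4 &= k_k(V_3-V_4),
\end{aligned}
$$

with $V_{tot} = V_1+\dots+V_4+U_1+U_2$. Initial conditions
$V_i(0)=V_0(k_k/k_g)^{i-1}$, $U_j(0)=0$ make the untreated tumor grow
strictly exponentially at the net rate $k_g-k_k$ (doubling time
$\ln 2/(k_g-k_k)\approx 5$ days at the bundled estimates).

Radiation acts twice:

* **Short term** — at each application of dose $D_R$, the fraction
  $F = 1-\exp\{-(1+aC)(\alpha D_R+\beta D_R^2)\}$ of $V_1$ moves
  instantaneously to $U_1$ (linear-quadratic cell kill, potentiated by the
  drug through $a$).
* **Long term** — the growth rate is inhibited by the accumulated dose
  through $I(D_{acc}, C)$, with the drug scaling the accumulated dose by
  $(1+bC)$. Three functional forms are supported: linear
  $I = 1-\gamma D_{acc}(1+bC)/s$, exponential
  $I=\exp\{-\gamma D_{acc}(1+bC)/s\}$, and saturating
  $I = 1-\gamma D_{acc}(1+bC)/(ID_{50}+D_{acc}(1+bC))$.

### Two unit conventions worth knowing

Two conventions are resolved once, at the parameter boundary, and flagged
by the loader:

* **The dose scale $s$ of the long-term effect.** The bundled estimates
  (e.g. $\gamma_1 = 0.027$) only reproduce the published worked
  percentages — 16% and 26% growth-rate inhibition at 60 Gy for the first
  two study medians, 20% with 1 µg/mL of the first compound — if the dose
  argument is taken per 10 Gy of accumulated dose. `gamma_dose_scale`
  therefore defaults to 10 (configurable). The analytical stasis dose
  $D_{acc} = s\,(1-k_k/k_g)/\{\gamma(1+bC)\}$ then lands at ≈159 Gy for
  $\gamma_3=0.02$, consistent with the reported dose magnitudes.
* **The quadratic kill term.** The constructor default is the standard
  $\alpha/\beta = 10$ Gy. The bundled published-parameter file, however,
  disables the quadratic term (`alpha_beta_ratio = Inf`): every kill
  fraction the source estimates imply (11% at 2 Gy for $\alpha=0.06$;
  17% and 55% at the lowest and highest exposure of the first compound)
  matches $F = 1-e^{-(1+aC)\alpha D_R}$ exactly and contradicts
  $\beta=\alpha/10$ (which would give 13.4%, 21%, 63%) — and the
  regenerated tumor-static doses agree with the published 220/50/65/100 Gy
  only under the α-only convention (see below). The reproduction
  configuration therefore treats the published $\alpha$ as an α-only kill
  coefficient.

### Simulation

Between applications the system is linear with constant coefficients (the
inhibition factor is piecewise constant: it is updated after each impulse
from the new accumulated dose and the concentration of the most recent
application, and held at its final value after the last fraction), so
`simulate_tumor()` propagates each segment **exactly** with a 6×6 matrix
exponential (scaling-and-squaring, compiled code). A general stiff
integrator route (`method = "ode"`, via deSolve) integrates the identical
piecewise system and is used as an independent numerical cross-check; the
two agree to better than $10^{-8}$ in relative volume in the test suite.
Requested output exactly at an application time returns the post-impulse
state; pre-impulse states are kept as the `left_states` attribute. With the
linear inhibition the growth factor $k_g I$ may become negative at large
accumulated doses; this is deliberate (net shrinkage) and is what makes
tumor stasis reachable by radiation alone.

## Tumor Static Exposure (TSE)

A TSE curve is the set of exposure pairs $(C, D_{acc})$ that hold the tumor
volume constant: exposures above the curve shrink the tumor, below it the
tumor regrows. Three routes are implemented:

1. **Analytical** (`analytic_tse()`): setting $\dot V_1=0$ with only the
   long-term effect and linear inhibition gives
   $D_{acc}= s(1-k_k/k_g)/\{\gamma(1+bC)\}$. The short-term potency $a$
   does not appear, which is the known limitation of this route.
2. **Simulation-based median** (`median_tse_curve()`,
   `stasis_concentration()`, `stasis_dose()`): for a fixed fractionation
   template (default 5 fractions/week × 6 weeks, weekend gaps preserved,
   total dose split evenly over the 30 fractions) the smallest exposure is
   sought whose total-volume derivative at an evaluation time $t^\*$
   satisfies $\mathrm dV_{tot}/\mathrm dt \le \epsilon$. Defaults
   $t^\*=60$ days and $\epsilon=10^{-4}$ mm³/day. The derivative is
   monotone decreasing in both dose and concentration while positive and
   crosses zero once, so bisection locates the boundary; concentrations are
   resolved to $10^{-4}$ µg/mL and doses to $10^{-2}$ Gy.
3. **Monte-Carlo population percentile** (`percentile_tse_curve()`,
   `stasis_dose_distribution()`): virtual individuals are drawn from the
   population model and the per-subject stasis problem is solved; the
   empirical nearest-rank percentile of the required exposure is reported
   per grid dose. The headline analyses use 1000 subjects, study-3
   covariates with the smallest $\gamma$ (a conservative choice), and the
   95th percentile. The radiation-alone requirement is computed per
   subject by bisection on total dose at $C=0$, which is numerically
   cleaner than locating the zero crossing of the concentration curve.

Numerical notes: $\epsilon$ is absolute, tuned to $t^\*=60$ d and volumes
of order 10–100 mm³. Because the system is homogeneous in volume the
stasis boundary is essentially independent of $V_0$; only through the
absolute $\epsilon$ does a (negligible) $V_0$ sensitivity enter, and the
reproduction runs fix $V_0$ at the study-3 median. At much larger $t^\*$
the post-treatment volumes near stasis are tiny, so verifying the
$t^\*\to\infty$ limit against the analytical curve uses a proportionally
smaller $\epsilon$ ($10^{-8}$ at $t^\*=600$ d, where simulated and
analytical doses agree within 3%). The default dose grid is 0–300 Gy in
5 Gy steps with monotone piecewise-linear interpolation between grid
points; doses whose required concentration exceeds the search bracket are
dropped from a curve with a warning (at 0 Gy no concentration can enforce
stasis, since the drug only potentiates radiation).

`rank_compounds()` orders compounds by the interpolated dose their curves
require at a common concentration — at 8 µg/mL and the 95th percentile the
bundled estimates rank the three compounds in the order Rs1, Rs2, Rs3, the
strongest saving roughly three quarters of the radiation-alone dose.

## The population model and the synthetic-study generator

The population structure is a nonlinear mixed-effects model: lognormal
between-subject variability on $\gamma$, $\alpha$ and $V_0$ (diagonal, no
correlation), study-indexed medians for $\gamma$ and $V_0$ (inter-study
variability as fixed effects, e.g.
$\gamma_j = (\gamma_1 \mathrm{Study}_1 + \gamma_2 \mathrm{Study}_2 +
\gamma_3 \mathrm{Study}_3)e^{\eta_j}$), and a combined residual error
$y = f(1+\varepsilon_1)+\varepsilon_2$ truncated at zero. Two printed-unit
decisions: the published between-subject variabilities (64, 50, 40) are
read as $100\,\omega$ (a CV% convention is available via
`bsv_convention = "cv_percent"`), and the proportional error printed as
"0.35 %" is read as the fraction 0.35 — a 0.35% CV would be far below the
visible scatter of caliper volume data.

`synthesize_study()` emulates the three efficacy studies bundled in
`default_study_designs()`: group sizes 9–10; vehicle, radiation-only and
combination arms; 2 Gy fractions Monday–Friday for 1 or 6 weeks; constant
per-arm exposure equal to the observed mean maximum concentration; tumor
volumes observed twice weekly (days 0 and 3 of each week) to 80 days for
the 6-week studies, with the highest-exposure 1-week arm followed to 120
days (the 80- and 60-day horizons of the remaining arms are package
choices; the sources state only the treatment durations). Each subject
receives a deterministic RNG substream derived from the master seed, so
datasets are bit-reproducible and arms can be regenerated independently.
What the generator deliberately does **not** emulate: dropout, toxicity,
measurement days lost to weekends/holidays, within-subject pharmacokinetic
variability, and any correlation between random effects. Passing tests on
these synthetic studies therefore demonstrates internal consistency of the
machinery, not fidelity to every feature of real caliper data.
`eradication_fraction()` classifies a simulated tumor as eradicated when
its noise-free end-of-study volume falls below 1 mm³ (the sources define
eradication only observationally; the threshold is configurable).

## Estimation

`fit_population()` maximizes a Laplace approximation to the NLME marginal
likelihood of the FOCE family: for each subject the mode of the
random-effect posterior is located by damped Gauss–Newton, and the
curvature term uses the Gauss–Newton (expected-information) Hessian at the
mode. The residual variance follows the individual prediction
($\sigma_{prop}^2 f^2 + \sigma_{add}^2$, the "interaction" convention) —
evaluating it at the observations instead is provably unbounded here,
because eradicated tumors contribute volumes truncated at zero whose
proportional variance vanishes. All parameters are estimated on the log
scale with box bounds of ±4 log-units around the starting values; the
default is 5 optimizer starts from log-perturbed initials. Relative
standard errors come from the inverse observed information at the optimum
(delta method on the log scale; reported as unavailable if the information
matrix is singular), and empirical-Bayes shrinkage is reported as
$1-\mathrm{SD}(\hat\eta)/\omega$ per random effect. Exact numerical
agreement with any particular FOCE implementation is not claimed; recovery
of the generating parameters on synthetic data is the supported accuracy
statement.

`fit_individual()` is the single-subject building block: free parameters
($\gamma$, $\alpha$, $V_0$ by default) are fitted by maximum likelihood
under a *given* error model, with the residual variance evaluated at the
observed volumes so that noise-free data are recovered exactly (verified
to $10^{-3}$ relative in the tests). For a radiation-free (vehicle)
regimen $\gamma$ and $\alpha$ carry no information; they are flagged and
the fit falls back to $V_0$ and the net growth rate.

`select_inhibition_variant()` fits the three inhibition functions on the
same data and picks the smallest $\mathrm{AIC}=2k-2\ln L$ (ties toward
fewer parameters). A caution from the package's own simulation
experiments: at desk-scale sample sizes (tens of subjects) the linear and
exponential variants differ by only a few percent in growth rate over the
studied dose range — second order in $\gamma D_{eff}$ — which is far
below a between-subject variability of $\omega_\gamma=0.64$, so AIC
differences of order 1 between variants are common and selection is
unstable. Distinguishing the variants reliably needs data on the scale of
the original three-study analysis (≈170 animals). The package's
acceptance suite runs the selection experiment at 16 subjects per
replicate and documents this limitation rather than overstating the
selection power.

`vpc_summary()` provides numeric visual-predictive-check bands (simulated
median and 5–95% band of per-arm medians, per observation time) and
`local_sensitivity()` computes central finite-difference relative
sensitivities of $V_{tot}(t^\*)$ per treatment group, normalized to a
maximum of 1 within each group, with study-specific parameters lumped;
at the bundled estimates the growth and kill rates $k_g$ and $k_k$
dominate every other parameter, matching the closed-form untreated
sensitivities $k_g t^\*$ and $-k_k t^\*$.

### Scaled problem sizes used by the test suite

The acceptance checks run at sizes chosen to keep the whole suite at desk
scale: the Monte-Carlo TSE quantities use the full 1000 virtual subjects;
parameter recovery fits all three study designs at 5 subjects per arm
(75 subjects) over 3 replicates with the drug potencies held at their
generating values (they are reported by the sources at 30–40% relative
standard error and are not part of the recovery claim; the residual-error
magnitudes stay free, since pinning them interacts with the zero-truncated
eradication volumes and biases the inhibition medians); the AIC experiment
uses the study-3 design at 4 subjects per arm over 20 replicates with the
variability and error magnitudes held at their generating values to keep
each of the 60 fits sharp.

## Known limitations

* Exposure is a single constant concentration per application (the
  observed mean maximum concentration); no pharmacokinetic model is
  provided, matching the exposure representation that described the
  original data best.
* TSE predictions assume the studied fractionation pattern; extrapolating
  the curves to very different schedules is not supported.
* The Laplace/Gauss–Newton marginal likelihood is an approximation; with
  heavily shrunk subjects (eradicated tumors observed mostly at zero
  volume) the curvature term is nearly flat in the $V_0$ random effect.
* Toxicity is not modelled; the compound ranking is an efficacy ranking
  only.
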