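# shared fixtures: published population values, small designs, and a
# memoised store for expensive Monte-Carlo results reused across tests
published <- published_population()

base_params <- function(...) {
  args <- list(kg = 0.44, kk = 0.3, alpha = 0.06, gamma = 0.02,
               v0 = 22, alpha_beta_ratio = 10)
  upd <- list(...)
  args[names(upd)] <- upd
  do.call(tgi_params, args)
}

# population with the published structure but configurable variability
pop_with <- function(omega = c(gamma = 0.64, alpha = 0.5, v0 = 0.4),
                     sigma = c(prop = 0.35, add = 4.4),
                     inhibition = "linear", id50 = NULL,
                     alpha_beta_ratio = published$alpha_beta_ratio) {
  population_model(kg = published$kg, kk = published$kk,
                   alpha = published$alpha, gamma = published$gamma,
                   v0 = published$v0, potency = published$potency,
                   omega = omega, sigma = sigma, inhibition = inhibition,
                   id50 = id50, alpha_beta_ratio = alpha_beta_ratio,
                   gamma_dose_scale = published$gamma_dose_scale)
}

# random admissible parameter draws for property-style tests
draw_params <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    kg <- runif(1, 0.2, 0.8)
    tgi_params(kg = kg, kk = runif(1, 0.05, 0.9) * kg,
               alpha = runif(1, 0.02, 0.2), gamma = runif(1, 0.005, 0.06),
               a = runif(1, 0, 0.7), b = runif(1, 0, 0.5),
               v0 = runif(1, 10, 120))
  })
}

# memoised Monte-Carlo stasis-dose distributions for the headline runs
.acceptance_cache <- new.env(parent = emptyenv())
headline_doses <- function(compound = NULL, conc = 0, n = 1000, seed = 1L) {
  key <- paste0(if (is.null(compound)) "RT" else compound, "_", conc,
                "_", n, "_", seed)
  if (is.null(.acceptance_cache[[key]])) {
    .acceptance_cache[[key]] <- stasis_dose_distribution(
      published, conc = conc, n_subjects = n, problem = stasis_problem(),
      seed = seed, study = 3, compound = compound)
  }
  .acceptance_cache[[key]]
}
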