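# Shared fixtures: small geometries and quick sampler settings so the
# default test run stays fast; acceptance checks scale up where needed.

tiny_layouts <- function(n_pairs = 1, width = 60, length = 120) {
  example_layouts(n_pairs = n_pairs, width = width, length = length)
}

quick_sampler <- function(seed = 1L, n_chains = 4) {
  sampler_config(n_chains = n_chains, n_iterations = 3000, n_burnin = 1000,
                 seed = seed)
}

# Measurements with a known flat truth (all stochastic terms off unless set)
flat_measurements <- function(layouts = tiny_layouts(), effect = 0,
                              noise_sd = 0, fertility_sd = 0, seed = 1L, ...) {
  simulate_measurements(layouts, sim_config(
    treatment_effect = effect, noise_sd = noise_sd,
    fertility_sd = fertility_sd, outlier_rate = 0, seed = seed, ...))
}

# Minimal group_posterior carrying given draws; lets contrast operations be
# tested against closed forms without running MCMC.
fake_posterior <- function(mu, sigma, n = 4000) {
  structure(list(
    draws = data.frame(chain = 1L, iteration = seq_len(n),
                       mu = rep_len(mu, n), sigma = rep_len(sigma, n)),
    acceptance = 1, rhat = c(mu = 1, sigma = 1),
    ess = c(mu = n, sigma = n), spec = NULL, config = NULL,
    sigma_fixed = NULL, n_data = n), class = "group_posterior")
}
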