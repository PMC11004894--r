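lprior_of <- function(spec, mu, sigma) {
  dnorm(mu, spec$mu_loc, spec$mu_scale, log = TRUE) +
    log(2) + dnorm(sigma, 0, spec$sigma_scale, log = TRUE)
}

test_that("log posterior equals a term-by-term brute-force summation", {
  set.seed(8)
  y <- rnorm(37, 3000, 500)
  spec <- model_spec(y)
  for (theta in list(c(2900, 450), c(3100, 600), c(0, 10), c(5000, 2000))) {
    mu <- theta[1]; sigma <- theta[2]
    # oracle: accumulate each point's log density in an explicit loop
    ll <- 0
    for (yi in y) ll <- ll + dnorm(yi, mu, sigma, log = TRUE)
    lp_oracle <- ll + dnorm(mu, spec$mu_loc, spec$mu_scale, log = TRUE) +
      log(2) + dnorm(sigma, 0, spec$sigma_scale, log = TRUE)
    expect_equal(log_posterior(mu, sigma, y, spec), lp_oracle)
    # the sufficient-statistic route used inside the sampler agrees exactly
    expect_equal(
      yieldbayes:::log_post_ss(mu, sigma, length(y), mean(y),
                               sum((y - mean(y))^2), spec),
      lp_oracle, tolerance = 1e-12)
  }

  # single datum at the mode with sigma 1: likelihood term is -log(2*pi)/2
  wide <- model_spec(mu_loc = 0, mu_scale = 1e6, sigma_scale = 1e6)
  lprior <- dnorm(0, 0, 1e6, log = TRUE) + log(2) + dnorm(1, 0, 1e6, log = TRUE)
  expect_equal(log_posterior(0, 1, 0, wide) - lprior, -0.5 * log(2 * pi))

  # additivity: duplicating the dataset doubles the likelihood term
  lp1 <- log_posterior(3000, 500, y, spec)
  lp2 <- log_posterior(3000, 500, c(y, y), spec)
  expect_equal(lp2 - lp1, lp1 - lprior_of(spec, 3000, 500))

  # invalid sigma is rejected softly, not an exception
  expect_identical(log_posterior(3000, -1, y, spec), -Inf)
  expect_identical(log_posterior(3000, 0, y, spec), -Inf)
})

test_that("Metropolis sampler recovers known truth and is deterministic", {
  set.seed(14)
  y <- rnorm(200, 10, 1)
  cfg <- quick_sampler(seed = 3)
  post <- metropolis_sample(y, config = cfg)
  mu_hat <- mean(post$draws$mu); mu_sd <- sd(post$draws$mu)
  expect_lt(abs(mu_hat - 10), 3 * mu_sd)
  expect_true(all(post$draws$sigma > 0))
  expect_lt(abs(mean(post$draws$sigma) - 1), 3 * sd(post$draws$sigma) + 0.1)
  # equal draw counts per parameter and chain
  expect_equal(nrow(post$draws),
               cfg$n_chains * (cfg$n_iterations - cfg$n_burnin))
  # determinism contract
  post2 <- metropolis_sample(y, config = cfg)
  expect_identical(post$draws, post2$draws)
  # a different seed gives different chains
  post3 <- metropolis_sample(y, config = quick_sampler(seed = 4))
  expect_false(identical(post$draws$mu, post3$draws$mu))
})

test_that("with sigma fixed the posterior of mu matches the conjugate closed form", {
  set.seed(2)
  sigma0 <- 2
  y <- rnorm(120, 50, sigma0)
  m0 <- 48; s0 <- 5   # informative enough that the prior matters
  spec <- model_spec(mu_loc = m0, mu_scale = s0, sigma_scale = 10)
  post <- metropolis_sample(y, spec = spec,
                            config = sampler_config(n_iterations = 6000,
                                                    n_burnin = 1000, seed = 9),
                            sigma_fixed = sigma0)
  # conjugate normal-normal posterior
  prec <- 1 / s0^2 + length(y) / sigma0^2
  mu_post <- (m0 / s0^2 + sum(y) / sigma0^2) / prec
  sd_post <- sqrt(1 / prec)
  ess <- post$ess["mu"]
  mc_se <- sd_post / sqrt(ess)
  expect_lt(abs(mean(post$draws$mu) - mu_post), 4 * mc_se)
  expect_equal(sd(post$draws$mu), sd_post, tolerance = 0.1)
  expect_true(all(post$draws$sigma == sigma0))
})

test_that("MCMC moments agree with dense grid integration of the posterior", {
  set.seed(5)
  y <- rnorm(50, 3000, 400)
  spec <- model_spec(y)
  oracle <- yieldbayes:::grid_posterior_moments(y, spec, n_grid = 300)
  post <- metropolis_sample(y, spec = spec,
                            config = sampler_config(n_iterations = 8000,
                                                    n_burnin = 2000, seed = 17))
  for (par in c("mu", "sigma")) {
    draws <- post$draws[[par]]
    mc_se <- sd(draws) / sqrt(post$ess[par])
    expect_lt(abs(mean(draws) - oracle[[paste0(par, "_mean")]]), 3 * mc_se)
    expect_equal(sd(draws), oracle[[paste0(par, "_sd")]], tolerance = 0.10)
  }
})

test_that("split-chain R-hat separates converged from divergent chains", {
  set.seed(23)
  # chains from the same distribution: R-hat below 1.01
  same <- matrix(rnorm(4000 * 4), ncol = 4)
  expect_lt(compute_rhat(same), 1.01)
  expect_gte(compute_rhat(same), sqrt((2000 - 1) / 2000))  # finite-sample floor
  # identical chains: no between-chain disagreement
  one <- rnorm(1000)
  expect_lt(compute_rhat(cbind(one, one)), 1.01)
  # far-separated chains: direct evaluation of the between/within formula
  apart <- cbind(rnorm(500, 0), rnorm(500, 20))
  r <- compute_rhat(apart)
  expect_gt(r, 5)
  half <- 250; n <- 250
  split <- cbind(apart[1:half, ], apart[(half + 1):(2 * half), ])
  w <- mean(apply(split, 2, var)); b <- n * var(colMeans(split))
  expect_equal(r, sqrt(((n - 1) / n * w + b / n) / w))
  # degenerate zero-variance chains: defined result with warning
  expect_warning(r0 <- compute_rhat(matrix(1, 100, 2)), "zero")
  expect_equal(r0, 1)
  expect_error(compute_rhat(matrix(1:3, ncol = 1)), "2 chains")
})

test_that("effective sample size reflects autocorrelation", {
  set.seed(4)
  iid <- matrix(rnorm(2000 * 4), ncol = 4)
  ess_iid <- compute_ess(iid)
  expect_gt(ess_iid, 0.5 * 8000)
  expect_lte(ess_iid, 8000)
  # an AR(1) chain with high persistence has far fewer effective draws
  ar <- replicate(4, as.vector(arima.sim(list(ar = 0.95), 2000)))
  expect_lt(compute_ess(ar), 0.2 * 8000)
})

test_that("fit_group builds priors from data and enforces convergence", {
  m <- flat_measurements(tiny_layouts(), effect = 0, noise_sd = 300, seed = 6)
  g <- m[m$group == "test", ]
  post <- fit_group(g, config = quick_sampler(seed = 11))
  expect_identical(attr(post, "group"), "test")
  expect_equal(post$spec$mu_loc, mean(g$dry_yield))
  expect_equal(post$spec$mu_scale, 10 * sd(g$dry_yield))
  expect_lt(max(post$rhat), 1.01)
  # mixed groups are refused
  expect_error(fit_group(m), "single group")
  # an unconverged fit raises an error that carries the diagnostics
  err <- tryCatch(
    fit_group(g$dry_yield,
              config = sampler_config(n_chains = 2, n_iterations = 40,
                                      n_burnin = 20, prop_mu = 1e-9,
                                      prop_log_sigma = 1e-9, adapt = FALSE,
                                      seed = 1),
              rhat_threshold = 1.000001),
    error = function(e) e)
  expect_s3_class(err, "error")
  expect_match(conditionMessage(err), "R-hat")
  expect_true(!is.null(err$diagnostics))
})

test_that("posterior sd of mu contracts at roughly 1/sqrt(n)", {
  set.seed(77)
  y_big <- rnorm(2000, 3000, 400)
  sd_small <- sd(metropolis_sample(y_big[1:500],
                                   config = quick_sampler(seed = 21))$draws$mu)
  sd_big <- sd(metropolis_sample(y_big,
                                 config = quick_sampler(seed = 22))$draws$mu)
  expect_equal(sd_big / sd_small, 0.5, tolerance = 0.2)
})
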