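#' Model specification for one group's yield distribution
#'
#' Dry yields of a group are modelled as independent draws from
#' `Normal(mu, sigma)`. Priors are weakly informative and data-scaled:
#' `mu ~ Normal(mu_loc, mu_scale)` and `sigma ~ HalfNormal(sigma_scale)`,
#' with `mu_loc` the sample mean and both scales
#' `prior_scale_factor * sample sd` (default factor 10), so the prior is
#' broad on the scale of the data without being improper.
#'
#' @param y numeric vector of dry yields (kg/ha) used to centre and scale
#'   the priors; ignored if all three hyperparameters are supplied.
#' @param mu_loc,mu_scale prior location and scale for `mu` (kg/ha).
#' @param sigma_scale half-normal prior scale for `sigma` (kg/ha).
#' @param prior_scale_factor dimensionless multiplier applied to the
#'   sample sd when deriving `mu_scale` and `sigma_scale` from data.
#' @return A `model_spec` list.
#' @export
model_spec <- function(y = NULL, mu_loc = NULL, mu_scale = NULL,
                       sigma_scale = NULL, prior_scale_factor = 10) {
  if (is.null(mu_loc) || is.null(mu_scale) || is.null(sigma_scale)) {
    if (is.null(y) || length(y) < 2)
      stop("need data (>= 2 values) to derive priors, or all three hyperparameters",
           call. = FALSE)
    s <- sd(y)
    if (s == 0) s <- max(abs(mean(y)), 1)  # degenerate data: fall back to a broad scale
    mu_loc <- mu_loc %||% mean(y)
    mu_scale <- mu_scale %||% (prior_scale_factor * s)
    sigma_scale <- sigma_scale %||% (prior_scale_factor * s)
  }
  if (mu_scale <= 0 || sigma_scale <= 0)
    stop("prior scales must be positive", call. = FALSE)
  structure(list(mu_loc = mu_loc, mu_scale = mu_scale,
                 sigma_scale = sigma_scale,
                 prior_scale_factor = prior_scale_factor),
            class = "model_spec")
}

#' Sampler configuration
#'
#' Settings for the random-walk Metropolis sampler. Proposal scales left
#' `NULL` are initialised from the data (`2.4 * sd / sqrt(n)` for `mu`,
#' `2.4 / sqrt(2 n)` for `log sigma`) and, when `adapt = TRUE`, tuned
#' during burn-in towards an acceptance rate of about 0.3; adaptation
#' stops at the end of burn-in so the retained chain is a valid Markov
#' chain with the posterior as its stationary distribution.
#'
#' @param n_chains number of independent chains (>= 2 for diagnostics).
#' @param n_iterations iterations per chain, including burn-in.
#' @param n_burnin iterations discarded from the start of each chain.
#' @param prop_mu,prop_log_sigma proposal standard deviations; `NULL` for
#'   data-derived defaults.
#' @param adapt tune proposal scales during burn-in?
#' @param seed integer seed; chain seeds are derived substreams.
#' @return A `sampler_config` list.
#' @export
sampler_config <- function(n_chains = 4, n_iterations = 5000,
                           n_burnin = 1000, prop_mu = NULL,
                           prop_log_sigma = NULL, adapt = TRUE, seed = 1L) {
  if (n_burnin >= n_iterations)
    stop("n_burnin must be smaller than n_iterations", call. = FALSE)
  if (n_chains < 2)
    stop("need at least 2 chains for convergence diagnostics", call. = FALSE)
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 n_burnin = as.integer(n_burnin),
                 prop_mu = prop_mu, prop_log_sigma = prop_log_sigma,
                 adapt = isTRUE(adapt), seed = as.integer(seed)),
            class = "sampler_config")
}

#' Unnormalised log posterior of (mu, sigma)
#'
#' Sum of the normal log likelihood over all measurements plus the log
#' prior densities of [model_spec()]. The evidence term of Bayes' theorem
#' is omitted: MCMC only needs the posterior up to a constant. Returns
#' `-Inf` for `sigma <= 0` so invalid proposals are rejected rather than
#' raising an error.
#'
#' @param mu,sigma parameter values (kg/ha).
#' @param y numeric vector of dry yields (kg/ha).
#' @param spec a [model_spec()].
#' @return Scalar log density (unnormalised).
#' @export
log_posterior <- function(mu, sigma, y, spec) {
  stopifnot(inherits(spec, "model_spec"), length(y) > 0)
  if (!is.finite(sigma) || sigma <= 0) return(-Inf)
  sum(dnorm(y, mu, sigma, log = TRUE)) +
    dnorm(mu, spec$mu_loc, spec$mu_scale, log = TRUE) +
    log(2) + dnorm(sigma, 0, spec$sigma_scale, log = TRUE)
}

# O(1) log posterior from sufficient statistics (n, ybar, ss = sum (y-ybar)^2).
# Identical to log_posterior analytically; used inside the chain loop.
log_post_ss <- function(mu, sigma, n, ybar, ss, spec) {
  if (!is.finite(sigma) || sigma <= 0) return(-Inf)
  -0.5 * n * log(2 * pi) - n * log(sigma) -
    (ss + n * (ybar - mu)^2) / (2 * sigma^2) +
    dnorm(mu, spec$mu_loc, spec$mu_scale, log = TRUE) +
    log(2) + dnorm(sigma, 0, spec$sigma_scale, log = TRUE)
}

# One Metropolis chain on (mu, log sigma); Jacobian term `ls` makes the
# chain target the posterior of (mu, sigma). Returns post-burn-in draws
# and the post-burn-in acceptance rate.
run_chain <- function(n, ybar, ss, spec, cfg, scales, chain_seed,
                      sigma_fixed = NULL) {
  set.seed(chain_seed)
  n_it <- cfg$n_iterations; n_b <- cfg$n_burnin
  fixed <- !is.null(sigma_fixed)
  target <- function(mu, ls) {
    sig <- if (fixed) sigma_fixed else exp(ls)
    lp <- log_post_ss(mu, sig, n, ybar, ss, spec)
    if (fixed) lp else lp + ls
  }
  # overdispersed start
  mu <- ybar + rnorm(1, 0, 2 * sqrt(ss / n / n + 1e-12) + 1e-6)
  ls <- if (fixed) log(sigma_fixed) else log(sqrt(ss / max(n - 1, 1))) + rnorm(1, 0, 0.2)
  lp <- target(mu, ls)
  eps_mu <- rnorm(n_it); eps_ls <- rnorm(n_it); logu <- log(runif(n_it))
  mu_out <- numeric(n_it); ls_out <- numeric(n_it); acc <- logical(n_it)
  s_mu <- scales[1]; s_ls <- scales[2]
  win_acc <- 0L; win_n <- 0L
  for (i in seq_len(n_it)) {
    mu_p <- mu + s_mu * eps_mu[i]
    ls_p <- if (fixed) ls else ls + s_ls * eps_ls[i]
    lp_p <- target(mu_p, ls_p)
    if (logu[i] < lp_p - lp) {
      mu <- mu_p; ls <- ls_p; lp <- lp_p; acc[i] <- TRUE
    }
    mu_out[i] <- mu; ls_out[i] <- ls
    if (cfg$adapt && i <= n_b) {
      win_acc <- win_acc + acc[i]; win_n <- win_n + 1L
      if (win_n == 50L) {  # Robbins-Monro-style scale update towards 0.3
        f <- exp(win_acc / win_n - 0.3)
        s_mu <- s_mu * f
        if (!fixed) s_ls <- s_ls * f
        win_acc <- 0L; win_n <- 0L
      }
    }
  }
  keep <- (n_b + 1):n_it
  list(mu = mu_out[keep],
       sigma = if (fixed) rep(sigma_fixed, length(keep)) else exp(ls_out[keep]),
       acceptance = mean(acc[keep]))
}

#' Sample the posterior by random-walk Metropolis
#'
#' Runs `n_chains` independent Metropolis chains on `(mu, log sigma)`
#' with diagonal Gaussian proposals. Sampling `sigma` on the log scale
#' (with the Jacobian correction) avoids boundary rejections; the
#' acceptance rule is the standard Metropolis ratio on the log scale.
#' Split-chain R-hat and effective sample sizes are attached.
#'
#' @param y numeric vector of dry yields (kg/ha).
#' @param spec a [model_spec()]; derived from `y` if `NULL`.
#' @param config a [sampler_config()].
#' @param sigma_fixed optional known `sigma`; if given, only `mu` is
#'   sampled (conjugate-check mode).
#' @return A `group_posterior`: `draws` (data frame `chain`, `iteration`,
#'   `mu`, `sigma`), `acceptance` per chain, `rhat` and `ess` per
#'   parameter, plus the spec and config used.
#' @examples
#' set.seed(1)
#' post <- metropolis_sample(rnorm(200, 10, 1),
#'                           config = sampler_config(n_iterations = 2000,
#'                                                   n_burnin = 500, seed = 1))
#' post
#' @export
metropolis_sample <- function(y, spec = NULL, config = sampler_config(),
                              sigma_fixed = NULL) {
  stopifnot(is.numeric(y), length(y) >= 2, inherits(config, "sampler_config"))
  if (is.null(spec)) spec <- model_spec(y)
  n <- length(y); ybar <- mean(y); ss <- sum((y - ybar)^2)
  scales <- c(config$prop_mu %||% (2.4 * sd(y) / sqrt(n)),
              config$prop_log_sigma %||% (2.4 / sqrt(2 * n)))
  chain_seeds <- derive_seeds(config$seed, config$n_chains)
  chains <- lapply(seq_len(config$n_chains), function(c) {
    run_chain(n, ybar, ss, spec, config, scales, chain_seeds[c], sigma_fixed)
  })
  n_keep <- config$n_iterations - config$n_burnin
  draws <- data.frame(
    chain = rep(seq_len(config$n_chains), each = n_keep),
    iteration = rep(seq_len(n_keep), config$n_chains),
    mu = unlist(lapply(chains, `[[`, "mu")),
    sigma = unlist(lapply(chains, `[[`, "sigma"))
  )
  acceptance <- vapply(chains, `[[`, numeric(1), "acceptance")
  if (any(acceptance < 0.05))
    warning(sprintf("low Metropolis acceptance rate (min %.3f); chains may mix poorly",
                    min(acceptance)), call. = FALSE)
  mu_mat <- matrix(draws$mu, nrow = n_keep)
  sig_mat <- matrix(draws$sigma, nrow = n_keep)
  rhat <- c(mu = compute_rhat(mu_mat),
            sigma = if (is.null(sigma_fixed)) compute_rhat(sig_mat) else 1)
  ess <- c(mu = compute_ess(mu_mat),
           sigma = if (is.null(sigma_fixed)) compute_ess(sig_mat)
                   else n_keep * config$n_chains)
  structure(list(draws = draws, acceptance = acceptance, rhat = rhat,
                 ess = ess, spec = spec, config = config,
                 sigma_fixed = sigma_fixed, n_data = n),
            class = "group_posterior")
}

#' @export
print.group_posterior <- function(x, ...) {
  cat(sprintf("Posterior of (mu, sigma) from %d chains x %d draws (n = %d)\n",
              max(x$draws$chain), max(x$draws$iteration), x$n_data))
  cat(sprintf("  mu    : mean %.1f, sd %.2f kg/ha  (rhat %.3f, ess %.0f)\n",
              mean(x$draws$mu), sd(x$draws$mu), x$rhat["mu"], x$ess["mu"]))
  cat(sprintf("  sigma : mean %.1f, sd %.2f kg/ha  (rhat %.3f, ess %.0f)\n",
              mean(x$draws$sigma), sd(x$draws$sigma), x$rhat["sigma"],
              x$ess["sigma"]))
  cat(sprintf("  acceptance: %s\n",
              paste(sprintf("%.2f", x$acceptance), collapse = " ")))
  invisible(x)
}

#' Split-chain potential scale reduction (R-hat)
#'
#' Gelman–Rubin statistic with each chain split in half, so within-chain
#' trends inflate the value. Values near 1 indicate the chains agree;
#' stationary chains give values below about 1.01.
#'
#' @param chains matrix of draws, one column per chain (>= 2 chains,
#'   >= 4 draws each).
#' @return Scalar R-hat (>= 1 up to floating tolerance).
#' @export
compute_rhat <- function(chains) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2 || nrow(chains) < 4)
    stop("need >= 2 chains of >= 4 draws", call. = FALSE)
  half <- floor(nrow(chains) / 2)
  split <- cbind(chains[1:half, , drop = FALSE],
                 chains[(half + 1):(2 * half), , drop = FALSE])
  m <- ncol(split); n <- nrow(split)
  w <- mean(apply(split, 2, var))
  b <- n * var(colMeans(split))
  if (w == 0) {
    warning("zero within-chain variance; R-hat undefined, returning 1",
            call. = FALSE)
    return(1)
  }
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Effective sample size of MCMC draws
#'
#' Multi-chain effective sample size from combined autocorrelations
#' (Geyer initial monotone positive sequence), as used by modern MCMC
#' diagnostics.
#'
#' @param chains matrix of draws, one column per chain.
#' @return Scalar effective sample size.
#' @export
compute_ess <- function(chains) {
  chains <- as.matrix(chains)
  m <- ncol(chains); n <- nrow(chains)
  w <- mean(apply(chains, 2, var))
  varplus <- (n - 1) / n * w + (if (m > 1) var(colMeans(chains)) else 0)
  if (varplus == 0) return(m * n)
  max_lag <- min(n - 1, 500)
  acov <- sapply(seq_len(m), function(c)
    acf(chains[, c], lag.max = max_lag, type = "covariance",
        plot = FALSE, demean = TRUE)$acf[, 1, 1])
  rho <- 1 - (w - rowMeans(acov)[-1]) / varplus   # lags 1..max_lag
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  n_pair <- floor(length(rho) / 2)
  tau <- 1
  prev <- Inf
  for (k in seq_len(n_pair)) {
    p <- rho[2 * k - 1] + rho[2 * k]
    if (p < 0) break
    p <- min(p, prev); prev <- p
    tau <- tau + 2 * p
  }
  min(m * n, m * n / tau)
}

#' Fit the normal model to one group's measurements
#'
#' Builds a data-scaled [model_spec()], runs [metropolis_sample()], and
#' checks convergence: if the largest split-chain R-hat exceeds
#' `rhat_threshold` the fit is refused with an error that carries the
#' diagnostics, rather than returning an unreliable posterior.
#'
#' @param x a `yield_measurements` data frame containing a single group,
#'   or a numeric vector of dry yields (kg/ha).
#' @param spec optional [model_spec()]; derived from the data if `NULL`.
#' @param config a [sampler_config()].
#' @param rhat_threshold convergence limit on R-hat (default 1.01).
#' @return A `group_posterior` (see [metropolis_sample()]) with a
#'   `group` attribute when the input carried one.
#' @export
fit_group <- function(x, spec = NULL, config = sampler_config(),
                      rhat_threshold = 1.01) {
  grp <- NULL
  if (inherits(x, "yield_measurements") || is.data.frame(x)) {
    grp <- unique(x$group)
    if (length(grp) != 1)
      stop("fit_group() expects measurements from a single group; got: ",
           paste(grp, collapse = ", "), call. = FALSE)
    y <- x$dry_yield
  } else y <- as.numeric(x)
  if (length(y) < 2) stop("need at least 2 measurements", call. = FALSE)
  post <- metropolis_sample(y, spec = spec, config = config)
  if (max(post$rhat) > rhat_threshold) {
    cond <- simpleError(sprintf(
      "chains did not converge: max R-hat %.4f > %.3f (mu %.4f, sigma %.4f)",
      max(post$rhat), rhat_threshold, post$rhat["mu"], post$rhat["sigma"]))
    cond$diagnostics <- list(rhat = post$rhat, ess = post$ess,
                             acceptance = post$acceptance)
    stop(cond)
  }
  attr(post, "group") <- grp
  post
}

# Dense grid integration of the unnormalised posterior over (mu, sigma).
# Independent oracle for the sampler on small datasets; returns posterior
# means and sds of both parameters.
grid_posterior_moments <- function(y, spec, n_grid = 200, half_width = 6) {
  n <- length(y); ybar <- mean(y); s <- sd(y)
  mu_se <- s / sqrt(n)
  mus <- seq(ybar - half_width * mu_se, ybar + half_width * mu_se,
             length.out = n_grid)
  sigs <- seq(max(s / 3, 1e-6), s * 3, length.out = n_grid)
  lp <- outer(mus, sigs, Vectorize(function(m, sg) log_posterior(m, sg, y, spec)))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  pm <- rowSums(p); ps <- colSums(p)
  list(mu_mean = sum(pm * mus),
       mu_sd = sqrt(sum(pm * mus^2) - sum(pm * mus)^2),
       sigma_mean = sum(ps * sigs),
       sigma_sd = sqrt(sum(ps * sigs^2) - sum(ps * sigs)^2))
}
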