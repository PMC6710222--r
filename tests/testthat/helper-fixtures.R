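# shared fixtures: conjugate toy targets with analytic posteriors and
# marginal likelihoods, and a quick LBA fit configuration for smoke tests

# y_i ~ N(mu, 1), mu ~ N(0, 1)
normal_toy <- function(seed = 7, n = 10, mu = 0.5) {
  set.seed(seed)
  y <- rnorm(n, mu, 1)
  S <- diag(n) + matrix(1, n, n)
  list(
    y = y,
    post_mean = sum(y) / (n + 1),
    post_var = 1 / (n + 1),
    logml = as.numeric(-0.5 * (n * log(2 * pi) + determinant(S)$modulus +
                                 t(y) %*% solve(S) %*% y)),
    target = mcmc_target(
      k = 1,
      log_lik = function(th) vapply(th[, 1], function(m)
        sum(dnorm(y, m, 1, log = TRUE)), numeric(1)),
      log_prior = function(th) dnorm(th[, 1], 0, 1, log = TRUE),
      sample_init = function(k) matrix(rnorm(k), k),
      trial_loglik = function(th)
        t(vapply(th[, 1], function(m) dnorm(y, m, 1, log = TRUE),
                 numeric(length(y)))),
      par_names = "mu"))
}

# y ~ Binomial(n, p), p ~ Beta(a, b)
betabinom_toy <- function(y = 6, n = 20, a = 2, b = 2) {
  list(
    y = y, n = n,
    logml = lchoose(n, y) + lbeta(y + a, n - y + b) - lbeta(a, b),
    target = mcmc_target(
      k = 1,
      log_lik = function(th) ifelse(
        th[, 1] > 0 & th[, 1] < 1,
        lchoose(n, y) + y * log(th[, 1]) + (n - y) * log(1 - th[, 1]),
        -Inf),
      log_prior = function(th) dbeta(th[, 1], a, b, log = TRUE),
      sample_init = function(k) matrix(rbeta(k, a, b), k),
      par_names = "p"))
}

# small LBA fit for tests that need a posterior but not a converged study
quick_lba_fit <- function(variant = "complex", n_trials = 50, seed = 11,
                          burn = 200, keep = 200,
                          cell = list(drift_size = "moderate",
                                      threshold_size = "moderate",
                                      arrangement = "extreme",
                                      trials_per_condition = n_trials)) {
  data <- generate_dataset(cell, replicate = 1, master_seed = seed)
  demcmc_sample(lba_model(variant), data, burn = burn, keep = keep,
                seed = seed)
}
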