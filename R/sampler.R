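#' Generic MCMC target for the DE-MCMC engine
#'
#' Wraps an arbitrary (small) Bayesian model so that it can be sampled with
#' the same differential-evolution engine used for the LBA models; used in
#' the package's tests against conjugate targets with known posteriors.
#'
#' @param k number of free parameters.
#' @param log_lik function(theta_matrix) -> per-row log-likelihood.
#' @param log_prior function(theta_matrix) -> per-row log prior.
#' @param sample_init function(n) -> n x k matrix of starting values.
#' @param trial_loglik optional function(theta_matrix) -> draws x trials
#'   log-likelihood matrix.
#' @param par_names optional parameter names.
#' @return An object of class `mcmc_target`.
#' @export
mcmc_target <- function(k, log_lik, log_prior, sample_init,
                        trial_loglik = NULL, par_names = NULL) {
  structure(list(k = k, log_lik = log_lik, log_prior = log_prior,
                 sample_init = sample_init, trial_loglik = trial_loglik,
                 par_names = par_names %||% paste0("theta", seq_len(k))),
            class = "mcmc_target")
}

# uniform internal interface over lba_model and mcmc_target; eval() returns
# log prior and log likelihood in one pass (one support check per proposal)
target_fns <- function(model, data, floor = 1e-10) {
  if (inherits(model, "lba_model")) {
    empty <- is.null(data) || nrow(data) == 0
    rt <- data$rt
    correct <- as.integer(data$response == "correct")
    cond <- data$condition
    list(k = model$k, par_names = model$par_names,
         eval = function(th) {
           ok <- theta_support_ok(th, model)
           lp <- ll <- rep(-Inf, nrow(th))
           if (any(ok)) {
             thok <- th[ok, , drop = FALSE]
             lp[ok] <- prior_logdens(thok, model)
             ll[ok] <- if (empty) 0 else {
               cp <- theta_to_condition_matrices(thok, model)
               cpp_lba_loglik(rt, correct, cond, cp$par1, cp$par2, floor)
             }
           }
           list(lp = lp, ll = ll)
         },
         sample_init = function(n) sample_prior(model, n),
         trial_loglik = function(th) {
           cp <- theta_to_condition_matrices(th, model)
           cpp_lba_trial_loglik(rt, correct, cond, cp$par1, cp$par2, floor)
         })
  } else if (inherits(model, "mcmc_target")) {
    c(model[c("k", "par_names", "sample_init", "trial_loglik")],
      list(eval = function(th) {
        lp <- model$log_prior(th)
        ll <- rep(-Inf, nrow(th))
        fin <- is.finite(lp)
        if (any(fin)) ll[fin] <- model$log_lik(th[fin, , drop = FALSE])
        list(lp = lp, ll = ll)
      }))
  } else stop("model must be an lba_model or mcmc_target")
}

# crossover + migration differential-evolution engine; `temps` holds one
# likelihood temperature per chain (all 1 for an ordinary posterior)
de_engine <- function(fns, n_chains, burn, keep, temps, migrate_prob = 0.05,
                      gamma = NULL, eps = 1e-3, max_init_tries = 1000,
                      init = NULL) {
  k <- fns$k
  gamma <- gamma %||% (2.38 / sqrt(2 * k))
  theta <- matrix(NA_real_, n_chains, k)
  ll <- lp <- rep(-Inf, n_chains)
  need <- rep(TRUE, n_chains)
  if (!is.null(init)) {
    pick <- init[sample.int(nrow(init), n_chains, replace = TRUE), ,
                 drop = FALSE]
    ev <- fns$eval(pick)
    good <- is.finite(ev$lp) & is.finite(ev$ll)
    theta[good, ] <- pick[good, , drop = FALSE]
    ll[good] <- ev$ll[good]
    lp[good] <- ev$lp[good]
    need <- !good
  }
  for (try in seq_len(max_init_tries)) {
    if (!any(need)) break
    cand <- fns$sample_init(sum(need))
    ev <- fns$eval(cand)
    good <- is.finite(ev$lp) & is.finite(ev$ll)
    if (any(good)) {
      idx <- which(need)[which(good)]
      theta[idx, ] <- cand[good, , drop = FALSE]
      ll[idx] <- ev$ll[good]
      lp[idx] <- ev$lp[good]
      need[idx] <- FALSE
    }
  }
  if (any(need)) stop("could not initialize all chains at finite log posterior")

  n_iter <- burn + keep
  S <- keep * n_chains
  draws <- matrix(NA_real_, S, k, dimnames = list(NULL, fns$par_names))
  out_ll <- out_lp <- numeric(S)
  out_chain <- integer(S)
  pos <- 0L

  for (it in seq_len(n_iter)) {
    in_burn <- it <= burn
    if (in_burn && migrate_prob > 0 && stats::runif(1) < migrate_prob) {
      # migration: cycle states through a random subset of chains
      nm <- sample.int(n_chains, 1)
      cyc <- sample.int(n_chains, nm)
      if (nm > 1) {
        from <- cyc[c(nm, seq_len(nm - 1))]
        for (j in seq_len(nm)) {
          i <- cyc[j]; src <- from[j]
          num <- temps[i] * ll[src] + lp[src]
          den <- temps[i] * ll[i] + lp[i]
          if (is.finite(num) && log(stats::runif(1)) < num - den) {
            theta[i, ] <- theta[src, ]; ll[i] <- ll[src]; lp[i] <- lp[src]
          }
        }
      }
    } else {
      # crossover: theta* = theta_i + gamma (theta_m - theta_n) + eps noise
      self <- seq_len(n_chains)
      m <- sample.int(n_chains, n_chains, replace = TRUE)
      n <- sample.int(n_chains, n_chains, replace = TRUE)
      repeat {
        bad <- m == self | n == self | m == n
        if (!any(bad)) break
        m[bad] <- sample.int(n_chains, sum(bad), replace = TRUE)
        n[bad] <- sample.int(n_chains, sum(bad), replace = TRUE)
      }
      prop <- theta + gamma * (theta[m, , drop = FALSE] -
                               theta[n, , drop = FALSE]) +
        matrix(stats::runif(n_chains * k, -eps, eps), n_chains, k)
      ev <- fns$eval(prop)
      plp <- ev$lp; pll <- ev$ll
      logr <- (temps * pll + plp) - (temps * ll + lp)
      logr[!is.finite(plp) | !is.finite(pll)] <- -Inf
      acc <- log(stats::runif(n_chains)) < logr
      if (any(acc)) {
        theta[acc, ] <- prop[acc, , drop = FALSE]
        ll[acc] <- pll[acc]; lp[acc] <- plp[acc]
      }
    }
    if (!in_burn) {
      idx <- pos + seq_len(n_chains)
      draws[idx, ] <- theta
      out_ll[idx] <- ll
      out_lp[idx] <- lp
      out_chain[idx] <- seq_len(n_chains)
      pos <- pos + n_chains
    }
  }
  list(draws = draws, log_lik = out_ll, log_prior = out_lp,
       chain = out_chain, temps = temps)
}

#' Differential-evolution MCMC posterior sampling
#'
#' Samples the posterior of a model with the DE-MCMC algorithm: per chain
#' and iteration a crossover proposal `theta* = theta_i + gamma (theta_m -
#' theta_n) + U(-0.001, 0.001)` with distinct chains `m, n != i` and `gamma
#' = 2.38 / sqrt(2 k)`, plus an occasional migration step (probability 0.05,
#' burn-in only) that cycles states through a random chain subset to recover
#' outlier chains. Chains start from prior draws, re-drawn until the log
#' posterior is finite. The default chain count is `3 k`.
#'
#' @param model an [lba_model] or [mcmc_target].
#' @param data a [choice_rt] dataset (ignored for self-contained targets).
#' @param n_chains number of parallel chains; default `3 * k` (at least
#'   `k + 2`).
#' @param burn,keep iterations discarded / retained per chain.
#' @param seed optional integer seed.
#' @param migrate_prob per-iteration migration probability during burn-in.
#' @param store_trial_loglik keep the per-draw x per-trial log-likelihood
#'   matrix (needed for WAIC)?
#' @param floor per-trial density floor for LBA likelihoods.
#' @return An object of class `posterior_samples`: `draws` (S x k matrix),
#'   `log_lik`, `log_prior` (per draw), `chain`, `trial_loglik` (S x n or
#'   NULL), `temps`, `model`, and `n_obs`.
#' @export
demcmc_sample <- function(model, data = NULL, n_chains = NULL, burn = 1000,
                          keep = 1000, seed = NULL,
                          migrate_prob = 0.05, store_trial_loglik = TRUE,
                          floor = 1e-10) {
  if (!is.null(seed)) set.seed(seed)
  fns <- target_fns(model, data, floor)
  n_chains <- n_chains %||% (3L * fns$k)
  if (n_chains < fns$k + 2) stop("need at least k + 2 chains")
  res <- de_engine(fns, n_chains, burn, keep, temps = rep(1, n_chains),
                   migrate_prob = migrate_prob)
  trial_ll <- NULL
  if (store_trial_loglik && !is.null(fns$trial_loglik) &&
      (is.null(data) || nrow(data) > 0)) {
    trial_ll <- fns$trial_loglik(res$draws)
  }
  structure(list(draws = res$draws, log_lik = res$log_lik,
                 log_prior = res$log_prior, chain = res$chain,
                 trial_loglik = trial_ll, temps = 1,
                 model = model, data = data,
                 n_obs = if (is.null(data)) NA_integer_ else nrow(data)),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("posterior_samples: %d draws x %d parameters (%d chains)\n",
              nrow(x$draws), ncol(x$draws), max(x$chain)))
  invisible(x)
}

#' Power-posterior temperature ladder
#'
#' @param n_temps number of temperatures (default 40).
#' @param power exponent of the schedule `t_j = ((j - 1) / (J - 1))^power`;
#'   the default fifth power concentrates temperatures near zero where the
#'   integrand changes fastest.
#' @return Numeric vector of temperatures from 0 to 1.
#' @export
temperature_ladder <- function(n_temps = 40, power = 5) {
  if (n_temps < 2) stop("need at least 2 temperatures")
  ((seq_len(n_temps) - 1) / (n_temps - 1))^power
}

#' Sample all power posteriors of a model in one DE-MCMC run
#'
#' Runs one differential-evolution population in which each chain targets
#' the power posterior `p(theta) p(y | theta)^t` at its own temperature `t`
#' (the thermodynamic-integration-via-differential-evolution scheme, one
#' chain per temperature by default). The chain at `t = 0` samples the
#' prior, with proposals rejected only on prior support; the chain at
#' `t = 1` samples the ordinary posterior. Records the per-temperature mean
#' retained log-likelihood, the integrand of the thermodynamic identity.
#'
#' @inheritParams demcmc_sample
#' @param temps temperature ladder (default [temperature_ladder()] with 40
#'   rungs).
#' @param chains_per_temp chains per temperature rung.
#' @param init optional matrix of starting values (for instance retained
#'   draws from an ordinary posterior fit of the same model); chains start
#'   from rows sampled from it, falling back to prior draws where a row is
#'   invalid. Warm starts from the posterior shorten the ladder's burn-in
#'   substantially, because the high-temperature chains begin in the
#'   typical set while the low-temperature chains relax quickly toward the
#'   wide prior.
#' @return An object of class `ti_ladder`: `temps`, `mean_loglik` (per
#'   temperature), `n_draws` per temperature, and the retained per-chain
#'   log-likelihoods.
#' @export
power_posterior_run <- function(model, data = NULL, temps = temperature_ladder(),
                                chains_per_temp = 1, burn = 1000, keep = 1000,
                                seed = NULL, migrate_prob = 0.05,
                                floor = 1e-10, init = NULL) {
  if (is.unsorted(temps, strictly = TRUE) || temps[1] != 0 ||
      temps[length(temps)] != 1)
    stop("temps must be strictly increasing from 0 to 1")
  if (!is.null(seed)) set.seed(seed)
  fns <- target_fns(model, data, floor)
  chain_temps <- rep(temps, each = chains_per_temp)
  res <- de_engine(fns, length(chain_temps), burn, keep, temps = chain_temps,
                   migrate_prob = migrate_prob, init = init)
  by_temp <- split(res$log_lik, chain_temps[res$chain])
  mean_ll <- vapply(by_temp, mean, numeric(1))
  ord <- order(as.numeric(names(mean_ll)))
  structure(list(temps = temps, mean_loglik = unname(mean_ll[ord]),
                 n_draws = unname(lengths(by_temp)[ord]),
                 log_lik = res$log_lik, chain_temp = chain_temps[res$chain]),
            class = "ti_ladder")
}

#' Split-chain potential scale reduction diagnostic
#'
#' Splits each chain's retained draws in half and computes the rank-free
#' potential scale reduction factor (R-hat) per parameter across the
#' resulting half-chains.
#'
#' @param fit a `posterior_samples` object.
#' @return Named vector of R-hat values, one per parameter.
#' @export
split_rhat <- function(fit) {
  k <- ncol(fit$draws)
  out <- numeric(k)
  for (j in seq_len(k)) {
    halves <- unlist(lapply(split(fit$draws[, j], fit$chain), function(x) {
      h <- length(x) %/% 2
      list(x[seq_len(h)], x[h + seq_len(h)])
    }), recursive = FALSE)
    m <- length(halves); n <- length(halves[[1]])
    mu <- vapply(halves, mean, numeric(1))
    s2 <- vapply(halves, stats::var, numeric(1))
    B <- n * stats::var(mu)
    W <- mean(s2)
    out[j] <- if (W <= 0) 1 else sqrt(((n - 1) / n * W + B / n) / W)
  }
  stats::setNames(out, colnames(fit$draws))
}
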