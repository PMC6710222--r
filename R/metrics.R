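#' Information criteria for fitted models
#'
#' Deviance-scale model selection criteria. `aic()` and `bic()` take the
#' maximum log-likelihood (by convention here, the best per-draw
#' log-likelihood contained in the retained posterior) and the free
#' parameter count; `bic()` additionally takes the number of observations
#' (total trials across conditions). `dic()` operates on the per-draw
#' log-likelihoods, using the point of minimum deviance in the posterior as
#' its plug-in: with `Dbar` the mean per-draw log-likelihood, the effective
#' parameter count is `P_D = max(log-lik) - Dbar` and `DIC = -2 (Dbar -
#' P_D)`. `dic_p()` applies identical mechanics to the per-draw unnormalized
#' log posterior (log-likelihood + log prior). `waic()` takes the per-draw x
#' per-trial log-likelihood matrix: the log pointwise predictive density is
#' the sum over trials of the log of the mean per-draw likelihood, the
#' penalty is the summed per-trial sample variance (denominator S - 1) of
#' the log-likelihood, and `WAIC = -2 (lpd - penalty)`.
#'
#' @param max_loglik maximum log-likelihood.
#' @param k number of free parameters.
#' @param n number of observations (trials).
#' @param loglik_draws per-draw log-likelihood vector.
#' @param logpost_draws per-draw unnormalized log posterior vector.
#' @param trial_loglik S x n per-draw, per-trial log-likelihood matrix.
#' @return The criterion value (deviance scale; smaller is better).
#' @export
aic <- function(max_loglik, k) {
  stopifnot(k >= 0)
  -2 * (max_loglik - k)
}

#' @rdname aic
#' @export
bic <- function(max_loglik, k, n) {
  stopifnot(k >= 0, n >= 1)
  -2 * (max_loglik - 0.5 * k * log(n))
}

#' @rdname aic
#' @export
dic <- function(loglik_draws) {
  if (length(loglik_draws) == 0) stop("no posterior draws")
  dbar <- mean(loglik_draws)
  pd <- max(loglik_draws) - dbar
  -2 * (dbar - pd)
}

#' @rdname aic
#' @export
dic_p <- function(logpost_draws) dic(logpost_draws)

#' @rdname aic
#' @export
waic <- function(trial_loglik) {
  if (is.null(dim(trial_loglik)) || nrow(trial_loglik) == 0)
    stop("trial_loglik must be an S x n matrix")
  S <- nrow(trial_loglik)
  lpd <- sum(apply(trial_loglik, 2, logsumexp) - log(S))
  pw <- if (S == 1) 0 else sum(apply(trial_loglik, 2, stats::var))
  -2 * (lpd - pw)
}

# free parameter counts of the four variants
variant_k <- c(null = 6L, drift = 7L, threshold = 7L, complex = 8L)

#' Chi-squared deviance test decision tree over the four nested variants
#'
#' Selects among the null, drift, threshold, and complex variants by
#' likelihood-ratio testing, with deviance `= -2 x` maximum log-likelihood.
#' The single-effect model (drift or threshold) with the better deviance is
#' tested against the null (df 1); if significant, that single-effect model
#' is tested against the complex model (df 1) to pick between them;
#' otherwise the null is tested against the complex model (df 2). Negative
#' improvement in deviance counts as a zero statistic.
#'
#' @param deviances named numeric with entries `null`, `drift`, `threshold`,
#'   `complex`.
#' @param alpha significance level (default 0.05).
#' @return List with `selected` (variant name) and `p_values` of the tests
#'   performed.
#' @export
chi2_select <- function(deviances, alpha = 0.05) {
  need <- c("null", "drift", "threshold", "complex")
  if (!all(need %in% names(deviances)))
    stop("deviances must be named null, drift, threshold, complex")
  dev <- deviances[need]
  lr_p <- function(simpler, larger, df) {
    stat <- max(dev[[simpler]] - dev[[larger]], 0)
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  }
  single <- if (dev[["drift"]] <= dev[["threshold"]]) "drift" else "threshold"
  p1 <- lr_p("null", single, df = 1)
  if (p1 < alpha) {
    p2 <- lr_p(single, "complex", df = 1)
    sel <- if (p2 < alpha) "complex" else single
    ps <- c(single_vs_null = p1, single_vs_complex = p2)
  } else {
    p2 <- lr_p("null", "complex",
               df = variant_k[["complex"]] - variant_k[["null"]])
    sel <- if (p2 < alpha) "complex" else "null"
    ps <- c(single_vs_null = p1, null_vs_complex = p2)
  }
  list(selected = sel, p_values = ps)
}

#' Region-of-practical-equivalence bounds for the condition effects
#'
#' Default widths equal the parameter changes defining a small effect:
#' `[-0.3, 0.3]` for the drift difference and `[-0.11, 0.11]` for the
#' threshold difference.
#'
#' @param v_c,b numeric length-2 `(lower, upper)` with `lower < 0 < upper`.
#' @return List of class `rope_bounds`.
#' @export
rope_bounds <- function(v_c = c(-0.3, 0.3), b = c(-0.11, 0.11)) {
  for (bd in list(v_c, b))
    if (length(bd) != 2 || bd[1] >= 0 || bd[2] <= 0)
      stop("each bound must be (lower, upper) with lower < 0 < upper")
  structure(list(v_c = v_c, b = b), class = "rope_bounds")
}

#' Augmented ROPE decision from the complex-model posterior
#'
#' For each effect, forms the posterior of the condition difference on the
#' natural scale (`v_c[2] - v_c[1]` and `b[2] - b[1]`) from the
#' complex-model draws and declares the effect present when more than half
#' of the difference draws fall outside its region of practical equivalence
#' (an exact tie counts as absent). The two binary decisions are always
#' made, so a model is selected in every instance; the selected variant
#' combines them.
#'
#' @param fit complex-model `posterior_samples`.
#' @param bounds a [rope_bounds] object.
#' @return List with `selected`, `prop_outside` (named: drift, threshold),
#'   and `effect_present` logical vector.
#' @export
rope_select <- function(fit, bounds = rope_bounds()) {
  model <- fit$model
  if (!inherits(model, "lba_model") || model$variant != "complex")
    stop("rope_select needs a complex-model fit")
  cp <- theta_to_condition_matrices(fit$draws, model)
  d_v <- cp$par2[, 1] - cp$par1[, 1]
  d_b <- cp$par2[, 6] - cp$par1[, 6]
  p_out <- c(drift = mean(d_v < bounds$v_c[1] | d_v > bounds$v_c[2]),
             threshold = mean(d_b < bounds$b[1] | d_b > bounds$b[2]))
  present <- p_out > 0.5
  sel <- if (present[["drift"]] && present[["threshold"]]) "complex"
         else if (present[["drift"]]) "drift"
         else if (present[["threshold"]]) "threshold"
         else "null"
  list(selected = sel, prop_outside = p_out, effect_present = present)
}

#' Log marginal likelihood by bridge sampling
#'
#' Iterative optimal-bridge estimate of the log marginal likelihood from
#' posterior draws. The retained draws are split in half: the first half
#' fits a moment-matched multivariate normal proposal, the second half
#' enters the bridge iteration together with fresh proposal draws. The
#' iteration uses the optimal bridge function and runs to a relative
#' tolerance of `1e-10` on successive estimates (at most `max_iter`
#' iterations); non-convergence is flagged, not fatal.
#'
#' @param fit a `posterior_samples` object.
#' @param log_post optional function(theta_matrix) -> per-row unnormalized
#'   log posterior; defaults to the fit's stored model and data likelihood
#'   plus prior.
#' @param n_proposal number of proposal draws (default: as many as retained
#'   posterior draws).
#' @param seed optional integer seed.
#' @param tol relative convergence tolerance.
#' @param max_iter maximum bridge iterations.
#' @return List with `logml`, `n_iter`, `converged`.
#' @export
bridge_logml <- function(fit, log_post = NULL, n_proposal = NULL, seed = NULL,
                         tol = 1e-10, max_iter = 1000) {
  if (!is.null(seed)) set.seed(seed)
  draws <- fit$draws
  S <- nrow(draws)
  lpost_draws <- if (is.null(log_post)) fit$log_lik + fit$log_prior else NULL
  # split: first half fits the proposal, second half enters the iteration
  first <- seq_len(S %/% 2)
  second <- setdiff(seq_len(S), first)
  mu <- colMeans(draws[first, , drop = FALSE])
  sigma <- stats::cov(draws[first, , drop = FALSE])
  ch <- chol(sigma + diag(1e-10, ncol(draws)))
  n_prop <- n_proposal %||% S
  z <- matrix(stats::rnorm(n_prop * ncol(draws)), n_prop)
  prop <- sweep(z %*% ch, 2, mu, `+`)

  ldmvn <- function(x) {
    q <- backsolve(ch, t(x) - mu, transpose = TRUE)
    -0.5 * colSums(q^2) - sum(log(diag(ch))) -
      0.5 * ncol(draws) * log(2 * pi)
  }
  lpost_fn <- log_post %||% local({
    fns <- target_fns(fit$model, fit$data)
    function(th) {
      ev <- fns$eval(th)
      ev$lp + ev$ll
    }
  })
  # log ratios l = log unnormalized posterior - log proposal density
  l_post <- (if (!is.null(lpost_draws)) lpost_draws[second]
             else lpost_fn(draws[second, , drop = FALSE])) -
    ldmvn(draws[second, , drop = FALSE])
  l_prop <- lpost_fn(prop) - ldmvn(prop)

  n1 <- length(l_post); n2 <- length(l_prop)
  s1 <- n1 / (n1 + n2); s2 <- n2 / (n1 + n2)
  lstar <- stats::median(l_post)
  e_post <- exp(l_post - lstar)          # finite, order ~1
  e_prop <- exp(l_prop - lstar)          # may underflow to 0: harmless
  r <- 1
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    r_new <- mean(e_prop / (s1 * e_prop + s2 * r)) /
      mean(1 / (s1 * e_post + s2 * r))
    if (!is.finite(r_new) || r_new <= 0) break
    if (abs(r_new - r) / r_new < tol) {
      r <- r_new; converged <- TRUE; break
    }
    r <- r_new
  }
  if (!converged) warning("bridge sampling did not converge")
  list(logml = log(r) + lstar, n_iter = iter, converged = converged)
}

#' Log marginal likelihood by thermodynamic integration
#'
#' Trapezoidal integral of the per-temperature mean log-likelihood over the
#' power-posterior temperature ladder, the discrete form of the
#' thermodynamic identity `log p(y) = integral_0^1 E_t[log p(y|theta)] dt`.
#'
#' @param ladder a `ti_ladder` from [power_posterior_run()].
#' @return List with `logml`.
#' @export
ti_logml <- function(ladder) {
  t <- ladder$temps
  m <- ladder$mean_loglik
  if (is.unsorted(t, strictly = TRUE)) stop("temperatures must be sorted")
  if (t[1] != 0 || t[length(t)] != 1) stop("ladder endpoints must be 0 and 1")
  logml <- sum(diff(t) * (utils::head(m, -1) + utils::tail(m, -1)) / 2)
  list(logml = logml)
}
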