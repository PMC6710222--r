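test_that("information criteria match their printed formulas", {
  expect_equal(aic(-100, 7), 214)
  expect_equal(aic(-50, 0), 100)
  expect_equal(bic(-100, 7, 1), 200)
  expect_equal(bic(-100, 7, 600), 200 + 7 * log(600))
  # BIC - AIC identity on any fit
  expect_equal(bic(-123.4, 8, 600) - aic(-123.4, 8), 8 * (log(600) - 2))

  expect_equal(dic(c(-10, -12)), 24)   # Dbar = -11, P_D = 1
  expect_equal(dic(rep(-3, 50)), 6)    # constant log-lik: P_D = 0
  expect_error(dic(numeric()))

  # single trial, two draws; penalty is the sample variance
  w <- waic(matrix(c(-1, -3), ncol = 1))
  lpd <- log((exp(-1) + exp(-3)) / 2)
  expect_equal(w, -2 * (lpd - 2))
  # one draw: zero penalty
  expect_equal(waic(matrix(c(-1, -2, -3), nrow = 1)), -2 * -6)

  # flat prior makes the prior-inclusive DIC equal the ordinary DIC
  ll <- rnorm(500, -100, 3)
  expect_equal(dic_p(ll + 0), dic(ll))
})

test_that("deviance metrics equal brute-force loop implementations", {
  set.seed(601)
  ll <- rnorm(5000, -200, 5)
  S <- length(ll)
  dbar <- 0; for (s in seq_len(S)) dbar <- dbar + ll[s] / S
  mx <- -Inf; for (s in seq_len(S)) if (ll[s] > mx) mx <- ll[s]
  expect_equal(dic(ll), -2 * (dbar - (mx - dbar)), tolerance = 1e-10)

  lp <- rnorm(S, -3, 1)
  lpost <- ll + lp
  dbar2 <- 0; for (s in seq_len(S)) dbar2 <- dbar2 + lpost[s] / S
  mx2 <- max(lpost)
  expect_equal(dic_p(lpost), -2 * (dbar2 - (mx2 - dbar2)), tolerance = 1e-10)

  tl <- matrix(rnorm(100 * 50, -2, 0.5), 100, 50)
  lpd <- 0; pw <- 0
  for (i in 1:50) {
    lpd <- lpd + log(mean(exp(tl[, i])))
    mu <- mean(tl[, i])
    pw <- pw + sum((tl[, i] - mu)^2) / (nrow(tl) - 1)
  }
  expect_equal(waic(tl), -2 * (lpd - pw), tolerance = 1e-10)

  # invariant to draw order
  perm <- sample(S)
  expect_equal(dic(ll[perm]), dic(ll))
  expect_equal(waic(tl[sample(100), ]), waic(tl))
})

test_that("chi-squared decision tree follows the printed procedure", {
  devs <- function(n, d, t, cx) c(null = n, drift = d, threshold = t,
                                  complex = cx)
  # all equal: zero statistics are never significant
  expect_equal(chi2_select(devs(100, 100, 100, 100))$selected, "null")
  # strong single effect, no gain from complex
  r <- chi2_select(devs(100, 90, 95, 89))
  expect_equal(r$selected, "drift")
  expect_equal(unname(r$p_values["single_vs_null"]),
               pchisq(10, 1, lower.tail = FALSE))
  expect_equal(unname(r$p_values["single_vs_complex"]),
               pchisq(1, 1, lower.tail = FALSE))
  # nothing significant anywhere: df-2 null-vs-complex test
  r2 <- chi2_select(devs(100, 99.5, 99.6, 99.0))
  expect_equal(r2$selected, "null")
  expect_equal(unname(r2$p_values["null_vs_complex"]),
               pchisq(1, 2, lower.tail = FALSE))
  # large two-parameter improvement is caught by the df-2 test
  expect_equal(chi2_select(devs(100, 99.5, 99.6, 80))$selected, "complex")
  expect_error(chi2_select(c(null = 1, drift = 2)))
})

test_that("augmented ROPE decides each effect by majority posterior mass", {
  fit <- quick_lba_fit("complex", n_trials = 30, seed = 603,
                       burn = 100, keep = 100)
  # synthetic draws: overwrite the posterior with controlled differences
  doctor <- function(fit, d_v, d_b) {
    n <- nrow(fit$draws)
    fit$draws[, "v_c.1"] <- 3
    fit$draws[, "v_c.2"] <- 3 + d_v
    fit$draws[, "A"] <- 1
    fit$draws[, "B.1"] <- 1
    fit$draws[, "B.2"] <- 1 + d_b
    fit
  }
  r0 <- rope_select(doctor(fit, rep(0, 200), rep(0, 200)))
  expect_equal(r0$selected, "null")
  expect_false(any(r0$effect_present))

  r1 <- rope_select(doctor(fit, rep(1, 200), rep(0, 200)))
  expect_equal(r1$selected, "drift")
  expect_equal(unname(r1$prop_outside["drift"]), 1)

  # 60% of drift draws inside the ROPE: effect absent
  d_v <- c(rep(0, 120), rep(1, 80))
  r2 <- rope_select(doctor(fit, d_v, rep(0.5, 200)))
  expect_equal(unname(r2$prop_outside["drift"]), 0.4)
  expect_equal(r2$selected, "threshold")

  # exact tie counts as absent
  r3 <- rope_select(doctor(fit, c(rep(0, 100), rep(1, 100)), rep(0, 200)))
  expect_equal(r3$selected, "null")

  expect_error(rope_select(quick_lba_fit("drift", n_trials = 20, seed = 604,
                                         burn = 50, keep = 50)))
  expect_error(rope_bounds(v_c = c(0.1, 0.3)))
})

test_that("thermodynamic integration applies the trapezoidal rule", {
  lad <- structure(list(temps = c(0, 0.5, 1), mean_loglik = c(-8, -8, -8)),
                   class = "ti_ladder")
  expect_equal(ti_logml(lad)$logml, -8)
  lad2 <- structure(list(temps = c(0, 1), mean_loglik = c(-10, -2)),
                    class = "ti_ladder")
  expect_equal(ti_logml(lad2)$logml, -6)
  bad <- structure(list(temps = c(0, 0.7), mean_loglik = c(-1, -1)),
                   class = "ti_ladder")
  expect_error(ti_logml(bad))
})

test_that("bridge sampling recovers analytic marginal likelihoods", {
  toy <- normal_toy()
  fit <- demcmc_sample(toy$target, n_chains = 10, burn = 500, keep = 1000,
                       seed = 5)
  bs <- bridge_logml(fit, seed = 6)
  expect_true(bs$converged)
  expect_lt(abs(bs$logml - toy$logml), 0.05)

  bb <- betabinom_toy()
  fitb <- demcmc_sample(bb$target, n_chains = 10, burn = 500, keep = 1000,
                        seed = 7)
  bsb <- bridge_logml(fitb, seed = 8)
  expect_lt(abs(bsb$logml - bb$logml), 0.05)
})
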