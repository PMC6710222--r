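test_that("node density vanishes before accumulation starts and integrates to one", {
  expect_equal(lba_node_density(-0.1, b = 2, A = 1, v = 3, sv = 1), 0)
  expect_equal(lba_node_cdf(0, b = 2, A = 1, v = 3, sv = 1), 0)
  expect_equal(lba_node_cdf(1e6, b = 2, A = 1, v = 3, sv = 1), 1,
               tolerance = 1e-6)

  # truncated drift is always positive, so the node finishes almost surely
  set.seed(401)
  for (i in 1:20) {
    A <- runif(1, 0.2, 3)
    b <- A + runif(1, 0.1, 3)
    v <- runif(1, 0.5, 5)
    sv <- runif(1, 0.5, 2)
    q <- integrate(function(t) lba_node_density(t, b, A, v, sv), 0, Inf,
                   rel.tol = 1e-8)
    expect_equal(q$value, 1, tolerance = 1e-4)
  }
})

test_that("node cdf is the integral of the node density", {
  ts <- c(0.2, 0.5, 1, 2, 5)
  h <- 1e-6
  num <- (lba_node_cdf(ts + h, 2, 1, 3, 1) -
            lba_node_cdf(ts - h, 2, 1, 3, 1)) / (2 * h)
  expect_equal(num, lba_node_density(ts, 2, 1, 3, 1), tolerance = 1e-5)
  expect_true(all(diff(lba_node_cdf(seq(0.01, 10, 0.01), 2, 1, 3, 1)) >=
                    -1e-12))
})

test_that("node functions reject invalid inputs", {
  expect_error(lba_node_density(NA, 2, 1, 3, 1))
  expect_error(lba_node_density(1, 1, 2, 3, 1))   # b < A
  expect_error(lba_node_cdf(1, 2, 1, 3, -1))      # sv <= 0
})

test_that("defective densities of the two responses integrate to one", {
  set.seed(402)
  for (i in 1:20) {
    p <- lba_params(v_c = runif(1, 1, 5), v_e = runif(1, 0.5, 4),
                    sv_e = runif(1, 0.5, 2), A = runif(1, 0.2, 2),
                    b = 2 + runif(1, 0.1, 2), t0 = runif(1, 0.1, 0.5))
    pc <- integrate(function(t)
      exp(lba_defective_logdens(t + p$t0, "correct", p)), 1e-6, 60,
      rel.tol = 1e-9)$value
    pe <- integrate(function(t)
      exp(lba_defective_logdens(t + p$t0, "error", p)), 1e-6, 60,
      rel.tol = 1e-9)$value
    expect_equal(pc + pe, 1, tolerance = 1e-4)
  }
})

test_that("symmetric accumulators split response probability in half", {
  p <- lba_params(v_c = 2.5, v_e = 2.5, sv_e = 1)
  pc <- integrate(function(t)
    exp(lba_defective_logdens(t + p$t0, "correct", p)), 1e-6, 60)$value
  expect_equal(pc, 0.5, tolerance = 1e-4)
})

test_that("per-trial density is floored for impossible response times", {
  p <- lba_params()
  expect_equal(lba_defective_logdens(p$t0 - 0.01, "correct", p), log(1e-10))
  expect_equal(lba_defective_logdens(p$t0 - 0.01, "correct", p,
                                     floor = 1e-8), log(1e-8))
})

test_that("log-likelihood sums per-trial defective log densities", {
  m <- lba_model("complex")
  set.seed(403)
  cell <- enumerate_cells("main")[1, ]
  d <- generate_dataset(cell, 1, 403)[1:25, ]
  theta <- colMeans(sample_prior(m, 200))
  cp <- theta_to_condition_params(theta, m)
  manual <- 0
  for (i in seq_len(nrow(d))) {
    p <- if (d$condition[i] == 1) cp$cond1 else cp$cond2
    manual <- manual + lba_defective_logdens(d$rt[i], d$response[i], p)
  }
  expect_equal(lba_loglik(d, m, theta), manual, tolerance = 1e-12)

  # invariant to trial order
  perm <- sample(nrow(d))
  expect_equal(lba_loglik(d[perm, ], m, theta), manual, tolerance = 1e-12)

  # empty data and support violations
  expect_identical(lba_loglik(d[0, ], m, theta), 0)
  bad <- theta; bad[m$par_names == "B.1"] <- -0.1
  expect_identical(lba_loglik(d, m, bad), -Inf)
})

test_that("simulator is reproducible, respects t0, and matches the density", {
  p <- lba_params()
  expect_equal(nrow(simulate_lba_trials(p, n_per_condition = 0)), 0)

  d1 <- simulate_lba_trials(p, n_per_condition = 500, seed = 42)
  d2 <- simulate_lba_trials(p, n_per_condition = 500, seed = 42)
  expect_identical(d1, d2)

  big <- simulate_lba_trials(p, n_per_condition = 1e5, seed = 43)
  expect_gt(min(big$rt), p$t0)

  # accuracy matches quadrature of the defective density
  p_correct <- integrate(function(t)
    exp(lba_defective_logdens(t + p$t0, "correct", p)), 1e-6, 60)$value
  acc <- mean(big$response == "correct")
  mc_se <- sqrt(p_correct * (1 - p_correct) / nrow(big))
  expect_lt(abs(acc - p_correct), 3 * mc_se)

  # per-response RT quantiles match the numeric conditional CDF
  rts <- big$rt[big$response == "correct"] - p$t0
  for (q in c(0.25, 0.5, 0.9)) {
    target <- q * p_correct
    f <- function(t) integrate(function(u)
      exp(lba_defective_logdens(u + p$t0, "correct", p)), 1e-6, t)$value -
      target
    tq <- uniroot(f, c(0.05, 10))$root
    expect_equal(unname(quantile(rts, q)), tq, tolerance = 0.02)
  }
})

test_that("choice_rt datasets round-trip through CSV", {
  d <- simulate_lba_trials(lba_params(), lba_params(v_c = 3.5),
                           n_per_condition = 20, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_choice_rt(d, path)
  expect_equal(read_choice_rt(path), d)
  expect_error(choice_rt(1, "correct", -0.5))
  expect_error(choice_rt(3, "correct", 0.5))
})
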