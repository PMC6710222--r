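test_that("metric values convert to normalized probability weights", {
  expect_equal(unname(model_weights(c(a = 5, b = 5, c = 5, d = 5),
                                    "deviance")),
               rep(0.25, 4))
  w <- model_weights(c(m1 = 0, m2 = 2), "deviance")
  expect_equal(unname(w), c(1, exp(-1)) / (1 + exp(-1)))
  expect_equal(sum(w), 1)
  # log marginal likelihoods, with -Inf allowed
  w2 <- model_weights(c(m1 = 0, m2 = -Inf), "logml")
  expect_equal(unname(w2), c(1, 0))
  # stability far from zero
  w3 <- model_weights(c(a = -1e6, b = -1e6 - 2), "logml")
  expect_equal(unname(w3), c(1, exp(-2)) / (1 + exp(-2)))
  expect_error(model_weights(c(a = 1), "deviance"))
  expect_error(model_weights(c(a = -Inf, b = -Inf), "logml"))
})

test_that("ROPE weights multiply independent per-effect probabilities", {
  w <- rope_weights(c(drift = 1, threshold = 0))
  expect_equal(unname(w["drift"]), 1)
  expect_equal(sum(w), 1)
  expect_equal(unname(rope_weights(c(drift = 0.5, threshold = 0.5))),
               rep(0.25, 4))
  w3 <- rope_weights(c(drift = 0.8, threshold = 0.3))
  expect_equal(unname(w3[c("null", "drift", "threshold", "complex")]),
               c(0.2 * 0.7, 0.8 * 0.7, 0.2 * 0.3, 0.8 * 0.3))
  expect_error(rope_weights(c(drift = 1.2, threshold = 0)))
})

test_that("adjusted Brier scores hit the perfect / chance / worst anchors", {
  vn <- c("null", "drift", "threshold", "complex")
  perfect <- setNames(c(1, 0, 0, 0), vn)
  expect_equal(brier_score(perfect, "null")$adjusted, 1)
  expect_equal(brier_score(perfect, "null")$raw, 0)
  uniform <- setNames(rep(0.25, 4), vn)
  expect_equal(brier_score(uniform, "null")$adjusted, 0)
  worst <- setNames(c(0, 1, 0, 0), vn)
  expect_equal(brier_score(worst, "null")$adjusted, -1)
  expect_equal(brier_score(worst, "null")$raw, 0.5)   # 2 / R
  # raw score bounds and monotonicity between the anchors
  mid <- setNames(c(0.7, 0.1, 0.1, 0.1), vn)
  b <- brier_score(mid, "null")
  expect_true(b$raw >= 0 && b$raw <= 0.5)
  expect_true(b$adjusted > 0 && b$adjusted < 1)
  expect_error(brier_score(perfect, "other"))
})

test_that("cell scoring reproduces hand-computed summaries", {
  # 6 replicates, 2 methods, truth = drift
  rows <- list()
  sel_a <- c("drift", "drift", "null", "drift", "complex", "drift")
  w_a <- rbind(c(0.1, 0.8, 0.05, 0.05),
               c(0.2, 0.6, 0.1, 0.1),
               c(0.6, 0.2, 0.1, 0.1),
               c(0.0, 1.0, 0.0, 0.0),
               c(0.1, 0.3, 0.2, 0.4),
               c(0.25, 0.25, 0.25, 0.25))
  for (r in 1:6) {
    rows[[length(rows) + 1]] <- data.frame(
      method = "A", replicate = r, selected = sel_a[r],
      true_variant = "drift", w_null = w_a[r, 1], w_drift = w_a[r, 2],
      w_threshold = w_a[r, 3], w_complex = w_a[r, 4],
      stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      method = "chi2", replicate = r,
      selected = rep(c("drift", "null"), 3)[r],
      true_variant = "drift", w_null = NA_real_, w_drift = NA_real_,
      w_threshold = NA_real_, w_complex = NA_real_,
      stringsAsFactors = FALSE)
  }
  res <- score_cell(do.call(rbind, rows))
  a <- res[res$method == "A", ]
  expect_equal(a$prop_correct, 4 / 6)
  expect_equal(a$prop_drift, 5 / 6)       # drift or complex selected
  expect_equal(a$prop_threshold, 1 / 6)   # complex counts for threshold
  hand <- mean(vapply(1:6, function(r)
    brier_score(setNames(w_a[r, ], c("null", "drift", "threshold",
                                     "complex")), "drift")$adjusted,
    numeric(1)))
  expect_equal(a$mean_brier, hand)
  chi <- res[res$method == "chi2", ]
  expect_equal(chi$prop_correct, 0.5)
  expect_true(is.na(chi$mean_brier))
})

test_that("agreement matrices count pairwise identical selections", {
  sel <- data.frame(
    method = rep(c("A", "B", "C"), each = 4),
    replicate = rep(1:4, 3),
    selected = c("null", "drift", "null", "complex",
                 "null", "drift", "drift", "complex",
                 "drift", "null", "complex", "null"),
    stringsAsFactors = FALSE)
  M <- agreement_matrix(sel)
  expect_equal(diag(M), setNames(c(1, 1, 1), c("A", "B", "C")))
  expect_equal(M, t(M))
  expect_equal(M["A", "B"], 3 / 4)
  expect_equal(M["A", "C"], 0)
  expect_true(all(M >= 0 & M <= 1))
})

test_that("better-than-chance selection yields positive mean Brier scores", {
  set.seed(610)
  vn <- c("null", "drift", "threshold", "complex")
  rows <- lapply(1:40, function(r) {
    correct <- runif(1) < 0.8
    sel <- if (correct) "drift" else "null"
    w <- if (correct) c(0.1, 0.7, 0.1, 0.1) else c(0.55, 0.25, 0.1, 0.1)
    data.frame(method = "M", replicate = r, selected = sel,
               true_variant = "drift", w_null = w[1], w_drift = w[2],
               w_threshold = w[3], w_complex = w[4],
               stringsAsFactors = FALSE)
  })
  res <- score_cell(do.call(rbind, rows))
  expect_gt(res$prop_correct, 0.25)
  expect_gt(res$mean_brier, 0)
})
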