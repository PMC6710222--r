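#' Probability weights over candidate models from metric values
#'
#' Converts a metric's values for the candidate models into normalized
#' probability weights. On the deviance scale (AIC, BIC, DIC, WAIC,
#' prior-inclusive DIC) the weight of model i is `exp(-0.5 value_i)`
#' renormalized; on the log-marginal-likelihood scale (bridge sampling,
#' thermodynamic integration) it is `exp(value_i)` renormalized. The best
#' value is subtracted before exponentiation for numerical stability.
#'
#' @param values named numeric, one value per candidate model; `-Inf`
#'   allowed on the log-ML scale.
#' @param scale `"deviance"` or `"logml"`.
#' @return Named weights, non-negative, summing to one.
#' @export
model_weights <- function(values, scale = c("deviance", "logml")) {
  scale <- match.arg(scale)
  if (length(values) < 2) stop("need at least two models")
  lw <- if (scale == "deviance") {
    if (any(!is.finite(values))) stop("deviance values must be finite")
    -0.5 * (values - min(values))
  } else {
    if (all(!is.finite(values))) stop("all log marginal likelihoods are -Inf")
    values - max(values)
  }
  w <- exp(lw)
  w / sum(w)
}

#' Probability weights over variants from ROPE posterior proportions
#'
#' Treats the two effect decisions as independent binary cases: the weight
#' of a variant is the product over effects of the posterior proportion
#' outside the ROPE (if the variant includes the effect) or inside it (if
#' not), renormalized across the four variants.
#'
#' @param prop_outside named numeric with entries `drift` and `threshold`,
#'   each in `[0, 1]`.
#' @return Named weights over `null`, `drift`, `threshold`, `complex`.
#' @export
rope_weights <- function(prop_outside) {
  pd <- prop_outside[["drift"]]; pt <- prop_outside[["threshold"]]
  if (any(c(pd, pt) < 0 | c(pd, pt) > 1)) stop("proportions must be in [0, 1]")
  w <- c(null = (1 - pd) * (1 - pt), drift = pd * (1 - pt),
         threshold = (1 - pd) * pt, complex = pd * pt)
  if (sum(w) == 0) w + 0.25 else w / sum(w)
}

#' Brier score of a probabilistic model selection
#'
#' Raw score `(1/R) sum_i (f_i - o_i)^2` over the R candidate outcomes,
#' where `f_i` is the forecast probability and `o_i` indicates the outcome
#' that occurred; raw scores lie in `[0, 2/R]`. The adjusted score maps this
#' piecewise-linearly onto `[-1, 1]` so that a perfect forecast scores 1,
#' the uniform (chance) forecast scores 0, and all mass on a wrong outcome
#' scores -1: with `B_c` the raw score of the uniform forecast and `B_max`
#' the worst raw score, `adjusted = 1 - B / B_c` for `B <= B_c` and
#' `-(B - B_c) / (B_max - B_c)` above. The adjustment is a reconstruction
#' anchored at those three points; any monotone map through them preserves
#' orderings but not intermediate values.
#'
#' @param weights named forecast probabilities over outcomes (sum to 1).
#' @param true_outcome name of the outcome that occurred.
#' @return List with `raw` and `adjusted` scores.
#' @export
brier_score <- function(weights, true_outcome) {
  if (!true_outcome %in% names(weights)) stop("unknown true outcome")
  if (abs(sum(weights) - 1) > 1e-6) stop("weights must sum to 1")
  R <- length(weights)
  o <- as.numeric(names(weights) == true_outcome)
  raw <- mean((weights - o)^2)
  b_chance <- ((1 / R - 1)^2 + (R - 1) * (1 / R)^2) / R
  b_max <- 2 / R
  adjusted <- if (raw <= b_chance) 1 - raw / b_chance
              else -(raw - b_chance) / (b_max - b_chance)
  list(raw = raw, adjusted = adjusted)
}

variant_has_effect <- function(variant, effect) {
  switch(effect,
         drift = variant %in% c("drift", "complex"),
         threshold = variant %in% c("threshold", "complex"),
         stop("unknown effect"))
}

#' Per-cell performance summary across replicates
#'
#' Aggregates one design cell's replicates into per-method rows: the
#' proportion of replicates selecting the generating model, the proportions
#' selecting each effect (a drift effect is "selected" when the chosen
#' variant is drift or complex, analogously for threshold), the mean
#' adjusted Brier score over the four variants, and per-effect mean
#' adjusted Brier scores computed over the two-outcome forecast
#' (effect present with probability `w_drift + w_complex`, or
#' `w_threshold + w_complex`). Methods without probability weights (the
#' chi-squared test) get `NA` Brier scores.
#'
#' @param results data frame with one row per (method, replicate): columns
#'   `method`, `replicate`, `selected`, `true_variant`, and optional weight
#'   columns `w_null`, `w_drift`, `w_threshold`, `w_complex`.
#' @return Data frame with one row per method: `prop_correct`,
#'   `prop_drift`, `prop_threshold`, `mean_brier`, `brier_drift`,
#'   `brier_threshold`, `n_replicates`.
#' @export
score_cell <- function(results) {
  stopifnot(nrow(results) >= 1)
  has_w <- all(c("w_null", "w_drift", "w_threshold", "w_complex")
               %in% names(results))
  out <- lapply(split(results, results$method), function(d) {
    truth <- d$true_variant
    briers <- bd <- bt <- rep(NA_real_, nrow(d))
    if (has_w && !anyNA(d$w_null)) {
      for (i in seq_len(nrow(d))) {
        w <- c(null = d$w_null[i], drift = d$w_drift[i],
               threshold = d$w_threshold[i], complex = d$w_complex[i])
        briers[i] <- brier_score(w, truth[i])$adjusted
        wd <- c(present = w[["drift"]] + w[["complex"]],
                absent = w[["null"]] + w[["threshold"]])
        bd[i] <- brier_score(wd, if (variant_has_effect(truth[i], "drift"))
                                   "present" else "absent")$adjusted
        wt <- c(present = w[["threshold"]] + w[["complex"]],
                absent = w[["null"]] + w[["drift"]])
        bt[i] <- brier_score(wt, if (variant_has_effect(truth[i], "threshold"))
                                   "present" else "absent")$adjusted
      }
    }
    data.frame(
      method = d$method[1],
      prop_correct = mean(d$selected == truth),
      prop_drift = mean(vapply(d$selected, variant_has_effect, logical(1),
                               effect = "drift")),
      prop_threshold = mean(vapply(d$selected, variant_has_effect,
                                   logical(1), effect = "threshold")),
      mean_brier = mean(briers),
      brier_drift = mean(bd),
      brier_threshold = mean(bt),
      n_replicates = nrow(d),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Heat map of per-cell method performance
#'
#' Renders one panel per method over the design grid (drift effect size as
#' columns, threshold effect size crossed with arrangement as rows),
#' colouring each cell by a chosen summary statistic — the layout used for
#' the study's selection-performance figures.
#'
#' @param summary the `summary` element of [summarize_study()] output,
#'   joined here with the cell descriptors from [enumerate_cells()].
#' @param cells the cell table used for the study.
#' @param statistic column of `summary` to plot (default `prop_correct`).
#' @return A ggplot object.
#' @export
plot_selection_heatmap <- function(summary, cells,
                                   statistic = "prop_correct") {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("the ggplot2 package is required for heat maps")
  d <- merge(summary, cells, by = "cell_id")
  d$col_lab <- factor(d$drift_size, levels = size_levels)
  d$row_lab <- factor(
    ifelse(d$arrangement == "n/a", d$threshold_size,
           paste(d$threshold_size, substr(d$arrangement, 1, 3))),
    levels = c(t(outer(size_levels,
                       c("", " ext", " bal"), paste0))))
  d$stat_value <- d[[statistic]]
  ggplot2::ggplot(d, ggplot2::aes(x = col_lab, y = row_lab,
                                  fill = stat_value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~method) +
    ggplot2::scale_fill_gradient2(low = "red", mid = "black",
                                  high = "green", midpoint = 0.5,
                                  limits = c(0, 1)) +
    ggplot2::labs(x = "drift effect", y = "threshold effect",
                  fill = statistic) +
    ggplot2::theme_minimal()
}

#' Between-method agreement matrix
#'
#' Proportion of replicates on which each pair of methods selected the same
#' variant.
#'
#' @param selections data frame with columns `method`, `replicate`,
#'   `selected` (every method present for every replicate).
#' @return Symmetric method x method matrix with unit diagonal.
#' @export
agreement_matrix <- function(selections) {
  methods <- unique(selections$method)
  wide <- do.call(cbind, lapply(methods, function(m) {
    d <- selections[selections$method == m, ]
    d$selected[order(d$replicate)]
  }))
  colnames(wide) <- methods
  M <- matrix(1, length(methods), length(methods),
              dimnames = list(methods, methods))
  for (i in seq_along(methods))
    for (j in seq_along(methods))
      if (i < j)
        M[i, j] <- M[j, i] <- mean(wide[, i] == wide[, j])
  M
}
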