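#' Baseline generating parameters and calibrated effect values
#'
#' `baseline_params()` returns the non-manipulated generating parameters
#' shared by every design cell: `v_c = 3`, `v_e = 2`, `sv_c = 1`,
#' `sv_e = 1`, `A = 1`, `b = 2`, `t0 = 0.3`. `effect_values()` returns the
#' manipulated values that produce standardized RT differences of about
#' 0.2, 0.5, and 0.8 between conditions: `v_c` raised to 3.3 / 3.75 / 4.25
#' and `b` lowered to 1.89 / 1.74 / 1.595 for small / moderate / large
#' effects.
#'
#' @return `baseline_params()`: an [lba_params]; `effect_values()`: a list
#'   with named vectors `v_c` and `b`.
#' @export
baseline_params <- function() {
  lba_params(v_c = 3, v_e = 2, sv_c = 1, sv_e = 1, A = 1, b = 2, t0 = 0.3)
}

#' @rdname baseline_params
#' @export
effect_values <- function() {
  list(v_c = c(small = 3.3, moderate = 3.75, large = 4.25),
       b = c(small = 1.89, moderate = 1.74, large = 1.595))
}

size_levels <- c("none", "small", "moderate", "large")

#' Enumerate the cells of a simulation design
#'
#' The `"main"` design crosses drift and threshold effect sizes (none /
#' small / moderate / large): 1 null cell, 6 one-way cells, and 18 two-way
#' cells (3 x 3 sizes x extreme / balanced arrangement), 25 in total, each
#' with 100 replicate datasets of 300 trials per condition. The
#' `"sample_size_followup"` design takes the five most diagnostic cells
#' (null, small drift, small threshold, small/small extreme, small/small
#' balanced) at 30, 100, 300, and 900 trials per condition (20 cells). The
#' `"prior_followup"` design is those five cells at 300 trials.
#'
#' @param design `"main"`, `"sample_size_followup"`, or `"prior_followup"`.
#' @param replicates datasets per cell (default 100).
#' @param trials_per_condition trials per condition for designs with a
#'   fixed trial count (default 300).
#' @return Data frame of cells: `cell_id`, `drift_size`, `threshold_size`,
#'   `arrangement`, `trials_per_condition`, `replicates`, `true_variant`.
#' @export
enumerate_cells <- function(design = c("main", "sample_size_followup",
                                       "prior_followup"),
                            replicates = 100, trials_per_condition = 300) {
  design <- match.arg(design)
  small5 <- data.frame(
    drift_size = c("none", "small", "none", "small", "small"),
    threshold_size = c("none", "none", "small", "small", "small"),
    arrangement = c("n/a", "n/a", "n/a", "extreme", "balanced"),
    stringsAsFactors = FALSE)
  cells <- switch(design,
    main = {
      one <- expand.grid(drift_size = size_levels,
                         threshold_size = size_levels,
                         stringsAsFactors = FALSE)
      one <- one[!(one$drift_size != "none" & one$threshold_size != "none"), ]
      one$arrangement <- "n/a"
      two <- expand.grid(drift_size = size_levels[-1],
                         threshold_size = size_levels[-1],
                         arrangement = c("extreme", "balanced"),
                         stringsAsFactors = FALSE)
      out <- rbind(one, two)
      out$trials_per_condition <- trials_per_condition
      out
    },
    sample_size_followup = {
      out <- merge(small5, data.frame(trials_per_condition =
                                        c(30L, 100L, 300L, 900L)))
      out[order(out$trials_per_condition), ]
    },
    prior_followup = {
      small5$trials_per_condition <- trials_per_condition
      small5
    })
  cells$replicates <- replicates
  cells$true_variant <- ifelse(
    cells$drift_size != "none" & cells$threshold_size != "none", "complex",
    ifelse(cells$drift_size != "none", "drift",
           ifelse(cells$threshold_size != "none", "threshold", "null")))
  cells$cell_id <- sprintf("d%s_t%s_%s_n%d",
                           substr(cells$drift_size, 1, 1),
                           substr(cells$threshold_size, 1, 1),
                           sub("n/a", "na", cells$arrangement),
                           cells$trials_per_condition)
  rownames(cells) <- NULL
  cells[, c("cell_id", "drift_size", "threshold_size", "arrangement",
            "trials_per_condition", "replicates", "true_variant")]
}

#' Generating parameters for one design cell
#'
#' Condition 1 is the baseline unless the cell assigns it an effect. Drift
#' effects raise `v_c` in condition 2. Threshold effects lower `b`: in the
#' "extreme" arrangement (and all one-way threshold cells) the decrease is
#' in condition 2, the same condition as the drift increase, making the RT
#' difference between conditions more extreme; in the "balanced"
#' arrangement the decrease is in condition 1, so the two effects offset
#' each other. Null cells have identical conditions.
#'
#' @param cell one row of [enumerate_cells()] output (or a list with
#'   `drift_size`, `threshold_size`, `arrangement`).
#' @return List with `cond1` and `cond2` [lba_params].
#' @export
cell_params <- function(cell) {
  ev <- effect_values()
  p1 <- unclass(baseline_params())
  p2 <- p1
  if (cell$drift_size != "none")
    p2$v_c <- ev$v_c[[cell$drift_size]]
  if (cell$threshold_size != "none") {
    b_new <- ev$b[[cell$threshold_size]]
    if (cell$drift_size != "none" && cell$arrangement == "balanced")
      p1$b <- b_new
    else
      p2$b <- b_new
  }
  list(cond1 = do.call(lba_params, p1), cond2 = do.call(lba_params, p2))
}

#' Generate one replicate dataset for a design cell
#'
#' Simulates `trials_per_condition` trials for each condition from the
#' cell's generating parameters. The seed is derived deterministically from
#' the master seed, the cell, and the replicate index, so every dataset in
#' a study is independently reproducible.
#'
#' @param cell one row of [enumerate_cells()] output.
#' @param replicate replicate index (1-based).
#' @param master_seed integer master seed.
#' @return A [choice_rt] dataset.
#' @export
generate_dataset <- function(cell, replicate = 1, master_seed = 1) {
  pars <- cell_params(cell)
  simulate_lba_trials(pars$cond1, pars$cond2, cell$trials_per_condition,
                      seed = dataset_seed(cell, replicate, master_seed))
}

dataset_seed <- function(cell, replicate, master_seed) {
  derive_seed(master_seed,
              match(cell$drift_size, size_levels),
              match(cell$threshold_size, size_levels),
              match(cell$arrangement, c("n/a", "extreme", "balanced")),
              cell$trials_per_condition, replicate)
}

#' Standardized RT difference produced by one parameter change
#'
#' Monte-Carlo calibration of the effect size of a manipulation: simulates
#' trials from the baseline parameters and from a configuration with one
#' parameter (`v_c` or `b`) set to `new_value`, and returns the pooled-SD
#' standardized mean difference (Cohen's d) between the two RT
#' distributions, pooling all trials regardless of accuracy. The sign
#' convention is baseline minus manipulated, so speed-ups (higher drift,
#' lower threshold) give positive effect sizes.
#'
#' By default the statistic is evaluated at the design's own experiment
#' scale: `n_mc` trials per condition are split into pseudo-experiments of
#' `trials_per_experiment` trials per condition, d is computed within each,
#' and the mean over pseudo-experiments is returned. This matters because
#' the LBA's winning-time distribution is heavy-tailed (a drift draw near
#' zero produces an arbitrarily slow trial, giving a roughly `t^-2` RT
#' tail), so a single pooled SD over hundreds of thousands of trials is
#' dominated by a handful of extreme trials and drifts with the sample
#' size. The per-experiment average is stable and reflects the effect size
#' observed at the scale the datasets are actually generated at. Set
#' `trials_per_experiment = NULL` for the single-pool statistic.
#'
#' @param parameter `"v_c"` or `"b"`.
#' @param new_value manipulated parameter value.
#' @param n_mc total trials per condition (`>= 1e4`).
#' @param seed optional integer seed.
#' @param trials_per_experiment trials per condition within each
#'   pseudo-experiment (default 300, the design's trial count), or `NULL`
#'   to pool all `n_mc` trials into one sample.
#' @return Standardized mean RT difference.
#' @export
calibrate_effect_size <- function(parameter = c("v_c", "b"), new_value,
                                  n_mc = 2e5, seed = NULL,
                                  trials_per_experiment = 300) {
  parameter <- match.arg(parameter)
  if (n_mc < 1e4) stop("n_mc must be at least 1e4")
  if (!is.null(seed)) set.seed(seed)
  p_base <- baseline_params()
  p_new <- unclass(p_base)
  p_new[[parameter]] <- new_value
  p_new <- do.call(lba_params, p_new)
  d_pool <- function(x, y) {
    (mean(x) - mean(y)) /
      sqrt(((length(x) - 1) * stats::var(x) +
            (length(y) - 1) * stats::var(y)) /
           (length(x) + length(y) - 2))
  }
  if (is.null(trials_per_experiment)) {
    return(d_pool(simulate_lba_trials(p_base, n_per_condition = n_mc)$rt,
                  simulate_lba_trials(p_new, n_per_condition = n_mc)$rt))
  }
  reps <- max(1L, floor(n_mc / trials_per_experiment))
  mean(vapply(seq_len(reps), function(r) {
    d_pool(
      simulate_lba_trials(p_base,
                          n_per_condition = trials_per_experiment)$rt,
      simulate_lba_trials(p_new,
                          n_per_condition = trials_per_experiment)$rt)
  }, numeric(1)))
}

#' Design manifest: one row per dataset
#'
#' Expands a cell table into the full list of replicate datasets with their
#' derived seeds and generating parameter values, suitable for writing as a
#' CSV manifest.
#'
#' @param cells output of [enumerate_cells()].
#' @param master_seed integer master seed.
#' @return Data frame with one row per dataset.
#' @export
design_manifest <- function(cells, master_seed = 1) {
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    pars <- cell_params(cell)
    data.frame(
      dataset_id = sprintf("%s_r%03d", cell$cell_id,
                           seq_len(cell$replicates)),
      cell_id = cell$cell_id, replicate = seq_len(cell$replicates),
      drift_size = cell$drift_size, threshold_size = cell$threshold_size,
      arrangement = cell$arrangement,
      trials_per_condition = cell$trials_per_condition,
      true_variant = cell$true_variant,
      seed = vapply(seq_len(cell$replicates), function(r)
        dataset_seed(cell, r, master_seed), integer(1)),
      v_c_1 = pars$cond1$v_c, b_1 = pars$cond1$b,
      v_c_2 = pars$cond2$v_c, b_2 = pars$cond2$b,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
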