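#' Study configuration
#'
#' Bundles every knob of a simulation study: the design and any cell
#' subset, replicate and trial counts, MCMC settings, the metric list, the
#' prior level for reparameterized fits, the chi-squared significance
#' level, ROPE bounds, and the master seed.
#'
#' @param design design name passed to [enumerate_cells()].
#' @param cells optional character vector of `cell_id`s to run.
#' @param replicates datasets per cell.
#' @param trials_per_condition trials per condition.
#' @param methods metrics to compute (subset of the nine implemented).
#' @param chains_multiplier chains per free parameter for ordinary fits.
#' @param burn,keep burn-in and retained iterations per chain.
#' @param n_temps temperature count for thermodynamic integration.
#' @param ti_burn burn-in for the power-posterior ladder runs, which start
#'   warm from the ordinary posterior fit; defaults to `burn %/% 2`.
#' @param ti_keep retained iterations per ladder chain; defaults to `keep`.
#'   The thermodynamic integral is noisier than the other metrics at equal
#'   draw counts, so reduced-scale runs may want `ti_keep > keep`.
#' @param prior_level prior level (with `parameterization = "mean-diff"`).
#' @param parameterization model parameterization for the fitted variants.
#' @param alpha significance level of the chi-squared deviance test.
#' @param bounds [rope_bounds()] for the augmented ROPE rule.
#' @param seed master seed; all job seeds derive from it.
#' @param outdir optional directory for per-dataset result CSVs (enables
#'   resuming).
#' @return List of class `study_config`.
#' @export
study_config <- function(design = "main", cells = NULL, replicates = 100,
                         trials_per_condition = 300,
                         methods = lba_methods(), chains_multiplier = 3,
                         burn = 1000, keep = 1000, n_temps = 40,
                         ti_burn = NULL, ti_keep = NULL,
                         prior_level = "default",
                         parameterization = "per-condition",
                         alpha = 0.05, bounds = rope_bounds(), seed = 1,
                         outdir = NULL) {
  methods <- match.arg(methods, lba_methods(), several.ok = TRUE)
  stopifnot(replicates >= 1)
  structure(list(design = design, cells = cells, replicates = replicates,
                 trials_per_condition = trials_per_condition,
                 methods = methods, chains_multiplier = chains_multiplier,
                 burn = burn, keep = keep, n_temps = n_temps,
                 ti_burn = ti_burn %||% (burn %/% 2),
                 ti_keep = ti_keep %||% keep,
                 prior_level = prior_level,
                 parameterization = parameterization, alpha = alpha,
                 bounds = bounds, seed = seed, outdir = outdir),
            class = "study_config")
}

#' The nine implemented model selection methods
#' @return Character vector of method names.
#' @export
lba_methods <- function() {
  c("AIC", "BIC", "DIC", "WAIC", "DICp", "BF-BS", "BF-TI", "ROPE", "chi2")
}

config_cells <- function(config) {
  cells <- enumerate_cells(config$design, replicates = config$replicates,
                           trials_per_condition = config$trials_per_condition)
  if (!is.null(config$cells)) {
    cells <- cells[cells$cell_id %in% config$cells, ]
    if (nrow(cells) == 0) stop("cell subset matches no cells")
  }
  cells
}

#' Plan the jobs of a study
#'
#' Deterministically enumerates the datasets, model fits (four variants per
#' dataset), and metric evaluations (nine per fitted model, with the
#' chi-squared tree counted once per model) implied by a configuration.
#'
#' @param config a [study_config()].
#' @return List with `cells`, `datasets` (manifest), `fits` (one row per
#'   dataset x variant), and `n_metric_evals`.
#' @export
plan_jobs <- function(config) {
  cells <- config_cells(config)
  datasets <- design_manifest(cells, master_seed = config$seed)
  fits <- merge(datasets[, c("dataset_id", "cell_id", "replicate")],
                data.frame(variant = c("null", "drift", "threshold",
                                       "complex")))
  fits <- fits[order(fits$dataset_id, fits$variant), ]
  rownames(fits) <- NULL
  list(cells = cells, datasets = datasets, fits = fits,
       n_metric_evals = nrow(fits) * length(lba_methods()))
}

# the four variants fitted to every dataset
fit_variants <- function(config) {
  lapply(stats::setNames(nm = c("null", "drift", "threshold", "complex")),
         function(v) {
           if (config$parameterization == "mean-diff" && v != "null")
             lba_model(v, "mean-diff", config$prior_level)
           else lba_model(v)
         })
}

#' Fit the four variants to one dataset and compute all requested metrics
#'
#' Runs the ordinary DE-MCMC fit for each variant (and the power-posterior
#' ladder when thermodynamic integration is requested), then evaluates each
#' requested selection method. Per-job seeds derive from `seed` and the
#' variant, so jobs are order-independent.
#'
#' @param data a [choice_rt] dataset.
#' @param config a [study_config()].
#' @param seed integer seed for this dataset's fits.
#' @return List with `values` (method x variant metric values, long form),
#'   `weights` (per method over variants), `selections` (per method), and
#'   `diagnostics` (max split R-hat per variant).
#' @export
fit_and_score <- function(data, config, seed = 1) {
  variants <- fit_variants(config)
  need_ti <- "BF-TI" %in% config$methods
  need_waic <- "WAIC" %in% config$methods
  fits <- list(); ladders <- list()
  for (v in names(variants)) {
    model <- variants[[v]]
    fits[[v]] <- demcmc_sample(
      model, data, n_chains = config$chains_multiplier * model$k,
      burn = config$burn, keep = config$keep,
      seed = derive_seed(seed, match(v, names(variants)), 1),
      store_trial_loglik = need_waic)
    if (need_ti) {
      ladders[[v]] <- power_posterior_run(
        model, data, temps = temperature_ladder(config$n_temps),
        burn = config$ti_burn, keep = config$ti_keep,
        seed = derive_seed(seed, match(v, names(variants)), 2),
        init = fits[[v]]$draws)
    }
  }

  vn <- names(variants)
  k <- vapply(fits, function(f) f$model$k, integer(1))
  n <- nrow(data)
  max_ll <- vapply(fits, function(f) max(f$log_lik), numeric(1))
  values <- list(); weights <- list(); selections <- list()
  add_value_method <- function(method, vals, scale) {
    values[[method]] <<- data.frame(method = method, variant = vn,
                                    value = unname(vals), scale = scale,
                                    stringsAsFactors = FALSE)
    w <- model_weights(vals, if (scale == "deviance") "deviance" else "logml")
    weights[[method]] <<- w
    best <- if (scale == "deviance") which.min(vals) else which.max(vals)
    selections[[method]] <<- vn[best]
  }

  for (method in config$methods) {
    switch(method,
      "AIC" = add_value_method("AIC", aic(max_ll, k), "deviance"),
      "BIC" = add_value_method("BIC", bic(max_ll, k, n), "deviance"),
      "DIC" = add_value_method(
        "DIC", vapply(fits, function(f) dic(f$log_lik), numeric(1)),
        "deviance"),
      "WAIC" = add_value_method(
        "WAIC", vapply(fits, function(f) waic(f$trial_loglik), numeric(1)),
        "deviance"),
      "DICp" = add_value_method(
        "DICp", vapply(fits, function(f) dic_p(f$log_lik + f$log_prior),
                       numeric(1)), "deviance"),
      "BF-BS" = add_value_method(
        "BF-BS", vapply(vn, function(v) bridge_logml(
          fits[[v]], seed = derive_seed(seed, match(v, vn), 3))$logml,
          numeric(1)), "logml"),
      "BF-TI" = add_value_method(
        "BF-TI", vapply(vn, function(v) ti_logml(ladders[[v]])$logml,
                        numeric(1)), "logml"),
      "ROPE" = {
        rs <- rope_select(fits[["complex"]], config$bounds)
        values[["ROPE"]] <- data.frame(
          method = "ROPE", variant = c("drift", "threshold"),
          value = unname(rs$prop_outside), scale = "prop_outside",
          stringsAsFactors = FALSE)
        weights[["ROPE"]] <- rope_weights(rs$prop_outside)
        selections[["ROPE"]] <- rs$selected
      },
      "chi2" = {
        cs <- chi2_select(-2 * max_ll, alpha = config$alpha)
        values[["chi2"]] <- data.frame(
          method = "chi2", variant = vn, value = unname(-2 * max_ll),
          scale = "deviance", stringsAsFactors = FALSE)
        weights[["chi2"]] <- NULL
        selections[["chi2"]] <- cs$selected
      })
  }
  list(values = do.call(rbind, unname(values)),
       weights = weights,
       selections = unlist(selections),
       diagnostics = vapply(fits, function(f) max(split_rhat(f)),
                            numeric(1)))
}

#' Read a study configuration from a YAML file
#'
#' The file may set any argument of [study_config()] (scalar fields and the
#' `methods` / `cells` vectors); `bounds` may be given as a mapping with
#' `v_c` and `b` entries of two numbers each.
#'
#' @param path YAML file path.
#' @return A [study_config()].
#' @export
study_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$bounds))
    cfg$bounds <- rope_bounds(v_c = as.numeric(cfg$bounds$v_c),
                              b = as.numeric(cfg$bounds$b))
  do.call(study_config, cfg)
}

# one tidy row per method for a scored dataset
result_rows <- function(scored, dataset_row) {
  methods <- names(scored$selections)
  w <- lapply(methods, function(m) {
    wi <- scored$weights[[m]]
    if (is.null(wi)) rep(NA_real_, 4) else
      wi[c("null", "drift", "threshold", "complex")]
  })
  w <- do.call(rbind, w)
  data.frame(dataset_id = dataset_row$dataset_id,
             cell_id = dataset_row$cell_id,
             replicate = dataset_row$replicate,
             true_variant = dataset_row$true_variant,
             method = methods, selected = unname(scored$selections),
             w_null = w[, 1], w_drift = w[, 2], w_threshold = w[, 3],
             w_complex = w[, 4], stringsAsFactors = FALSE)
}

# tidy metric-value rows (one per method x variant) for a scored dataset
value_rows <- function(scored, dataset_row) {
  v <- scored$values
  data.frame(dataset_id = dataset_row$dataset_id,
             cell_id = dataset_row$cell_id,
             replicate = dataset_row$replicate,
             method = v$method, variant = v$variant, value = v$value,
             scale = v$scale,
             selected = v$variant ==
               unname(scored$selections[v$method]),
             stringsAsFactors = FALSE)
}

#' Run a simulation study
#'
#' Executes the generate / fit / score loop over every dataset in the plan.
#' With an `outdir` configured, each dataset's result rows are written to
#' `<outdir>/result_<dataset_id>.csv` as they complete and existing files
#' are skipped, making interrupted studies resumable; per-job seeds make
#' any execution order equivalent. A failing dataset is recorded and the
#' study continues.
#'
#' @param config a [study_config()].
#' @param progress print one line per completed dataset?
#' @return Data frame of selection rows (one per dataset x method), with
#'   attribute `"failed"` listing failed dataset ids and attribute
#'   `"values"` holding the tidy metric-value table (one row per dataset x
#'   method x variant: `value`, `scale`, `selected`).
#' @export
run_study <- function(config, progress = interactive()) {
  plan <- plan_jobs(config)
  if (!is.null(config$outdir))
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- list(); vals <- list(); failed <- character()
  for (i in seq_len(nrow(plan$datasets))) {
    ds <- plan$datasets[i, ]
    path <- vpath <- NULL
    if (!is.null(config$outdir)) {
      path <- file.path(config$outdir,
                        paste0("result_", ds$dataset_id, ".csv"))
      vpath <- file.path(config$outdir,
                         paste0("values_", ds$dataset_id, ".csv"))
    }
    if (!is.null(path) && file.exists(path)) {
      out[[ds$dataset_id]] <- utils::read.csv(path, stringsAsFactors = FALSE)
      if (file.exists(vpath))
        vals[[ds$dataset_id]] <- utils::read.csv(vpath,
                                                 stringsAsFactors = FALSE)
      next
    }
    cell <- plan$cells[plan$cells$cell_id == ds$cell_id, ]
    rows <- tryCatch({
      data <- generate_dataset(cell, ds$replicate, config$seed)
      scored <- fit_and_score(data, config,
                              seed = derive_seed(config$seed, 1000L + i))
      list(sel = result_rows(scored, ds), val = value_rows(scored, ds))
    }, error = function(e) {
      warning(sprintf("dataset %s failed: %s", ds$dataset_id,
                      conditionMessage(e)))
      NULL
    })
    if (is.null(rows)) { failed <- c(failed, ds$dataset_id); next }
    if (!is.null(path)) {
      utils::write.csv(rows$sel, path, row.names = FALSE)
      utils::write.csv(rows$val, vpath, row.names = FALSE)
    }
    out[[ds$dataset_id]] <- rows$sel
    vals[[ds$dataset_id]] <- rows$val
    if (progress)
      message(sprintf("[%d/%d] %s done", i, nrow(plan$datasets),
                      ds$dataset_id))
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  attr(res, "failed") <- failed
  values <- do.call(rbind, unname(vals))
  rownames(values) <- NULL
  attr(res, "values") <- values
  res
}

#' Summarize study results per cell and method
#'
#' Applies [score_cell()] within each design cell and assembles the
#' between-method agreement matrix per cell.
#'
#' @param results output of [run_study()].
#' @return List with `summary` (one row per cell x method) and `agreement`
#'   (named list of per-cell agreement matrices).
#' @export
summarize_study <- function(results) {
  if (is.null(results) || nrow(results) == 0) stop("no results to summarize")
  by_cell <- split(results, results$cell_id)
  summary <- do.call(rbind, lapply(names(by_cell), function(cid) {
    s <- score_cell(by_cell[[cid]])
    cbind(cell_id = cid, s, stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  agreement <- lapply(by_cell, agreement_matrix)
  list(summary = summary, agreement = agreement)
}
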