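#' Accumulator parameters for one condition
#'
#' Bundles the seven Linear Ballistic Accumulator (LBA) parameters governing
#' a single experimental condition: mean drift rates for the correct and
#' error accumulators (`v_c`, `v_e`, evidence units per second), their
#' between-trial drift standard deviations (`sv_c`, `sv_e`; `sv_c` is fixed
#' at 1 to satisfy the model's scaling property), the start-point upper
#' bound `A`, the response threshold `b` (with `b >= A`), and the
#' non-decision time `t0` in seconds.
#'
#' @param v_c,v_e mean drift rates of the correct and error accumulators.
#' @param sv_c correct-accumulator drift SD; must equal 1.
#' @param sv_e error-accumulator drift SD.
#' @param A upper bound of the uniform start-point distribution.
#' @param b response threshold; must satisfy `b >= A`.
#' @param t0 non-decision time in seconds.
#' @return An object of class `lba_params`.
#' @export
lba_params <- function(v_c = 3, v_e = 2, sv_c = 1, sv_e = 1, A = 1, b = 2,
                       t0 = 0.3) {
  x <- c(v_c, v_e, sv_c, sv_e, A, b, t0)
  names(x) <- c("v_c", "v_e", "sv_c", "sv_e", "A", "b", "t0")
  if (any(!is.finite(x))) stop("all LBA parameters must be finite")
  if (any(x < 0)) stop("all LBA parameters must be non-negative")
  if (b < A) stop("threshold b must be >= start-point bound A")
  if (sv_c != 1) stop("sv_c is fixed to 1 (scaling constraint)")
  if (sv_e <= 0) stop("sv_e must be positive")
  structure(as.list(x), class = "lba_params")
}

#' @export
print.lba_params <- function(x, ...) {
  cat("LBA parameters:",
      paste(names(x), unlist(x), sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

params_row <- function(p) {
  out <- unlist(p[c("v_c", "v_e", "sv_c", "sv_e", "A", "b", "t0")],
                use.names = FALSE)
  if (length(out) != 7 || anyNA(out)) stop("invalid lba_params")
  out
}

#' Choice response-time dataset
#'
#' Constructs and validates a per-trial dataset: condition index (1 or 2),
#' response correctness (`"correct"` or `"error"`), and response time in
#' seconds.
#'
#' @param condition integer vector of condition indices in `{1, 2}`.
#' @param response character vector, `"correct"` or `"error"`.
#' @param rt positive response times in seconds.
#' @return A `data.frame` of class `choice_rt`.
#' @export
choice_rt <- function(condition = integer(), response = character(),
                      rt = numeric()) {
  condition <- as.integer(condition)
  response <- as.character(response)
  rt <- as.double(rt)
  n <- length(rt)
  if (length(condition) != n || length(response) != n)
    stop("condition, response and rt must have equal length")
  if (n > 0) {
    if (!all(condition %in% c(1L, 2L))) stop("condition must be 1 or 2")
    if (!all(response %in% c("correct", "error")))
      stop('response must be "correct" or "error"')
    if (any(!is.finite(rt)) || any(rt <= 0)) stop("rt must be positive")
  }
  structure(data.frame(condition = condition, response = response, rt = rt,
                       stringsAsFactors = FALSE),
            class = c("choice_rt", "data.frame"))
}

#' Read / write a choice-RT dataset as CSV
#'
#' @param path file path.
#' @return `read_choice_rt` returns a `choice_rt` data frame.
#' @export
read_choice_rt <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  choice_rt(d$condition, d$response, d$rt)
}

#' @param data a `choice_rt` dataset.
#' @rdname read_choice_rt
#' @export
write_choice_rt <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' First-passage density and distribution of a single LBA accumulator
#'
#' Density (`lba_node_density`) and distribution function (`lba_node_cdf`)
#' of the time at which one accumulator with start point `U(0, A)` and drift
#' drawn from `N(v, sv)` truncated below at zero first reaches threshold
#' `b`. Because the drift is always positive the accumulator finishes almost
#' surely, so the density integrates to one.
#'
#' @param t decision time(s) in seconds; values `<= 0` give 0.
#' @param b threshold; `A` start-point upper bound (`b >= A >= 0`).
#' @param v mean drift rate; `sv` drift SD (`> 0`).
#' @return Vector of densities or probabilities.
#' @export
lba_node_density <- function(t, b, A, v, sv) {
  check_node_args(t, b, A, v, sv)
  cpp_node_density(as.double(t), A, b, v, sv)
}

#' @rdname lba_node_density
#' @export
lba_node_cdf <- function(t, b, A, v, sv) {
  check_node_args(t, b, A, v, sv)
  cpp_node_cdf(as.double(t), A, b, v, sv)
}

check_node_args <- function(t, b, A, v, sv) {
  if (any(!is.finite(t))) stop("t must be finite")
  if (!all(is.finite(c(b, A, v, sv)))) stop("parameters must be finite")
  if (A < 0 || b < A) stop("need b >= A >= 0")
  if (sv <= 0) stop("sv must be positive")
  invisible(TRUE)
}

#' Defective log density of one trial outcome
#'
#' The race likelihood of observing a given response at time `rt`: the
#' winning accumulator's finishing-time density times the survivor function
#' of the losing accumulator, evaluated at decision time `rt - t0`. The
#' per-trial density is floored at `floor` before taking the log, so trials
#' faster than `t0` (or in far tails) contribute `log(floor)` rather than
#' `-Inf`.
#'
#' @param rt response time(s) in seconds.
#' @param response `"correct"` or `"error"` per trial (recycled).
#' @param params an [lba_params] object.
#' @param floor density floor (default `1e-10`).
#' @return Vector of log densities.
#' @export
lba_defective_logdens <- function(rt, response, params, floor = 1e-10) {
  if (!inherits(params, "lba_params")) params <- do.call(lba_params, params)
  n <- max(length(rt), length(response))
  rt <- rep_len(as.double(rt), n)
  correct <- rep_len(as.integer(response == "correct"), n)
  p <- matrix(params_row(params), nrow = 1)
  drop(cpp_lba_trial_loglik(rt, correct, rep(1L, n), p, p, floor))
}

#' Simulate LBA trials
#'
#' Draws race trials from the LBA: per trial and accumulator, a start point
#' from `U(0, A)` and a drift from the positive-truncated normal; the
#' finishing time is `(b - start) / drift`, the response is the accumulator
#' finishing first, and `rt = t0 +` winning time.
#'
#' @param params1 [lba_params] for condition 1.
#' @param params2 [lba_params] for condition 2; omit for a single condition.
#' @param n_per_condition trials per condition (`>= 0`).
#' @param seed optional integer seed.
#' @return A [choice_rt] dataset.
#' @export
simulate_lba_trials <- function(params1, params2 = NULL, n_per_condition,
                                seed = NULL) {
  if (!inherits(params1, "lba_params")) params1 <- do.call(lba_params, params1)
  if (!is.null(seed)) set.seed(seed)
  if (n_per_condition < 0) stop("n_per_condition must be >= 0")
  conds <- if (is.null(params2)) list(params1) else {
    if (!inherits(params2, "lba_params")) params2 <- do.call(lba_params, params2)
    list(params1, params2)
  }
  out <- lapply(seq_along(conds), function(i) {
    p <- conds[[i]]
    s <- cpp_simulate_lba(as.integer(n_per_condition), p$v_c, p$v_e, p$sv_c,
                          p$sv_e, p$A, p$b, p$t0)
    data.frame(condition = rep(i, n_per_condition),
               response = ifelse(s$correct == 1L, "correct", "error"),
               rt = s$rt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  choice_rt(out$condition, out$response, out$rt)
}

#' Total LBA log-likelihood of a dataset under a model
#'
#' Sums the defective log density over trials, with each trial evaluated
#' under its condition's parameters as mapped from the free parameter vector
#' by the model specification. Returns `-Inf` (not an error) when `theta`
#' falls outside the model's support.
#'
#' @param data a [choice_rt] dataset.
#' @param model an [lba_model] specification.
#' @param theta free parameter vector (or matrix, one row per vector).
#' @param floor per-trial density floor.
#' @return Scalar log-likelihood (vector for matrix `theta`).
#' @export
lba_loglik <- function(data, model, theta, floor = 1e-10) {
  theta <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
  if (ncol(theta) != model$k) stop("theta length does not match model")
  out <- rep(-Inf, nrow(theta))
  ok <- theta_support_ok(theta, model)
  if (nrow(data) == 0) {
    out[ok] <- 0
  } else if (any(ok)) {
    cp <- theta_to_condition_matrices(theta[ok, , drop = FALSE], model)
    out[ok] <- cpp_lba_loglik(data$rt, as.integer(data$response == "correct"),
                              data$condition, cp$par1, cp$par2, floor)
  }
  if (length(out) == 1) out[1] else out
}
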