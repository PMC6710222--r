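#' The four nested LBA model variants
#'
#' Builds a model specification for one of the four variants used throughout
#' the package: `"null"` (no parameter varies across the two conditions),
#' `"drift"` (the correct-response mean drift `v_c` varies), `"threshold"`
#' (the threshold `b` varies), and `"complex"` (both vary). The threshold is
#' sampled as `B = b - A`, on which the prior is placed; `b` is derived as
#' `A + B`, which keeps the support rectangular and `b >= A` automatic.
#'
#' Default priors (truncated normals, `TN(mean, SD, 0, Inf)`):
#' `v_c ~ TN(3, 3)`, `v_e ~ TN(2, 3)`, `sv_e ~ TN(2, 3)`, `A ~ TN(2, 2)`,
#' `b - A ~ TN(2, 2)`, `t0 ~ TN(0.5, 0.5)`. Under the per-condition
#' parameterization each condition's varying parameter receives an
#' independent copy of its prior.
#'
#' The `"mean-diff"` parameterization replaces each varying pair with its
#' across-condition mean and half-difference (`X_1 = X_mean - X_diff`,
#' `X_2 = X_mean + X_diff`); the mean keeps the default prior while the
#' half-difference receives a zero-centred normal whose SD is set by
#' `prior_level`: `UP` (SD 10), `WIP` (SD 1), `MIP` (SD 0.1), `HIP`
#' (SD 0.01). The half-difference prior is untruncated; positivity of the
#' mapped condition-level parameters is enforced through the log prior.
#'
#' @param variant one of `"null"`, `"drift"`, `"threshold"`, `"complex"`.
#' @param parameterization `"per-condition"` (default) or `"mean-diff"`.
#' @param prior_level `"default"` for the per-condition parameterization, or
#'   one of `"UP"`, `"WIP"`, `"MIP"`, `"HIP"` with `"mean-diff"`.
#' @return An object of class `lba_model` with elements `variant`,
#'   `parameterization`, `prior_level`, `par_names`, `k` (free parameter
#'   count), and `priors` (one row per free parameter).
#' @export
lba_model <- function(variant = c("null", "drift", "threshold", "complex"),
                      parameterization = c("per-condition", "mean-diff"),
                      prior_level = c("default", "UP", "WIP", "MIP", "HIP")) {
  variant <- match.arg(variant)
  parameterization <- match.arg(parameterization)
  prior_level <- match.arg(prior_level)
  if (parameterization == "per-condition" && prior_level != "default")
    stop("informed prior levels require the mean-diff parameterization")
  if (parameterization == "mean-diff" && prior_level == "default")
    stop('mean-diff parameterization needs a prior level ("UP", "WIP", "MIP", "HIP")')
  if (parameterization == "mean-diff" && variant == "null")
    stop("the null model has no condition differences to reparameterize")

  base <- list(v_c = c(3, 3), v_e = c(2, 3), sv_e = c(2, 3),
               A = c(2, 2), B = c(2, 2), t0 = c(0.5, 0.5))
  diff_sd <- c(UP = 10, WIP = 1, MIP = 0.1, HIP = 0.01)

  drift_varies <- variant %in% c("drift", "complex")
  thresh_varies <- variant %in% c("threshold", "complex")

  rows <- list()
  add_tn <- function(name, ref) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, family = "tnorm", mean = base[[ref]][1],
      sd = base[[ref]][2], lower = 0, stringsAsFactors = FALSE)
  }
  add_diff <- function(name) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, family = "norm", mean = 0, sd = diff_sd[[prior_level]],
      lower = -Inf, stringsAsFactors = FALSE)
  }

  if (parameterization == "per-condition") {
    if (drift_varies) { add_tn("v_c.1", "v_c"); add_tn("v_c.2", "v_c") }
    else add_tn("v_c", "v_c")
    add_tn("v_e", "v_e"); add_tn("sv_e", "sv_e"); add_tn("A", "A")
    if (thresh_varies) { add_tn("B.1", "B"); add_tn("B.2", "B") }
    else add_tn("B", "B")
    add_tn("t0", "t0")
  } else {
    if (drift_varies) { add_tn("v_c.mean", "v_c"); add_diff("v_c.diff") }
    else add_tn("v_c", "v_c")
    add_tn("v_e", "v_e"); add_tn("sv_e", "sv_e"); add_tn("A", "A")
    if (thresh_varies) { add_tn("B.mean", "B"); add_diff("B.diff") }
    else add_tn("B", "B")
    add_tn("t0", "t0")
  }
  priors <- do.call(rbind, rows)
  structure(list(variant = variant, parameterization = parameterization,
                 prior_level = prior_level, par_names = priors$name,
                 k = nrow(priors), priors = priors),
            class = "lba_model")
}

#' @export
print.lba_model <- function(x, ...) {
  cat(sprintf("LBA %s model (%s parameterization, %s priors), %d free parameters:\n",
              x$variant, x$parameterization, x$prior_level, x$k))
  print(x$priors, row.names = FALSE)
  invisible(x)
}

# per-condition values of a possibly reparameterized quantity
.cond_values <- function(theta, model, stem) {
  pn <- model$par_names
  if (model$parameterization == "mean-diff" &&
      paste0(stem, ".mean") %in% pn) {
    m <- theta[, pn == paste0(stem, ".mean")]
    d <- theta[, pn == paste0(stem, ".diff")]
    cbind(m - d, m + d)
  } else if (paste0(stem, ".1") %in% pn) {
    cbind(theta[, pn == paste0(stem, ".1")], theta[, pn == paste0(stem, ".2")])
  } else {
    v <- theta[, pn == stem]
    cbind(v, v)
  }
}

# map an m x k theta matrix to two m x 7 condition parameter matrices
# (columns v_c, v_e, sv_c, sv_e, A, b, t0)
theta_to_condition_matrices <- function(theta, model) {
  pn <- model$par_names
  vc <- .cond_values(theta, model, "v_c")
  B <- .cond_values(theta, model, "B")
  ve <- theta[, pn == "v_e"]
  sve <- theta[, pn == "sv_e"]
  A <- theta[, pn == "A"]
  t0 <- theta[, pn == "t0"]
  one <- rep(1, nrow(theta))
  list(par1 = cbind(vc[, 1], ve, one, sve, A, A + B[, 1], t0),
       par2 = cbind(vc[, 2], ve, one, sve, A, A + B[, 2], t0))
}

#' Map a free parameter vector to per-condition LBA parameters
#'
#' Deterministically expands a model's free parameter vector into the two
#' conditions' [lba_params], undoing the mean/half-difference
#' reparameterization where present (`X_1 = X_mean - X_diff`,
#' `X_2 = X_mean + X_diff`) and recovering `b` as `A + B`.
#'
#' @param theta free parameter vector in the model's support.
#' @param model an [lba_model].
#' @return List with elements `cond1` and `cond2`, each an [lba_params].
#' @export
theta_to_condition_params <- function(theta, model) {
  stopifnot(length(theta) == model$k)
  cp <- theta_to_condition_matrices(matrix(theta, nrow = 1), model)
  mk <- function(r) lba_params(v_c = r[1], v_e = r[2], sv_c = r[3],
                               sv_e = r[4], A = r[5], b = r[6], t0 = r[7])
  list(cond1 = mk(cp$par1[1, ]), cond2 = mk(cp$par2[1, ]))
}

# rows of theta (m x k) whose mapped condition parameters are all valid
theta_support_ok <- function(theta, model) {
  pr <- model$priors
  ok <- rep(TRUE, nrow(theta))
  for (j in seq_len(model$k)) {
    ok <- ok & is.finite(theta[, j]) & theta[, j] >= pr$lower[j]
  }
  cp <- theta_to_condition_matrices(theta, model)
  ok & rowSums(cp$par1 < 0) == 0 & rowSums(cp$par2 < 0) == 0 &
    cp$par1[, 4] > 0 & cp$par2[, 4] > 0
}

#' Log prior density of a free parameter vector
#'
#' Sum of independent univariate log prior densities from the model's prior
#' block (normalized truncated normals for bounded parameters, plain normals
#' for half-difference parameters). Returns `-Inf` outside the support,
#' including when a mapped condition-level parameter (such as `b - A` in a
#' reparameterized model) would be negative.
#'
#' @param theta free parameter vector (or matrix, one row per vector).
#' @param model an [lba_model].
#' @return Scalar log prior density (vector for matrix `theta`).
#' @export
log_prior <- function(theta, model) {
  theta <- if (is.matrix(theta)) theta else matrix(theta, nrow = 1)
  if (ncol(theta) != model$k) stop("theta length does not match model")
  ok <- theta_support_ok(theta, model)
  out <- rep(-Inf, nrow(theta))
  if (any(ok))
    out[ok] <- prior_logdens(theta[ok, , drop = FALSE], model)
  if (length(out) == 1) out[1] else out
}

# prior log density without support checks (callers guarantee validity)
prior_logdens <- function(theta, model) {
  pr <- model$priors
  lp <- 0
  for (j in seq_len(model$k)) {
    x <- theta[, j]
    lp <- lp + if (pr$family[j] == "tnorm") {
      dtnorm(x, pr$mean[j], pr$sd[j], pr$lower[j], log = TRUE)
    } else {
      stats::dnorm(x, pr$mean[j], pr$sd[j], log = TRUE)
    }
  }
  lp
}

#' Draw free parameter vectors from a model's prior
#'
#' @param model an [lba_model].
#' @param n number of draws.
#' @return An `n x k` matrix with one draw per row.
#' @export
sample_prior <- function(model, n) {
  pr <- model$priors
  out <- matrix(NA_real_, n, model$k, dimnames = list(NULL, model$par_names))
  for (j in seq_len(model$k)) {
    out[, j] <- if (pr$family[j] == "tnorm") {
      rtnorm(n, pr$mean[j], pr$sd[j], pr$lower[j])
    } else {
      stats::rnorm(n, pr$mean[j], pr$sd[j])
    }
  }
  out
}
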