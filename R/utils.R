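#' @useDynLib lbaselect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm pnorm qnorm rnorm runif var quantile median
#'   pchisq aggregate rbinom setNames
#' @importFrom utils read.csv write.csv
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Derive a reproducible child seed from a master seed and integer indices
#'
#' A small multiplicative hash over the master seed and any number of integer
#' indices. Used so that every (cell, replicate, model, task) job in a study
#' has its own deterministic seed below 2^31.
#'
#' @param master integer master seed.
#' @param ... integer indices identifying the job.
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.double(master) %% 2147483647
  for (x in idx) {
    h <- (h * 69069 + as.double(x) * 12345 + 1) %% 2147483647
  }
  as.integer(h) + 1L
}

# truncated-normal helpers: TN(mean, sd, lower, Inf); second argument is an SD
dtnorm <- function(x, mean, sd, lower = 0, log = FALSE) {
  lz <- stats::pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE)
  out <- stats::dnorm(x, mean, sd, log = TRUE) - lz
  out[x < lower] <- -Inf
  if (log) out else exp(out)
}

rtnorm <- function(n, mean, sd, lower = 0) {
  lo <- stats::pnorm(lower, mean, sd)
  u <- lo + stats::runif(n) * (1 - lo)
  u <- pmin(u, 1 - 1e-16)
  stats::qnorm(u, mean, sd)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

utils::globalVariables(c("col_lab", "row_lab", "stat_value"))
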