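# Internal numeric helpers shared across modules.

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Inverse-gamma density, draws and mean
#'
#' The IG(a, b) parameterisation with shape `a` and scale `b` has density
#' proportional to `x^-(a+1) exp(-b/x)` and mean `b / (a - 1)` for `a > 1`.
#' These helpers back the variance priors used throughout the package.
#'
#' @param x,n Evaluation points / number of draws.
#' @param shape,scale Positive inverse-gamma hyperparameters.
#' @param log Return the log density?
#' @return `dinvgamma()` a density vector, `rinvgamma()` draws,
#'   `invgamma_mean()` the scalar mean.
#' @export
dinvgamma <- function(x, shape, scale, log = FALSE) {
  ld <- ifelse(x > 0,
    shape * base::log(scale) - lgamma(shape) - (shape + 1) * base::log(pmax(x, .Machine$double.xmin)) - scale / x,
    -Inf)
  if (log) ld else exp(ld)
}

#' @rdname dinvgamma
#' @export
rinvgamma <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

#' @rdname dinvgamma
#' @export
invgamma_mean <- function(shape, scale) {
  if (shape <= 1) return(Inf)
  scale / (shape - 1)
}

# Truncated normal on [lo, hi] (used for correlation priors).
dtruncnorm_log <- function(x, mean = 0, sd = 1, lo = -1, hi = 1) {
  z <- stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)
  ifelse(x >= lo & x <= hi, stats::dnorm(x, mean, sd, log = TRUE) - log(z), -Inf)
}

rtruncnorm <- function(n, mean = 0, sd = 1, lo = -1, hi = 1) {
  u <- stats::runif(n,
    stats::pnorm(lo, mean, sd),
    stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# Cholesky (upper) with a single logged jitter retry; NULL if it still fails.
chol_jitter <- function(m, label = "matrix") {
  ch <- tryCatch(chol(m), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  eps <- 1e-10 * sum(diag(m)) / nrow(m)
  ch <- tryCatch(chol(m + diag(eps, nrow(m))), error = function(e) NULL)
  if (!is.null(ch)) {
    message(sprintf("jitter %.3g added to %s after failed Cholesky factorisation", eps, label))
  }
  ch
}

# log-density of N(mean, cov) with cov supplied via its upper Cholesky factor.
dmvnorm_chol_log <- function(x, mean, chol_cov) {
  d <- length(mean)
  z <- backsolve(chol_cov, x - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_cov))) - 0.5 * sum(z^2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
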