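# Recover coefficient posteriors from variance traces and compute the
# Mahalanobis recovery diagnostics.

# Dispatch: conditional coefficient posterior at one natural-scale variance
# point (named vector / one-row matrix from a trace).
conditional_at_point <- function(spec, stats, point) {
  point <- drop(point)
  kind <- spec$kind
  if (kind == "linear") {
    return(conditional_posterior_linear(stats, spec$coef_prior, point[["sigma2"]]))
  }
  if (kind == "linear_nig") {
    cp <- spec$coef_prior
    s2 <- point[["sigma2"]]
    scaled <- gaussian_prior(cp$mean, cp$gamma * s2 * cp$cov)
    return(conditional_posterior_linear(stats, scaled, s2))
  }
  if (kind == "multilevel_intercept") {
    return(conditional_posterior_ml_intercept(stats, spec$coef_prior,
                                              point[["sigma2_y"]], point[["sigma2_eta"]]))
  }
  nu <- point[names(point) != "sigma2_y"]
  conditional_posterior_ml_general(stats, spec$coef_prior, spec$structure,
                                   point[["sigma2_y"]], as.numeric(nu))
}

as_trace_matrix <- function(trace) {
  if (inherits(trace, "evidence_estimate")) trace <- variance_trace(trace)
  trace <- as.matrix(trace)
  if (nrow(trace) == 0L) stop_input("empty variance trace")
  if (is.null(colnames(trace))) stop_input("variance trace must have named columns")
  trace
}

#' Mahalanobis distance of a coefficient vector from an integrated-mode posterior
#'
#' The average over the variance trace of the per-draw quadratic form
#' `(b - mu_tilde(v))' Sigma_tilde^-1(v) (b - mu_tilde(v))`, where
#' `(mu_tilde, Sigma_tilde)` is the conditional coefficient posterior at each
#' variance draw `v`. This is the per-draw average form (not a distance under
#' a pooled covariance); see [pooled_beta_posterior()] for the pooled
#' alternative.
#'
#' @param b True (or reference) coefficient vector.
#' @param trace A variance trace matrix with named columns, or an
#'   `evidence_estimate` from integrated-mode sampling.
#' @param stats A [sufficient_stats()] of the same data.
#' @param spec The [model_spec()] that produced the trace.
#' @return Non-negative scalar; zero iff `b` equals every conditional mean.
#' @export
mahalanobis_integrated <- function(b, trace, stats, spec) {
  trace <- as_trace_matrix(trace)
  if (length(b) != stats$d) stop_input("length(b) (%d) != d (%d)", length(b), stats$d)
  total <- 0
  for (i in seq_len(nrow(trace))) {
    cg <- conditional_at_point(spec, stats, trace[i, ])
    z <- cg$chol %*% (b - cg$mean)
    total <- total + sum(z^2)
  }
  total / nrow(trace)
}

#' Mahalanobis distance of a coefficient vector from full-mode draws
#'
#' `(b - beta_bar)' V^-1 (b - beta_bar)` with the sample mean `beta_bar` and
#' the 1/(N-1)-normalised sample covariance `V` of the coefficient draws.
#'
#' @param b True (or reference) coefficient vector.
#' @param draws An `N x d` matrix of coefficient draws (`N >= d + 1` so that
#'   `V` is invertible), or an `evidence_estimate` from full-mode sampling.
#' @return Non-negative scalar.
#' @export
mahalanobis_full <- function(b, draws) {
  if (inherits(draws, "evidence_estimate")) draws <- coefficient_draws(draws)
  draws <- as.matrix(draws)
  d <- ncol(draws)
  if (length(b) != d) stop_input("length(b) (%d) != ncol(draws) (%d)", length(b), d)
  if (nrow(draws) < d + 1L) {
    stop_input("need at least d + 1 = %d draws for an invertible covariance, got %d",
               d + 1L, nrow(draws))
  }
  V <- cov(draws)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    stop_input("singular sample covariance (rank %d of %d); more draws needed",
               qr(V)$rank, d)
  }
  ctr <- b - colMeans(draws)
  z <- backsolve(ch, ctr, transpose = TRUE)
  sum(z^2)
}

#' Pooled coefficient posterior from a variance trace
#'
#' Averages the conditional coefficient posteriors over the variance draws:
#' the pooled mean is the average of the conditional means. Two documented
#' covariance variants are offered: `"average"` is the plain average of the
#' conditional covariances, and `"total"` adds the between-draw spread of the
#' conditional means (law of total variance). The variant used is recorded in
#' the output.
#'
#' @inheritParams mahalanobis_integrated
#' @param variant `"average"` or `"total"`.
#' @return An object of class `coefficient_posterior` with `mean`, `cov`,
#'   `variant` and `n_draws`.
#' @export
pooled_beta_posterior <- function(trace, stats, spec, variant = c("average", "total")) {
  variant <- match.arg(variant)
  trace <- as_trace_matrix(trace)
  d <- stats$d
  N <- nrow(trace)
  mean_acc <- numeric(d)
  cov_acc <- matrix(0, d, d)
  means <- matrix(0, N, d)
  for (i in seq_len(N)) {
    cg <- conditional_at_point(spec, stats, trace[i, ])
    means[i, ] <- cg$mean
    mean_acc <- mean_acc + cg$mean
    cov_acc <- cov_acc + chol2inv(cg$chol)
  }
  pooled_mean <- mean_acc / N
  pooled_cov <- cov_acc / N
  if (variant == "total" && N > 1L) {
    pooled_cov <- pooled_cov + cov(means) * (N - 1) / N
  }
  structure(
    list(mean = pooled_mean, cov = pooled_cov, variant = variant, n_draws = N),
    class = "coefficient_posterior"
  )
}

#' @export
print.coefficient_posterior <- function(x, ...) {
  cat(sprintf("<coefficient_posterior> d = %d, pooled over %d draws (cov variant: %s)\n",
              length(x$mean), x$n_draws, x$variant))
  invisible(x)
}
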