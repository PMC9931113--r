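# Closed-form integrated log likelihoods and the sufficient statistics they
# consume. All log-determinants and quadratic forms go through Cholesky
# factorisations of precision matrices; no explicit matrix inverses appear in
# any likelihood path. Invalid parameter points (non-positive variances,
# non-SPD group covariances) return -Inf so samplers can reject them.

#' Precompute all data-only sums and products
#'
#' Everything the integrated likelihoods need from the data is computed once:
#' the cross-products `Sxx = sum_i x_i x_i'`, `Sxy = sum_i x_i y_i`,
#' `Syy = sum_i y_i^2`, and per group `j` the sums `gx_j = sum_i x_ij`,
#' `gy_j = sum_i y_ij` plus, when a `Z` matrix is present, `Szz_j`, `Szy_j`
#' and `Sxz_j`. None of these depend on any model parameter, so evaluating an
#' integrated likelihood at a new variance point touches no raw data.
#'
#' @param design A [grouped_design()].
#' @return An object of class `sufficient_stats`.
#' @export
sufficient_stats <- function(design) {
  stopifnot(inherits(design, "grouped_design"))
  X <- design$X; y <- design$y; Z <- design$Z
  g <- design$group; J <- design$J; m <- design$m
  gx <- t(rowsum(X, g, reorder = TRUE))          # d x J
  gy <- as.numeric(rowsum(y, g, reorder = TRUE)) # J
  Szz <- Szy <- Sxz <- NULL
  if (m > 0L) {
    Szz <- array(0, dim = c(m, m, J))
    Sxz <- array(0, dim = c(design$d, m, J))
    Szy <- matrix(0, m, J)
    for (j in seq_len(J)) {
      idx <- which(g == j)
      Zj <- Z[idx, , drop = FALSE]
      Szz[, , j] <- crossprod(Zj)
      Szy[, j] <- crossprod(Zj, y[idx])
      Sxz[, , j] <- crossprod(X[idx, , drop = FALSE], Zj)
    }
  }
  structure(
    list(
      Sxx = crossprod(X),
      Sxy = as.numeric(crossprod(X, y)),
      Syy = sum(y^2),
      gx = gx, gy = gy,
      Szz = Szz, Szy = Szy, Sxz = Sxz,
      n = design$n, nj = design$group_sizes,
      d = design$d, m = m, J = J
    ),
    class = "sufficient_stats"
  )
}

new_conditional_gaussian <- function(mean, precision, chol_prec) {
  structure(
    list(mean = as.numeric(mean), precision = precision, chol = chol_prec,
         log_det_precision = 2 * sum(log(diag(chol_prec)))),
    class = "conditional_gaussian"
  )
}

# Shared finishing step: given precision P and linear term b, return the
# conditional Gaussian N(P^-1 b, P^-1) without forming P^-1 explicitly.
finish_conditional <- function(P, b, label) {
  ch <- chol_jitter(P, label)
  if (is.null(ch)) {
    stop_input("conditional precision not positive-definite (%s); rcond ~ %.3g",
               label, rcond(P))
  }
  mean <- backsolve(ch, backsolve(ch, b, transpose = TRUE))
  new_conditional_gaussian(mean, P, ch)
}

#' Conditional coefficient posterior for the single-level linear model
#'
#' Returns the Gaussian posterior of `beta` given `sigma2`:
#' precision `Sigma^-1 + Sxx / sigma2`, mean
#' `solve(precision, Sigma^-1 mu + Sxy / sigma2)`.
#'
#' @param stats A [sufficient_stats()].
#' @param prior A [gaussian_prior()].
#' @param sigma2 Residual variance (> 0).
#' @return A `conditional_gaussian` (mean, precision, Cholesky factor,
#'   log-determinant of the precision).
#' @export
conditional_posterior_linear <- function(stats, prior, sigma2) {
  stopifnot(sigma2 > 0)
  P <- prior$prec + stats$Sxx / sigma2
  b <- prior$prec %*% prior$mean + stats$Sxy / sigma2
  finish_conditional(P, b, "linear conditional")
}

#' Integrated log likelihood for the single-level linear model
#'
#' The coefficient vector is marginalised analytically under its Gaussian
#' prior, leaving `log p(D | M, sigma2)`. Vectorised over `sigma2`; invalid
#' variances give `-Inf`.
#'
#' @inheritParams conditional_posterior_linear
#' @param sigma2 Residual variance(s); may be a vector.
#' @return Numeric vector of log integrated likelihood values.
#' @export
loglik_integrated_linear <- function(stats, prior, sigma2) {
  res <- cpp_ll_linear(stats$Sxx, stats$Sxy, stats$Syy, stats$n,
                       prior$mean, prior$prec, prior$logdet,
                       as.numeric(sigma2))
  as.numeric(res)
}

#' Integrated log likelihood under the normal-inverse-gamma prior
#'
#' For the joint prior `NIG(a, b, mu, gamma * Sigma)` the conditional
#' coefficient covariance is `gamma * sigma2 * Sigma`, so this equals
#' [loglik_integrated_linear()] evaluated at that scaled covariance (the two
#' printed forms of the integrated likelihood agree under this substitution).
#'
#' @param stats A [sufficient_stats()].
#' @param prior An [nig_prior()].
#' @param sigma2 Residual variance(s); may be a vector.
#' @return Numeric vector of log integrated likelihood values.
#' @export
loglik_integrated_nig <- function(stats, prior, sigma2) {
  res <- cpp_ll_nig(stats$Sxx, stats$Sxy, stats$Syy, stats$n,
                    prior$mean, prior$prec, prior$logdet, prior$gamma,
                    as.numeric(sigma2))
  as.numeric(res)
}

#' Analytic log model evidence under the normal-inverse-gamma prior
#'
#' The fully conjugate case: both `beta` and `sigma2` integrate out in closed
#' form. With effective coefficient template `Sigma_g = gamma * Sigma`,
#' `Sigma_hat^-1 = Sigma_g^-1 + Sxx`, `mu_hat = Sigma_hat (Sigma_g^-1 mu + Sxy)`
#' and `b' = b + (mu' Sigma_g^-1 mu + Syy - mu_hat' Sigma_hat^-1 mu_hat) / 2`:
#'
#' `log p(D|M) = -0.5 (log|Sigma_hat^-1| + log|Sigma_g| + n log 2pi)
#'   + a log b - (a + n/2) log b' + lgamma(n/2 + a) - lgamma(a)`
#'
#' Updating with no data returns exactly 0.
#'
#' @param stats A [sufficient_stats()].
#' @param prior An [nig_prior()].
#' @return Scalar log evidence.
#' @export
log_evidence_nig <- function(stats, prior) {
  a <- prior$shape; b <- prior$scale
  prec_g <- prior$prec / prior$gamma
  logdet_g <- prior$logdet + prior$d * log(prior$gamma)
  P <- prec_g + stats$Sxx
  ch <- chol_jitter(P, "NIG posterior precision")
  if (is.null(ch)) stop_input("NIG posterior precision not positive-definite")
  bvec <- prec_g %*% prior$mean + stats$Sxy
  z <- backsolve(ch, bvec, transpose = TRUE)
  quad <- sum(z^2)  # mu_hat' Sigma_hat^-1 mu_hat
  b_prime <- b + 0.5 * (sum(prior$mean * (prec_g %*% prior$mean)) + stats$Syy - quad)
  if (b_prime <= 0) stop_input("NIG update produced b' <= 0 (ill-posed data)")
  logdet_P <- 2 * sum(log(diag(ch)))
  -0.5 * (logdet_P + logdet_g + stats$n * log(2 * pi)) +
    a * log(b) - (a + stats$n / 2) * log(b_prime) +
    lgamma(stats$n / 2 + a) - lgamma(a)
}

#' Normal-inverse-gamma posterior update
#'
#' Conjugate update `NIG(a, b, mu, gamma * Sigma) -> NIG(a + n/2, b', mu_hat,
#' Sigma_hat)`. Updating with zero data is the identity, and two sequential
#' half-data updates equal one full update.
#'
#' @inheritParams log_evidence_nig
#' @return An [nig_prior()] holding the posterior (with `gamma = 1`, the
#'   multiplier having been folded into the covariance).
#' @export
nig_posterior <- function(stats, prior) {
  if (length(stats$Sxy) != prior$d) {
    stop_input("stats dimension (%d) != prior dimension (%d)", length(stats$Sxy), prior$d)
  }
  prec_g <- prior$prec / prior$gamma
  P <- prec_g + stats$Sxx
  ch <- chol_jitter(P, "NIG posterior precision")
  if (is.null(ch)) stop_input("NIG posterior precision not positive-definite")
  bvec <- prec_g %*% prior$mean + stats$Sxy
  mu_hat <- backsolve(ch, backsolve(ch, bvec, transpose = TRUE))
  quad <- sum(mu_hat * bvec)
  b_prime <- prior$scale +
    0.5 * (sum(prior$mean * (prec_g %*% prior$mean)) + stats$Syy - quad)
  nig_prior(prior$shape + stats$n / 2, b_prime, as.numeric(mu_hat), chol2inv(ch), gamma = 1)
}

#' Integrated log likelihood for the varying-intercept multilevel model
#'
#' Both the coefficients and the scalar group deviations `eta_j` are
#' marginalised analytically, leaving `log p(D | M, sigma2_y, sigma2_eta)`.
#' The group term contributes `sum_j log((sigma2_y + n_j sigma2_eta) / sigma2_y)`
#' and a per-group correction proportional to `(sum_i y_ij)^2`. Setting
#' `sigma2_eta = 0` recovers the single-level integrated likelihood exactly.
#' Vectorised over variance pairs.
#'
#' @param stats A [sufficient_stats()].
#' @param prior A [gaussian_prior()].
#' @param sigma2_y Residual variance(s) (> 0).
#' @param sigma2_eta Group-effect variance(s) (>= 0; 0 is the no-group limit).
#' @return Numeric vector of log integrated likelihood values.
#' @export
loglik_integrated_ml_intercept <- function(stats, prior, sigma2_y, sigma2_eta) {
  k <- max(length(sigma2_y), length(sigma2_eta))
  s2y <- rep_len(as.numeric(sigma2_y), k)
  s2e <- rep_len(as.numeric(sigma2_eta), k)
  res <- cpp_ll_ml_intercept(stats$Sxx, stats$Sxy, stats$Syy,
                             stats$gx, stats$gy, as.numeric(stats$nj), stats$n,
                             prior$mean, prior$prec, prior$logdet, s2y, s2e)
  as.numeric(res)
}

#' Conditional coefficient posterior for the varying-intercept model
#'
#' @inheritParams loglik_integrated_ml_intercept
#' @param sigma2_y,sigma2_eta Scalars.
#' @return A `conditional_gaussian`; reduces to
#'   [conditional_posterior_linear()] when `sigma2_eta = 0`.
#' @export
conditional_posterior_ml_intercept <- function(stats, prior, sigma2_y, sigma2_eta) {
  stopifnot(sigma2_y > 0, sigma2_eta >= 0)
  w <- sigma2_eta / (sigma2_y + stats$nj * sigma2_eta)  # length J
  gxw <- sweep(stats$gx, 2, w, `*`)
  P <- prior$prec + stats$Sxx / sigma2_y - tcrossprod(gxw, stats$gx) / sigma2_y
  b <- prior$prec %*% prior$mean + stats$Sxy / sigma2_y -
    as.numeric(gxw %*% stats$gy) / sigma2_y
  finish_conditional(P, b, "multilevel-intercept conditional")
}

#' Integrated log likelihood for the general multilevel model
#'
#' Group deviations are `m`-dimensional with covariance `Sigma_eta(nu)` given
#' by a [cov_structure()]. Each evaluation factorises the `m x m` per-group
#' conditional precisions `Sigma_eta^-1 + Szz_j / sigma2_y` afresh (they depend
#' on the parameter point). Non-SPD `Sigma_eta(nu)` gives `-Inf`. With
#' `m = 1`, `Z = 1` and a diagonal structure this reduces exactly to
#' [loglik_integrated_ml_intercept()].
#'
#' @param stats A [sufficient_stats()] built from a design with a `Z` matrix.
#' @param prior A [gaussian_prior()].
#' @param structure A [cov_structure()].
#' @param sigma2_y Residual variance(s).
#' @param nu Parameter vector, or a matrix with one row per evaluation point.
#' @return Numeric vector of log integrated likelihood values.
#' @export
loglik_integrated_ml_general <- function(stats, prior, structure, sigma2_y, nu) {
  if (is.vector(nu)) nu <- matrix(nu, nrow = 1L)
  k <- max(length(sigma2_y), nrow(nu))
  s2y <- rep_len(as.numeric(sigma2_y), k)
  if (nrow(nu) == 1L && k > 1L) nu <- nu[rep(1L, k), , drop = FALSE]
  m <- structure$m
  cube <- array(0, dim = c(m, m, k))
  valid <- logical(k)
  for (i in seq_len(k)) {
    cp <- cov_from_param(structure, nu[i, ])
    cube[, , i] <- cp$sigma
    valid[i] <- cp$valid
  }
  res <- cpp_ll_ml_general(stats$Sxx, stats$Sxy, stats$Syy,
                           stats$Szz, stats$Szy, stats$Sxz, stats$n,
                           prior$mean, prior$prec, prior$logdet,
                           s2y, cube, valid)
  as.numeric(res)
}

#' Conditional coefficient posterior for the general multilevel model
#'
#' @inheritParams loglik_integrated_ml_general
#' @param sigma2_y Scalar residual variance.
#' @param nu Parameter vector for the covariance structure.
#' @return A `conditional_gaussian`.
#' @export
conditional_posterior_ml_general <- function(stats, prior, structure, sigma2_y, nu) {
  stopifnot(sigma2_y > 0)
  cp <- cov_from_param(structure, nu)
  if (!cp$valid) stop_input("Sigma_eta(nu) is not positive-definite at this point")
  m <- stats$m; J <- stats$J
  ch_eta <- chol(cp$sigma)
  prec_eta <- chol2inv(ch_eta)
  P <- prior$prec + stats$Sxx / sigma2_y
  b <- prior$prec %*% prior$mean + stats$Sxy / sigma2_y
  for (j in seq_len(J)) {
    Aj <- prec_eta + matrix(stats$Szz[, , j], m, m) / sigma2_y
    chA <- chol(Aj)
    Sxz_j <- matrix(stats$Sxz[, , j], stats$d, m)
    W <- backsolve(chA, backsolve(chA, t(Sxz_j), transpose = TRUE))  # m x d
    P <- P - (Sxz_j %*% W) / sigma2_y^2
    vz <- backsolve(chA, backsolve(chA, stats$Szy[, j], transpose = TRUE))
    b <- b - (Sxz_j %*% vz) / sigma2_y^2
  }
  finish_conditional(P, b, "multilevel-general conditional")
}

#' Per-group conditional precisions for the general multilevel model
#'
#' The `J` conditional precisions `Sigma_eta^-1(nu) + Szz_j / sigma2_y` of the
#' group deviations, with their Cholesky factors and log-determinants.
#'
#' @inheritParams conditional_posterior_ml_general
#' @return A list of length `J`; each element has `precision`, `chol`,
#'   `log_det_precision` and the conditional mean contribution `mu_eta`
#'   (evaluated at `beta = mu_hat` of the coefficient conditional).
#' @export
per_group_conditional <- function(stats, prior, structure, sigma2_y, nu) {
  cp <- cov_from_param(structure, nu)
  if (!cp$valid) stop_input("Sigma_eta(nu) is not positive-definite at this point")
  prec_eta <- chol2inv(chol(cp$sigma))
  beta_hat <- conditional_posterior_ml_general(stats, prior, structure, sigma2_y, nu)$mean
  m <- stats$m
  lapply(seq_len(stats$J), function(j) {
    Aj <- prec_eta + matrix(stats$Szz[, , j], m, m) / sigma2_y
    chA <- chol(Aj)
    rhs <- (stats$Szy[, j] - t(matrix(stats$Sxz[, , j], stats$d, m)) %*% beta_hat) / sigma2_y
    list(
      precision = Aj, chol = chA,
      log_det_precision = 2 * sum(log(diag(chA))),
      mu_eta = as.numeric(backsolve(chA, backsolve(chA, rhs, transpose = TRUE)))
    )
  })
}

#' Full (unintegrated) log likelihood
#'
#' The joint Gaussian log density of the residuals given all parameters, plus
#' (for multilevel kinds) the log density of the group deviations under their
#' level-two distribution. This is the quantity the full-likelihood
#' comparison mode samples over.
#'
#' @param design A [grouped_design()].
#' @param spec A [model_spec()].
#' @param beta Coefficient vector (length `d`).
#' @param variances Named list: `sigma2` for single-level kinds;
#'   `sigma2_y` plus `sigma2_eta` (intercept) or `nu` (general) otherwise.
#' @param eta A [latent_effects()] (or bare matrix/vector) for multilevel kinds.
#' @return Scalar log density.
#' @export
loglik_full <- function(design, spec, beta, variances, eta = NULL) {
  check_spec_design(spec, design)
  if (length(beta) != design$d) stop_input("length(beta) (%d) != d (%d)", length(beta), design$d)
  kind <- spec$kind
  fitted <- as.numeric(design$X %*% beta)
  if (kind %in% c("linear", "linear_nig")) {
    s2 <- variances$sigma2 %||% variances$sigma2_y
    if (is.null(s2) || s2 <= 0) return(-Inf)
    return(sum(stats::dnorm(design$y, fitted, sqrt(s2), log = TRUE)))
  }
  if (is.null(eta)) stop_input("multilevel kinds require eta")
  if (!inherits(eta, "latent_effects")) eta <- latent_effects(eta)
  if (eta$J != design$J) stop_input("eta has %d rows, expected J = %d", eta$J, design$J)
  s2y <- variances$sigma2_y
  if (is.null(s2y) || s2y <= 0) return(-Inf)
  if (kind == "multilevel_intercept") {
    if (eta$m != 1L) stop_input("intercept model expects m = 1 latent effects")
    s2e <- variances$sigma2_eta
    if (is.null(s2e) || s2e <= 0) return(-Inf)
    fitted <- fitted + eta$eta[design$group, 1L]
    return(sum(stats::dnorm(design$y, fitted, sqrt(s2y), log = TRUE)) +
           sum(stats::dnorm(eta$eta[, 1L], 0, sqrt(s2e), log = TRUE)))
  }
  # multilevel_general
  if (eta$m != design$m) stop_input("eta has %d columns, expected m = %d", eta$m, design$m)
  cp <- cov_from_param(spec$structure, variances$nu)
  if (!cp$valid) return(-Inf)
  ch <- chol(cp$sigma)
  fitted <- fitted + rowSums(design$Z * eta$eta[design$group, , drop = FALSE])
  lp_eta <- sum(apply(eta$eta, 1L, dmvnorm_chol_log, mean = rep(0, design$m), chol_cov = ch))
  sum(stats::dnorm(design$y, fitted, sqrt(s2y), log = TRUE)) + lp_eta
}
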