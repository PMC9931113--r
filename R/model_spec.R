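# Domain types: grouped designs, priors, covariance structures, model specs.

#' Grouped regression design
#'
#' Container for an outcome vector `y`, an individual-level design matrix `X`
#' (which should contain an explicit intercept column if one is wanted), an
#' optional group-varying design matrix `Z`, and a group membership vector.
#' Group labels are re-indexed densely to `1..J` in first-appearance order;
#' the original labels are retained for reporting.
#'
#' @param y Numeric outcome vector of length `n`.
#' @param X Numeric `n x d` design matrix.
#' @param Z Optional numeric `n x m` design matrix for coefficients that vary
#'   by group. `NULL` means no group-varying part.
#' @param group Vector of group labels of length `n` (any atomic type), or
#'   `NULL` for a single group.
#' @param t Optional covariate (e.g. time) retained for plotting/serialisation.
#' @return An object of class `grouped_design` with elements `y`, `X`, `Z`,
#'   `group` (dense integer indices), `group_labels`, `group_sizes`, and the
#'   dimensions `n`, `d`, `m`, `J`.
#' @examples
#' d <- grouped_design(rnorm(6), cbind(1, rnorm(6)), group = c(1, 1, 2, 1, 2, 1))
#' d$J
#' d$group_sizes
#' @export
grouped_design <- function(y, X, Z = NULL, group = NULL, t = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  if (n == 0L) stop_input("empty design: y has length 0")
  if (nrow(X) != n) stop_input("nrow(X) (%d) != length(y) (%d)", nrow(X), n)
  if (!all(is.finite(y))) stop_input("y contains non-finite values")
  if (!all(is.finite(X))) stop_input("X contains non-finite values")
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (nrow(Z) != n) stop_input("nrow(Z) (%d) != length(y) (%d)", nrow(Z), n)
    if (!all(is.finite(Z))) stop_input("Z contains non-finite values")
  }
  if (is.null(group)) group <- rep(1L, n)
  if (length(group) != n) stop_input("length(group) (%d) != length(y) (%d)", length(group), n)
  if (anyNA(group)) stop_input("group contains missing values")
  labels <- unique(group)
  idx <- match(group, labels)
  sizes <- tabulate(idx, nbins = length(labels))
  structure(
    list(
      y = y, X = X, Z = Z,
      group = idx,
      group_labels = labels,
      group_sizes = sizes,
      n = n, d = ncol(X),
      m = if (is.null(Z)) 0L else ncol(Z),
      J = length(labels),
      t = t
    ),
    class = "grouped_design"
  )
}

#' @export
print.grouped_design <- function(x, ...) {
  cat(sprintf(
    "<grouped_design> n = %d, d = %d, m = %d, J = %d\n  group sizes: %s\n",
    x$n, x$d, x$m, x$J, paste(x$group_sizes, collapse = " ")
  ))
  invisible(x)
}

#' Build a grouped design from a labelled table
#'
#' @param table A data frame with named columns.
#' @param outcome Name of the outcome column.
#' @param covariates Character vector of column names forming `X`, in order.
#' @param group Optional name of the group-label column.
#' @param z_covariates Optional character vector of column names forming `Z`.
#' @return A [grouped_design()].
#' @export
build_design <- function(table, outcome, covariates, group = NULL, z_covariates = NULL) {
  if (!is.data.frame(table)) stop_input("`table` must be a data frame")
  if (nrow(table) == 0L) stop_input("`table` is empty")
  need <- c(outcome, covariates, group, z_covariates)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols) > 0) {
    stop_input("missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  num_cols <- c(outcome, covariates, z_covariates)
  vals <- table[num_cols]
  if (anyNA(vals)) stop_input("NA values in column(s): %s",
    paste(num_cols[vapply(vals, anyNA, logical(1))], collapse = ", "))
  grouped_design(
    y = table[[outcome]],
    X = as.matrix(table[covariates]),
    Z = if (is.null(z_covariates)) NULL else as.matrix(table[z_covariates]),
    group = if (is.null(group)) NULL else table[[group]]
  )
}

#' Gaussian prior for regression coefficients
#'
#' @param mean Prior mean vector (a scalar is recycled to `length = nrow(cov)`).
#' @param cov Symmetric positive-definite prior covariance matrix.
#' @return An object of class `gaussian_prior` caching the Cholesky factor,
#'   the precision matrix and the log-determinant of `cov`.
#' @export
gaussian_prior <- function(mean, cov) {
  cov <- as.matrix(cov)
  d <- nrow(cov)
  if (ncol(cov) != d) stop_input("cov must be square")
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-12))) stop_input("cov must be symmetric")
  if (length(mean) == 1L) mean <- rep(as.numeric(mean), d)
  if (length(mean) != d) stop_input("length(mean) (%d) != nrow(cov) (%d)", length(mean), d)
  ch <- tryCatch(chol(cov), error = function(e) NULL)
  if (is.null(ch)) stop_input("cov is not positive-definite (Cholesky failed)")
  structure(
    list(
      mean = as.numeric(mean), cov = cov, d = d,
      chol = ch,
      prec = chol2inv(ch),
      logdet = 2 * sum(log(diag(ch)))
    ),
    class = "gaussian_prior"
  )
}

#' Inverse-gamma prior for a variance component
#'
#' @param shape,scale Positive hyperparameters `a` and `b`; the prior mean is
#'   `b / (a - 1)` for `a > 1`.
#' @return An object of class `invgamma_prior`.
#' @export
invgamma_prior <- function(shape, scale) {
  if (!(is.numeric(shape) && shape > 0)) stop_input("shape must be > 0")
  if (!(is.numeric(scale) && scale > 0)) stop_input("scale must be > 0")
  structure(list(shape = shape, scale = scale), class = "invgamma_prior")
}

#' Normal-inverse-gamma joint prior
#'
#' The joint conjugate prior `NIG(a, b, mu, gamma * Sigma)` for `(beta, sigma2)`
#' in a Gaussian linear model: `sigma2 ~ IG(a, b)` and
#' `beta | sigma2 ~ N(mu, gamma * sigma2 * Sigma)`. The scalar `gamma`
#' multiplies the covariance template `Sigma`, so that e.g. `gamma = 1 / E[sigma2]`
#' makes the marginal coefficient covariance equal to `Sigma`.
#'
#' @param shape,scale Inverse-gamma hyperparameters `a`, `b`.
#' @param mean Coefficient prior mean (scalar recycled).
#' @param cov Coefficient covariance template `Sigma`.
#' @param gamma Positive scalar multiplier on `Sigma` (default 1).
#' @return An object of class `nig_prior`.
#' @export
nig_prior <- function(shape, scale, mean, cov, gamma = 1) {
  if (!(is.numeric(gamma) && gamma > 0)) stop_input("gamma must be > 0")
  g <- gaussian_prior(mean, cov)
  structure(
    list(
      shape = shape, scale = scale, gamma = gamma,
      mean = g$mean, cov = g$cov, d = g$d,
      chol = g$chol, prec = g$prec, logdet = g$logdet
    ),
    class = "nig_prior"
  )
}

#' Parameterised covariance structure for group effects
#'
#' Describes the map `nu -> Sigma_eta(nu)` for the group-effect covariance in
#' the general multilevel model. Supported kinds:
#'
#' * `"diagonal"`: `nu` holds the `m` diagonal variances.
#' * `"pair_correlation"`: `m = 2`, `nu = (s1^2, s2^2, rho)` with off-diagonal
#'   `rho * s1 * s2` (the varying-slopes-and-intercepts parameterisation).
#' * `"banded_shared_rho"`: `nu` holds `m` variances (plus a trailing free
#'   `rho` when `rho = NULL`); adjacent pairs `(k, k+1)` for `k >= 2` share the
#'   single correlation `rho`, and component 1 is independent. This realises
#'   the banded group-covariance used by the simulation study exactly.
#' * `"full_cholesky"`: `nu` of length `m(m+1)/2` holds the log-diagonal and
#'   the row-wise strict lower triangle of a Cholesky factor `L`, with
#'   `Sigma_eta = L L'` (an unrestricted SPD fallback).
#'
#' @param kind One of `"diagonal"`, `"pair_correlation"`, `"banded_shared_rho"`,
#'   `"full_cholesky"`.
#' @param m Dimension of the group-effect vector.
#' @param rho For `banded_shared_rho`: fixed correlation value, or `NULL` to
#'   treat it as a free component of `nu`.
#' @param rho_prior Optional truncated-normal prior on `[-1, 1]` for a free
#'   correlation, given as `list(mean =, sd =)`.
#' @return An object of class `cov_structure` with fields `n_par` (length of
#'   `nu`), `n_var` (number of variance components), `param_names`, and
#'   `rho_free`.
#' @export
cov_structure <- function(kind = c("diagonal", "pair_correlation", "banded_shared_rho", "full_cholesky"),
                          m, rho = NULL, rho_prior = NULL) {
  kind <- match.arg(kind)
  m <- as.integer(m)
  if (m < 1L) stop_input("m must be >= 1")
  rho_free <- FALSE
  if (kind == "diagonal") {
    n_par <- m; n_var <- m
    param_names <- paste0("sigma2_eta", seq_len(m))
  } else if (kind == "pair_correlation") {
    if (m != 2L) stop_input("pair_correlation requires m = 2")
    n_par <- 3L; n_var <- 2L; rho_free <- TRUE
    param_names <- c("sigma2_eta1", "sigma2_eta2", "rho")
  } else if (kind == "banded_shared_rho") {
    rho_free <- is.null(rho)
    n_var <- m
    n_par <- m + as.integer(rho_free)
    param_names <- c(paste0("sigma2_eta", seq_len(m)), if (rho_free) "rho")
  } else {
    n_par <- m * (m + 1L) / 2L; n_var <- m
    param_names <- paste0("chol", seq_len(n_par))
  }
  if (rho_free && is.null(rho_prior)) rho_prior <- list(mean = 0, sd = 1)
  structure(
    list(kind = kind, m = m, rho = rho, rho_free = rho_free,
         rho_prior = rho_prior, n_par = n_par, n_var = n_var,
         param_names = param_names),
    class = "cov_structure"
  )
}

#' Realise a group-effect covariance matrix from its parameter vector
#'
#' Non-positive-definite parameter values (e.g. `|rho| > 1` or a negative
#' variance) are flagged via `valid = FALSE` rather than raising an error, so
#' samplers can treat them as zero-probability points.
#'
#' @param structure A [cov_structure()].
#' @param nu Numeric parameter vector of length `structure$n_par`.
#' @return A list with `sigma` (an exactly symmetric `m x m` matrix) and
#'   `valid` (logical: is `sigma` symmetric positive-definite?).
#' @export
cov_from_param <- function(structure, nu) {
  stopifnot(inherits(structure, "cov_structure"))
  if (length(nu) != structure$n_par) {
    stop_input("length(nu) (%d) != expected (%d)", length(nu), structure$n_par)
  }
  m <- structure$m
  kind <- structure$kind
  valid <- all(is.finite(nu))
  if (kind == "full_cholesky") {
    L <- matrix(0, m, m)
    diag(L) <- exp(nu[seq_len(m)])
    if (m > 1L) L[lower.tri(L)] <- nu[-seq_len(m)]
    sig <- L %*% t(L)
    sig[upper.tri(sig)] <- t(sig)[upper.tri(sig)]  # exact symmetry
    return(list(sigma = sig, valid = valid))
  }
  vars <- nu[seq_len(structure$n_var)]
  if (any(vars <= 0)) valid <- FALSE
  sig <- diag(pmax(vars, 0), m, m)
  rho <- NULL
  if (kind == "pair_correlation" || (kind == "banded_shared_rho" && structure$rho_free)) {
    rho <- nu[structure$n_par]
  } else if (kind == "banded_shared_rho") {
    rho <- structure$rho
  }
  if (!is.null(rho)) {
    if (abs(rho) > 1) valid <- FALSE
    s <- sqrt(pmax(vars, 0))
    if (kind == "pair_correlation") {
      off <- rho * s[1] * s[2]
      sig[1, 2] <- off; sig[2, 1] <- off
    } else {
      for (k in seq_len(m - 1L)) {
        if (k >= 2L) {
          off <- rho * s[k] * s[k + 1L]
          sig[k, k + 1L] <- off; sig[k + 1L, k] <- off
        }
      }
    }
  }
  if (valid) {
    valid <- !is.null(tryCatch(chol(sig), error = function(e) NULL))
  }
  list(sigma = sig, valid = valid)
}

#' Model specification
#'
#' Binds a model kind, a coefficient prior and variance priors into the single
#' object consumed by the likelihood and evidence machinery. Kinds:
#'
#' * `"linear"`: `y = X b + e`, `b ~ N(mu, Sigma)`, `e ~ N(0, sigma2)`;
#'   variance prior named `sigma2`.
#' * `"linear_nig"`: as above with the joint conjugate [nig_prior()] on
#'   `(b, sigma2)`; the evidence is available analytically.
#' * `"multilevel_intercept"`: adds a scalar group deviation
#'   `eta_j ~ N(0, sigma2_eta)`; variance priors `sigma2_y`, `sigma2_eta`.
#' * `"multilevel_general"`: group deviations `eta_j ~ N(0, Sigma_eta(nu))` on
#'   the `Z` columns; requires a [cov_structure()] and one inverse-gamma prior
#'   per variance component of `nu` (list `nu` of priors), with any free
#'   correlation governed by the structure's `rho_prior`.
#'
#' @param kind Model kind (see above).
#' @param coef_prior A [gaussian_prior()] (or [nig_prior()] for `linear_nig`).
#' @param variance_priors Named list of [invgamma_prior()] objects; see kinds.
#' @param structure A [cov_structure()] for `multilevel_general`.
#' @param name Optional display name.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(kind = c("linear", "linear_nig", "multilevel_intercept", "multilevel_general"),
                       coef_prior, variance_priors = list(), structure = NULL,
                       name = NULL) {
  kind <- match.arg(kind)
  chk_ig <- function(p, what) {
    if (!inherits(p, "invgamma_prior")) stop_input("variance prior `%s` must be an invgamma_prior", what)
  }
  if (kind == "linear_nig") {
    if (!inherits(coef_prior, "nig_prior")) stop_input("linear_nig requires an nig_prior coefficient prior")
  } else {
    if (!inherits(coef_prior, "gaussian_prior")) stop_input("kind `%s` requires a gaussian_prior coefficient prior", kind)
  }
  if (kind == "linear") chk_ig(variance_priors$sigma2, "sigma2")
  if (kind == "multilevel_intercept") {
    chk_ig(variance_priors$sigma2_y, "sigma2_y")
    chk_ig(variance_priors$sigma2_eta, "sigma2_eta")
  }
  if (kind == "multilevel_general") {
    chk_ig(variance_priors$sigma2_y, "sigma2_y")
    if (!inherits(structure, "cov_structure")) stop_input("multilevel_general requires a cov_structure")
    nu_priors <- variance_priors$nu
    if (length(nu_priors) != structure$n_var) {
      stop_input("need %d inverse-gamma priors in variance_priors$nu, got %d",
                 structure$n_var, length(nu_priors))
    }
    for (p in nu_priors) chk_ig(p, "nu component")
  }
  structure(
    list(kind = kind, coef_prior = coef_prior,
         variance_priors = variance_priors, structure = structure,
         name = name %||% kind),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (kind = %s, d = %d)\n", x$name, x$kind, x$coef_prior$d))
  invisible(x)
}

#' Group-level latent effects
#'
#' @param eta A `J x m` matrix of group deviations (`m = 1` for the
#'   intercept-only multilevel model). A vector is treated as a single column.
#' @return An object of class `latent_effects`.
#' @export
latent_effects <- function(eta) {
  if (is.vector(eta)) eta <- matrix(eta, ncol = 1L)
  eta <- as.matrix(eta)
  if (!all(is.finite(eta))) stop_input("eta contains non-finite values")
  structure(list(eta = eta, J = nrow(eta), m = ncol(eta)), class = "latent_effects")
}

# Validate spec-vs-design compatibility; returns invisibly or stops.
check_spec_design <- function(spec, design) {
  if (spec$coef_prior$d != design$d) {
    stop_input("coefficient prior dimension (%d) != design d (%d)", spec$coef_prior$d, design$d)
  }
  if (spec$kind == "multilevel_general") {
    if (design$m == 0L) stop_input("multilevel_general requires a Z matrix in the design")
    if (spec$structure$m != design$m) {
      stop_input("cov_structure m (%d) != design m (%d)", spec$structure$m, design$m)
    }
  }
  if (spec$kind == "multilevel_intercept" && design$J < 1L) {
    stop_input("multilevel model requires group information")
  }
  invisible(TRUE)
}
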