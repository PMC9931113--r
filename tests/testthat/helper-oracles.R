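# Independent oracles and fixture builders used across the test files.
# Everything here deliberately avoids the package's own likelihood code paths:
# marginal covariances are built densely, quadrature integrates raw densities,
# and Monte-Carlo marginalisation draws directly from the priors.

# Random small grouped design.
rand_design <- function(n = 6, d = 2, J = 2, m = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (d - 1)), n, d - 1))
  g <- sample(seq_len(J), n, replace = TRUE)
  g[seq_len(J)] <- seq_len(J)  # every group occupied
  Z <- if (m > 0) cbind(1, matrix(rnorm(n * (m - 1)), n, m - 1)) else NULL
  grouped_design(rnorm(n, 0, 1.5), X, Z = Z, group = g)
}

rand_spd <- function(d, scale = 1) {
  A <- matrix(rnorm(d * d), d)
  crossprod(A) / d + diag(scale, d)
}

# Dense-marginal oracle for the single-level model:
# y ~ N(X mu, sigma2 I + X Sigma X').
oracle_linear_marginal <- function(design, mean, cov, sigma2) {
  n <- design$n
  V <- diag(sigma2, n) + design$X %*% cov %*% t(design$X)
  r <- design$y - as.numeric(design$X %*% mean)
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) +
            sum(r * solve(V, r)))
}

# Dense-marginal oracle for the multilevel models: adds the blockwise group
# covariance Z_j Seta Z_j' (Z = column of ones for the intercept model).
oracle_ml_marginal <- function(design, mean, cov, sigma2_y, Seta, Z = NULL) {
  n <- design$n
  if (is.null(Z)) Z <- matrix(1, n, 1)
  Seta <- as.matrix(Seta)
  B <- matrix(0, n, n)
  for (j in seq_len(design$J)) {
    idx <- which(design$group == j)
    Zj <- Z[idx, , drop = FALSE]
    B[idx, idx] <- Zj %*% Seta %*% t(Zj)
  }
  V <- diag(sigma2_y, n) + B + design$X %*% cov %*% t(design$X)
  r <- design$y - as.numeric(design$X %*% mean)
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) +
            sum(r * solve(V, r)))
}

# Nested adaptive quadrature of the coefficient integral for d <= 2:
# integral over beta of N(y | X beta, sigma2 I) N(beta | mean, cov).
oracle_linear_quadrature <- function(design, mean, cov, sigma2) {
  X <- design$X; y <- design$y
  ch <- chol(cov)
  joint <- function(b) {
    sum(dnorm(y, as.numeric(X %*% b), sqrt(sigma2), log = TRUE)) +
      dmvn_log_helper(b, mean, ch)
  }
  d <- length(mean)
  fit <- stats::lm.fit(X, y)
  ctr <- ifelse(is.na(fit$coefficients), mean, fit$coefficients)
  shift <- joint(ctr)
  if (d == 1) {
    val <- stats::integrate(function(b1) {
      vapply(b1, function(b) exp(joint(b) - shift), numeric(1))
    }, -Inf, Inf, rel.tol = 1e-11)$value
  } else {
    inner <- function(b1) {
      stats::integrate(function(b2) {
        vapply(b2, function(bb) exp(joint(c(b1, bb)) - shift), numeric(1))
      }, -Inf, Inf, rel.tol = 1e-10)$value
    }
    val <- stats::integrate(function(b1) vapply(b1, inner, numeric(1)),
                            -Inf, Inf, rel.tol = 1e-9)$value
  }
  log(val) + shift
}

dmvn_log_helper <- function(x, mean, chol_cov) {
  z <- backsolve(chol_cov, x - mean, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(chol_cov))) - 0.5 * sum(z^2)
}

# Monte-Carlo marginalisation over (beta, eta) from the priors, with a
# delta-method standard error of the log-mean-exp. Returns c(value, se).
oracle_mc_marginal <- function(design, mean, cov, sigma2_y, Seta, Z = NULL,
                               n_draws = 1e6, seed = 1, block = 1e5) {
  set.seed(seed)
  if (is.null(Z)) Z <- matrix(1, design$n, 1)
  Seta <- as.matrix(Seta)
  m <- ncol(Seta)
  chb <- chol(cov); che <- chol(Seta)
  n <- design$n; J <- design$J
  mx <- -Inf
  lls <- numeric(0)
  done <- 0
  while (done < n_draws) {
    nb <- min(block, n_draws - done)
    beta <- sweep(matrix(rnorm(nb * length(mean)), nb) %*% chb, 2, mean, `+`)
    fitted <- tcrossprod(design$X, beta)          # n x nb
    eta <- matrix(rnorm(nb * J * m), nb) %*% kronecker(diag(J), che)
    # eta columns laid out group-major: (j-1)*m + q
    gadd <- matrix(0, n, nb)
    for (j in seq_len(J)) {
      idx <- which(design$group == j)
      gadd[idx, ] <- gadd[idx, ] +
        Z[idx, , drop = FALSE] %*% t(eta[, (j - 1) * m + seq_len(m), drop = FALSE])
    }
    resid2 <- colSums((design$y - fitted - gadd)^2)
    lls <- c(lls, -0.5 * (n * log(2 * pi * sigma2_y) + resid2 / sigma2_y))
    done <- done + nb
  }
  mx <- max(lls)
  w <- exp(lls - mx)
  est <- mx + log(mean(w))
  se <- stats::sd(w) / (mean(w) * sqrt(length(w)))
  c(value = est, se = se)
}

# Tiny NIG linear-model spec + matching data, reused in SMC calibration tests.
nig_fixture <- function(n = 200, d = 5, seed = 99) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (d - 1)), n))
  Sigma <- diag(d)
  s2 <- rinvgamma(1, 3, 0.4)
  b <- rnorm(d, 0, sqrt(2 * s2))
  y <- as.numeric(X %*% b) + rnorm(n, 0, sqrt(s2))
  design <- grouped_design(y, X, group = rep(1:4, length.out = n))
  spec <- model_spec("linear_nig", nig_prior(3, 0.4, 0, Sigma, gamma = 2), name = "nig-toy")
  list(design = design, spec = spec)
}

# Reduced-scale simulation config shared by study-level tests.
reduced_config <- function(seed) {
  sim_study_config(J = 8L, n = 300L, basis = basis_config(n_harmonics = 5L),
                   covariate_seed = seed,
                   data_seeds = seed + c(D0 = 1L, D1 = 2L, D2 = 3L, D3 = 4L))
}

external_data_path <- function(file) {
  # Location where the reference repository CSVs can be placed to enable the
  # published-value checks; they are network downloads and are not bundled.
  file.path(system.file("extdata", package = "intlik"), "external", file)
}
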