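# Parameter-space descriptors for the SMC engine. A space bundles, for one
# model/mode, the dimension and coordinate names, a prior sampler, a
# vectorised prior log-density, a vectorised log likelihood, and the map back
# to natural-scale variance coordinates. Variance components are sampled on
# the log scale (the prior density includes the Jacobian); correlations stay
# on their natural scale with out-of-range proposals assigned -Inf prior
# density, i.e. rejected.

# Coordinate transforms for the variance block of each model kind.
variance_coords <- function(spec) {
  kind <- spec$kind
  if (kind %in% c("linear", "linear_nig")) {
    ig <- if (kind == "linear") spec$variance_priors$sigma2 else invgamma_prior(spec$coef_prior$shape, spec$coef_prior$scale)
    list(
      names = "sigma2",
      sample = function(n) matrix(log(rinvgamma(n, ig$shape, ig$scale)), ncol = 1L),
      log_prior = function(theta) dinvgamma(exp(theta[, 1L]), ig$shape, ig$scale, log = TRUE) + theta[, 1L],
      natural = function(theta) {
        out <- exp(theta)
        colnames(out) <- "sigma2"
        out
      }
    )
  } else if (kind == "multilevel_intercept") {
    py <- spec$variance_priors$sigma2_y
    pe <- spec$variance_priors$sigma2_eta
    list(
      names = c("sigma2_y", "sigma2_eta"),
      sample = function(n) cbind(log(rinvgamma(n, py$shape, py$scale)),
                                 log(rinvgamma(n, pe$shape, pe$scale))),
      log_prior = function(theta) {
        dinvgamma(exp(theta[, 1L]), py$shape, py$scale, log = TRUE) + theta[, 1L] +
          dinvgamma(exp(theta[, 2L]), pe$shape, pe$scale, log = TRUE) + theta[, 2L]
      },
      natural = function(theta) {
        out <- exp(theta)
        colnames(out) <- c("sigma2_y", "sigma2_eta")
        out
      }
    )
  } else {
    st <- spec$structure
    py <- spec$variance_priors$sigma2_y
    nu_p <- spec$variance_priors$nu
    nv <- st$n_var
    rho_free <- st$rho_free
    rp <- st$rho_prior
    nm <- c("sigma2_y", st$param_names)
    list(
      names = nm,
      sample = function(n) {
        out <- matrix(0, n, 1L + st$n_par)
        out[, 1L] <- log(rinvgamma(n, py$shape, py$scale))
        for (i in seq_len(nv)) {
          out[, 1L + i] <- log(rinvgamma(n, nu_p[[i]]$shape, nu_p[[i]]$scale))
        }
        if (rho_free) out[, ncol(out)] <- rtruncnorm(n, rp$mean %||% 0, rp$sd %||% 1)
        out
      },
      log_prior = function(theta) {
        lp <- dinvgamma(exp(theta[, 1L]), py$shape, py$scale, log = TRUE) + theta[, 1L]
        for (i in seq_len(nv)) {
          lp <- lp + dinvgamma(exp(theta[, 1L + i]), nu_p[[i]]$shape, nu_p[[i]]$scale, log = TRUE) +
            theta[, 1L + i]
        }
        if (rho_free) {
          lp <- lp + dtruncnorm_log(theta[, ncol(theta)], rp$mean %||% 0, rp$sd %||% 1)
        }
        lp
      },
      natural = function(theta) {
        out <- theta
        out[, seq_len(1L + nv)] <- exp(theta[, seq_len(1L + nv), drop = FALSE])
        colnames(out) <- nm
        out
      }
    )
  }
}

# Build the sampling space for one (design, spec, mode).
build_param_space <- function(design, spec, mode = c("integrated", "full"),
                              stats = NULL) {
  mode <- match.arg(mode)
  check_spec_design(spec, design)
  if (is.null(stats)) stats <- sufficient_stats(design)
  vc <- variance_coords(spec)
  kind <- spec$kind
  cp <- spec$coef_prior

  if (mode == "integrated") {
    ll <- switch(kind,
      linear = function(theta) loglik_integrated_linear(stats, cp, exp(theta[, 1L])),
      linear_nig = function(theta) loglik_integrated_nig(stats, cp, exp(theta[, 1L])),
      multilevel_intercept = function(theta) {
        loglik_integrated_ml_intercept(stats, cp, exp(theta[, 1L]), exp(theta[, 2L]))
      },
      multilevel_general = function(theta) {
        nu <- theta[, -1L, drop = FALSE]
        nv <- spec$structure$n_var
        nu[, seq_len(nv)] <- exp(nu[, seq_len(nv), drop = FALSE])
        loglik_integrated_ml_general(stats, cp, spec$structure, exp(theta[, 1L]), nu)
      })
    return(list(
      dim = length(vc$names), names = vc$names, mode = mode,
      sample = vc$sample, log_prior = vc$log_prior, log_lik = ll,
      natural = vc$natural, stats = stats
    ))
  }

  # Full mode: coordinates are (beta, eta, variance block). The data term is
  # tempered; the eta level-two density belongs to the prior so that the
  # stage-0 particles are genuine prior draws.
  d <- design$d
  m <- if (kind == "multilevel_general") design$m else if (kind == "multilevel_intercept") 1L else 0L
  J <- if (m > 0L) design$J else 0L
  nv <- length(vc$names)
  dim_total <- d + J * m + nv
  beta_idx <- seq_len(d)
  eta_idx <- if (m > 0L) d + seq_len(J * m) else integer(0)
  var_idx <- d + J * m + seq_len(nv)
  Zmat <- if (m > 0L) (if (kind == "multilevel_intercept") matrix(1, design$n, 1L) else design$Z) else matrix(0, 0, 0)
  names_all <- c(paste0("beta", seq_len(d)),
                 if (m > 0L) paste0("eta", rep(seq_len(J), each = m), "_", rep(seq_len(m), J)),
                 vc$names)

  sample_eta <- function(vtheta) {
    # vtheta: n x nv matrix of variance coords (transformed scale)
    n <- nrow(vtheta)
    if (m == 0L) return(matrix(0, n, 0L))
    out <- matrix(0, n, J * m)
    if (kind == "multilevel_intercept") {
      se <- sqrt(exp(vtheta[, 2L]))
      out <- matrix(rnorm(n * J), n, J) * se
    } else {
      nvv <- spec$structure$n_var
      for (i in seq_len(n)) {
        nu <- vtheta[i, -1L]
        nu[seq_len(nvv)] <- exp(nu[seq_len(nvv)])
        cpm <- cov_from_param(spec$structure, nu)
        ch <- chol(cpm$sigma)
        out[i, ] <- as.numeric(t(matrix(rnorm(J * m), J, m) %*% ch))
      }
    }
    out
  }

  log_prior_eta <- function(eta, vtheta) {
    n <- nrow(vtheta)
    if (m == 0L) return(rep(0, n))
    if (kind == "multilevel_intercept") {
      s2e <- exp(vtheta[, 2L])
      return(-0.5 * (J * log(2 * pi * s2e) + rowSums(eta^2) / s2e))
    }
    nvv <- spec$structure$n_var
    lp <- numeric(n)
    for (i in seq_len(n)) {
      nu <- vtheta[i, -1L]
      nu[seq_len(nvv)] <- exp(nu[seq_len(nvv)])
      cpm <- cov_from_param(spec$structure, nu)
      ch <- tryCatch(chol(cpm$sigma), error = function(e) NULL)
      if (!cpm$valid || is.null(ch)) { lp[i] <- -Inf; next }
      em <- matrix(eta[i, ], J, m, byrow = TRUE)
      z <- backsolve(ch, t(em), transpose = TRUE)
      lp[i] <- -J * (0.5 * m * log(2 * pi) + sum(log(diag(ch)))) - 0.5 * sum(z^2)
    }
    lp
  }

  log_prior_beta <- function(beta, vtheta) {
    n <- nrow(beta)
    if (kind == "linear_nig") {
      s2 <- exp(vtheta[, 1L])
      g <- cp$gamma * s2
      ctr <- sweep(beta, 2L, cp$mean)
      z <- ctr %*% backsolve(cp$chol, diag(d))  # beta' Sigma^-1 beta via chol
      quad <- rowSums(z^2)
      return(-0.5 * (d * log(2 * pi) + d * log(g) + cp$logdet + quad / g))
    }
    ctr <- sweep(beta, 2L, cp$mean)
    z <- ctr %*% backsolve(cp$chol, diag(d))
    rep(-0.5 * (d * log(2 * pi) + cp$logdet), n) - 0.5 * rowSums(z^2)
  }

  list(
    dim = dim_total, names = names_all, mode = mode,
    sample = function(n) {
      vtheta <- vc$sample(n)
      beta <- if (kind == "linear_nig") {
        s2 <- exp(vtheta[, 1L])
        base <- matrix(rnorm(n * d), n, d) %*% cp$chol
        sweep(base * sqrt(cp$gamma * s2), 2L, cp$mean, `+`)
      } else {
        sweep(matrix(rnorm(n * d), n, d) %*% cp$chol, 2L, cp$mean, `+`)
      }
      cbind(beta, sample_eta(vtheta), vtheta)
    },
    log_prior = function(theta) {
      vtheta <- theta[, var_idx, drop = FALSE]
      lp <- vc$log_prior(vtheta) +
        log_prior_beta(theta[, beta_idx, drop = FALSE], vtheta)
      if (m > 0L) lp <- lp + log_prior_eta(theta[, eta_idx, drop = FALSE], vtheta)
      lp
    },
    log_lik = function(theta) {
      s2y <- exp(theta[, var_idx[1L]])
      as.numeric(cpp_ll_full_data(
        design$X, design$y, as.integer(design$group), Zmat,
        theta[, beta_idx, drop = FALSE],
        if (m > 0L) theta[, eta_idx, drop = FALSE] else matrix(0, nrow(theta), 0L),
        m, s2y))
    },
    natural = function(theta) {
      out <- theta
      vn <- vc$natural(theta[, var_idx, drop = FALSE])
      out[, var_idx] <- vn
      colnames(out) <- names_all
      out
    },
    beta_idx = beta_idx,
    stats = stats
  )
}
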