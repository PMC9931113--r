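test_that("smc_config validates its fields", {
  expect_error(smc_config(n_particles = 1), "n_particles")
  expect_error(smc_config(ess_threshold = 1.2), "ess_threshold")
  expect_equal(smc_config(mode = "full")$mode, "full")
})

test_that("a constant likelihood yields log evidence exactly 0 in a single stage", {
  cfg <- smc_config(n_particles = 100, n_runs = 2, seed = 4)
  out <- run_smc(
    sample_prior = function(n) matrix(rnorm(n), ncol = 1),
    log_prior = function(theta) dnorm(theta[, 1], log = TRUE),
    log_lik = function(theta) rep(0, nrow(theta)),
    config = cfg
  )
  expect_identical(out$log_evidence, c(0, 0))
  expect_equal(out$diagnostics[[1]]$stages, 1L)
})

test_that("1-D evidence matches quadrature: IG(3,1) prior, N(0, sigma2) likelihood of 10 fixed values", {
  set.seed(12)
  yv <- round(rnorm(10, 0, 1.2), 3)
  loglik_fun <- function(s2) {
    vapply(s2, function(s) sum(dnorm(yv, 0, sqrt(s), log = TRUE)), numeric(1))
  }
  f <- function(s2) exp(loglik_fun(s2) + dinvgamma(s2, 3, 1, log = TRUE) + 16)
  quad <- log(stats::integrate(f, 0, Inf, rel.tol = 1e-11)$value) - 16
  cfg <- smc_config(n_particles = 500, n_runs = 6, seed = 8)
  out <- run_smc(
    sample_prior = function(n) matrix(log(rinvgamma(n, 3, 1)), ncol = 1),
    log_prior = function(theta) dinvgamma(exp(theta[, 1]), 3, 1, log = TRUE) + theta[, 1],
    log_lik = function(theta) loglik_fun(exp(theta[, 1])),
    config = cfg
  )
  expect_lt(abs(mean(out$log_evidence) - quad), 3 * sd(out$log_evidence))
})

test_that("estimate_evidence is bit-identical under the same seed and dispatches analytically for NIG", {
  fx <- nig_fixture(n = 60, d = 3)
  cfg <- smc_config(n_particles = 200, n_runs = 3, seed = 5)
  e1 <- estimate_evidence(fx$design, fx$spec, cfg, method = "smc")
  e2 <- estimate_evidence(fx$design, fx$spec, cfg, method = "smc")
  expect_identical(e1$runs, e2$runs)
  expect_identical(e1$trace, e2$trace)

  ea <- estimate_evidence(fx$design, fx$spec, cfg)  # auto -> analytic
  expect_equal(ea$method, "analytic")
  expect_equal(ea$sd, 0)
  expect_equal(ea$log_evidence,
               log_evidence_nig(sufficient_stats(fx$design), fx$spec$coef_prior))
  # SMC brackets the analytic value
  expect_lt(abs(e1$log_evidence - ea$log_evidence), 3 * max(e1$sd, 0.05))
})

test_that("tempering exponents increase strictly to exactly 1 and diagnostics are recorded", {
  fx <- nig_fixture(n = 80, d = 3)
  cfg <- smc_config(n_particles = 200, n_runs = 2, seed = 9)
  est <- estimate_evidence(fx$design, fx$spec, cfg, method = "smc")
  for (dg in est$diagnostics) {
    expect_identical(dg$betas[length(dg$betas)], 1)
    expect_true(all(diff(dg$betas) > 0))
    expect_true(all(dg$acceptance >= 0 & dg$acceptance <= 1))
    expect_equal(length(dg$ess), dg$stages)
  }
  expect_true(all(c("sigma2") %in% colnames(est$trace)))
})

test_that("integrated-mode evidence for a multilevel model matches the full mode within Monte-Carlo spread", {
  set.seed(33)
  n <- 80; J <- 4
  X <- cbind(1, rnorm(n)); g <- rep(1:J, length.out = n)
  y <- 0.3 + 0.5 * X[, 2] + rnorm(J, 0, 0.4)[g] + rnorm(n, 0, 0.6)
  des <- grouped_design(y, X, group = g)
  sp <- model_spec("multilevel_intercept", gaussian_prior(0, diag(2)),
                   list(sigma2_y = invgamma_prior(3, 1), sigma2_eta = invgamma_prior(3, 0.3)))
  ei <- estimate_evidence(des, sp, smc_config(300, 4, seed = 2))
  ef <- estimate_evidence(des, sp, smc_config(300, 4, seed = 2, mode = "full"))
  expect_lt(abs(ei$log_evidence - ef$log_evidence), 3 * sqrt(ei$sd^2 + ef$sd^2))
  # the headline variance-reduction pattern
  expect_lte(ei$sd, ef$sd)
  # full-mode trace carries coefficient draws
  expect_equal(ncol(coefficient_draws(ef)), 2L)
  expect_equal(ncol(coefficient_draws(ei)), 0L)
})

test_that("all-zero-likelihood inputs fail with a diagnostic rather than returning a value", {
  cfg <- smc_config(n_particles = 50, n_runs = 1, seed = 1)
  expect_error(
    run_smc(function(n) matrix(rnorm(n), ncol = 1),
            function(theta) rep(0, nrow(theta)),
            function(theta) rep(-Inf, nrow(theta)),
            cfg),
    "zero likelihood")
})

test_that("bayes_factor is the evidence difference, antisymmetric, and banded", {
  fx <- nig_fixture(n = 50, d = 2, seed = 77)
  cfg <- smc_config(n_particles = 100, n_runs = 2, seed = 3)
  e1 <- estimate_evidence(fx$design, fx$spec, cfg)
  bf0 <- bayes_factor(e1, e1)
  expect_equal(bf0$log_bf, 0)
  expect_equal(bf0$label, "not worth more than a bare mention")
  expect_equal(bf0$favoured, 0L)

  sp2 <- model_spec("linear", gaussian_prior(0, diag(2)),
                    list(sigma2 = invgamma_prior(3, 5)), name = "wide")
  e2 <- estimate_evidence(fx$design, sp2, smc_config(200, 2, seed = 3))
  b12 <- bayes_factor(e1, e2)
  b21 <- bayes_factor(e2, e1)
  expect_equal(b12$log_bf, -b21$log_bf)
  expect_equal(b12$log_bf, e1$log_evidence - e2$log_evidence)
  if (2 * abs(b12$log_bf) > 10) expect_equal(b12$label, "very strong")
})
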