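# All radon-pipeline tests run on the synthetic radon-like generator, which
# reproduces the survey's shape (919 measurements, 85 counties, group sizes
# 1..116, ~83% basement) without the external data.

radon_fixture <- function(seed = 1L) {
  path <- file.path(tempdir(), sprintf("synthetic_radon_%d.csv", seed))
  synthetic_radon(seed = seed, path = path)
  load_radon(path)
}

test_that("loader standardises the outcome and reports the survey descriptives", {
  rad <- radon_fixture()
  expect_equal(rad$summary$n, 919L)
  expect_equal(rad$summary$J, 85L)
  expect_equal(rad$summary$max_group_size, 116L)
  expect_equal(rad$summary$min_group_size, 1L)
  expect_gt(rad$summary$basement_fraction, 0.75)
  expect_lt(abs(mean(rad$table$y)), 1e-12)
  expect_equal(sd(rad$table$y), 1, tolerance = 1e-12)
  # county-level uranium standardised across counties
  v_by_county <- tapply(rad$table$v, rad$table$county, unique)
  expect_lt(abs(mean(v_by_county)), 1e-10)
  expect_equal(sd(v_by_county), 1, tolerance = 1e-10)
})

test_that("loader fails descriptively on missing columns and bad floors", {
  path <- file.path(tempdir(), "bad_radon.csv")
  df <- synthetic_radon(2)
  write.csv(df[, -2], path, row.names = FALSE)
  expect_error(load_radon(path), "floor")
  df2 <- df; df2$floor[1] <- 3
  write.csv(df2, path, row.names = FALSE)
  expect_error(load_radon(path), "basement")
})

test_that("model builders produce the printed design dimensions and priors", {
  rad <- radon_fixture()
  J <- rad$summary$J

  m0 <- build_radon_model("M0", rad$table)
  expect_equal(m0$design$d, 2L)
  expect_equal(m0$spec$kind, "linear")
  # floor encoded as (1 - t, t)
  expect_equal(m0$design$X[, 1] + m0$design$X[, 2], rep(1, 919))

  m1 <- build_radon_model("M1", rad$table)
  expect_equal(m1$design$d, 3L)

  m2 <- build_radon_model("M2", rad$table)
  expect_equal(m2$design$d, J + 2L)

  m3 <- build_radon_model("M3", rad$table)
  n_ff <- length(unique(rad$table$county[rad$table$floor == 1]))
  expect_equal(m3$design$d, J + n_ff)

  m4 <- build_radon_model("M4", rad$table)
  expect_equal(m4$spec$kind, "multilevel_intercept")
  expect_equal(m4$design$d, 3L)

  m5 <- build_radon_model("M5", rad$table)
  expect_equal(m5$spec$kind, "multilevel_general")
  expect_equal(m5$design$m, 2L)
  expect_equal(m5$spec$structure$kind, "pair_correlation")
  expect_true(m5$spec$structure$rho_free)
  expect_equal(m5$spec$variance_priors$sigma2_y$scale, 1)

  expect_error(build_radon_model("M9", rad$table), "M9")
})

test_that("single-level AIC matches the hand-computed least-squares form and rank convention", {
  # intercept-only toy with hand-computable RSS
  y <- c(1, 2, 3, 6)
  des <- grouped_design(y, matrix(1, 4, 1))
  sp <- model_spec("linear", gaussian_prior(0, diag(1)), list(sigma2 = invgamma_prior(3, 1)))
  a <- aic(des, sp)
  rss <- sum((y - 3)^2)
  expect_equal(a$k, 1L)
  expect_equal(a$aic, 2 * 1 + 4 * log(2 * pi * rss / 4) + 4, tolerance = 1e-12)

  # a redundant column is absorbed by the rank (the M2 convention)
  X <- cbind(1, c(1, 0, 1, 0), c(0, 1, 0, 1))  # rank 2
  des2 <- grouped_design(rnorm(4), X)
  sp2 <- model_spec("linear", gaussian_prior(0, diag(3)), list(sigma2 = invgamma_prior(3, 1)))
  expect_equal(aic(des2, sp2)$k, 2L)
})

test_that("multilevel AIC equals a dense-covariance maximisation and ignores row order", {
  set.seed(55)
  n <- 40; J <- 5
  X <- cbind(1, rnorm(n)); g <- rep(1:J, length.out = n)
  y <- 0.5 + 0.3 * X[, 2] + rnorm(J, 0, 0.5)[g] + rnorm(n, 0, 0.4)
  des <- grouped_design(y, X, group = g)
  sp <- model_spec("multilevel_intercept", gaussian_prior(0, diag(2)),
                   list(sigma2_y = invgamma_prior(3, 1), sigma2_eta = invgamma_prior(3, 1)))
  set.seed(1); a <- aic(des, sp)
  expect_equal(a$k, 4L)  # 2 coefficients + 2 variance components

  # dense oracle: optimise the full n x n marginal likelihood directly
  dense_negll <- function(par) {
    V <- diag(exp(par[1]), n) + exp(par[2]) * outer(g, g, "==")
    r <- -0.5 * (determinant(V)$modulus + n * log(2 * pi))
    fit <- solve(V, cbind(y, X))
    bh <- solve(crossprod(X, fit[, -1]), crossprod(X, fit[, 1]))
    res <- y - X %*% bh
    -as.numeric(r - 0.5 * t(res) %*% solve(V, res))
  }
  opt <- optim(c(log(0.2), log(0.2)), dense_negll, method = "BFGS")
  expect_equal(a$loglik, -opt$value, tolerance = 1e-6)

  # row-order invariance
  perm <- sample(n)
  des_p <- grouped_design(y[perm], X[perm, ], group = g[perm])
  set.seed(1); ap <- aic(des_p, sp)
  expect_equal(ap$aic, a$aic, tolerance = 1e-6)

  # general multilevel k convention: coefficients + variances + free rho
  Z <- cbind(1, rnorm(n))
  desg <- grouped_design(y, X, Z = Z, group = g)
  spg <- model_spec("multilevel_general", gaussian_prior(0, diag(2)),
                    list(sigma2_y = invgamma_prior(3, 1),
                         nu = list(invgamma_prior(3, 1), invgamma_prior(3, 1))),
                    structure = cov_structure("pair_correlation", m = 2))
  set.seed(2); ag <- aic(desg, spg)
  expect_equal(ag$k, 2L + 4L)
})

test_that("the comparison table ranks models coherently on synthetic data", {
  rad <- radon_fixture(3)
  res <- radon_table(rad$table, smc_config(n_particles = 200, n_runs = 2, seed = 7),
                     models = c("M0", "M1", "M4"))
  expect_equal(nrow(res), 3L)
  expect_setequal(res$aic_rank, 1:3)
  expect_setequal(res$evidence_rank, 1:3)
  expect_equal(res$k, c(2L, 3L, 5L))
  # the synthetic generator includes uranium and county effects, so the
  # county-aware models beat complete pooling under both criteria
  expect_gt(res$log_evidence[res$model == "M4"], res$log_evidence[res$model == "M0"])
  expect_lt(res$aic[res$model == "M4"], res$aic[res$model == "M0"])
  # single-model invocation
  res1 <- radon_table(rad$table, smc_config(100, 2, seed = 7), models = "M0")
  expect_equal(nrow(res1), 1L)
})
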