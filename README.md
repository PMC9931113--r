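# intlik

Bayesian model selection for single-level and multilevel (hierarchical)
Gaussian linear models via **integrated likelihoods**: regression
coefficients and group-level effects are marginalised in closed form under
conjugate Gaussian priors, so the Monte Carlo estimation of the model
evidence runs only over the one-to-four variance parameters. This makes
evidence estimates markedly more consistent (smaller across-run spread, less
bias) than sampling the full parameter space, especially when the
coefficient dimension is large — the regime where full-likelihood samplers
struggle.

The package is for statisticians and epidemiological modellers comparing
pooling structures on grouped data: should a model have one common intercept,
a varying intercept per group, or varying slopes and intercepts with a
correlated group covariance?

## The models and the core quantity

For data $(y_{ij}, x_{ij}, z_{ij})$ with observation $i$ in group $j$:

* single level: $y_i = \beta^T x_i + \epsilon_i$, $\epsilon_i \sim N(0, \sigma^2)$;
* varying intercept: $y_{ij} = \beta^T x_{ij} + \eta_j + \epsilon_{ij}$,
  $\eta_j \sim N(0, \sigma_\eta^2)$;
* general: $y_{ij} = \beta^T x_{ij} + \eta_j^T z_{ij} + \epsilon_{ij}$,
  $\eta_j \sim N(0, \Sigma_\eta(\nu))$;

with $\beta \sim N(\mu, \Sigma)$ and inverse-gamma priors on the variances.
The model evidence $p(D \mid M) = \int p(D \mid M, \theta)\, p(\theta \mid M)\, d\theta$
is estimated by tempered sequential Monte Carlo over the **integrated
likelihood** $p(D \mid M, \text{variances})$, in which $\beta$ (and $\eta$)
have been integrated out analytically. Models are compared through
$\log \mathrm{BF}_{mn} = \log p(D \mid M_m) - \log p(D \mid M_n)$.
For the fully conjugate normal-inverse-gamma prior
($\beta \mid \sigma^2 \sim N(\mu, \gamma\sigma^2\Sigma)$, $\sigma^2 \sim IG(a,b)$)
the evidence is computed exactly, with no sampling.

Also included: maximum likelihood and AIC for the same model family (with
group effects marginalised and coefficients profiled by GLS), coefficient
posterior recovery from variance traces with Mahalanobis recovery
diagnostics, a simulation-study toolkit (piecewise-linear + Fourier covariate
basis, Dirichlet group sizes, four generators with matching model suite), a
loader/model-builder pipeline for radon-style grouped survey data, and a CLI.

## A worked example

```r
library(intlik)

cfg <- sim_study_config(J = 8, n = 300, basis = basis_config(n_harmonics = 5),
                        covariate_seed = 1L,
                        data_seeds = 1L + c(D0 = 1L, D1 = 2L, D2 = 3L, D3 = 4L))
ds <- generate_dataset("D1", cfg)             # varying-intercept data
suite <- default_model_suite(cfg$basis)       # M0..M3
res <- run_simulation_study(cfg, smc_config(n_particles = 500, n_runs = 4, seed = 1),
                            models = suite, datasets = "D1")
res[order(res$rank), c("model", "log_evidence", "sd", "rank")]
#>  model log_evidence         sd rank
#>     M1    -241.9006 0.06802377    1
#>     M2    -242.3613 0.09130089    2
#>     M0    -257.7792 0.05821081    3
#>     M3    -258.7856 0.00000000    4
```

The generating structure (M1, varying intercept) attains the largest log
evidence; the general multilevel model M2 comes a few tenths of a nat behind
(it nests the truth but pays an Occam penalty for its extra variance
components), and both single-level models trail by ~16 nats. The `sd` column
is the spread across 4 independent SMC runs — M3's evidence is analytic,
hence exactly zero spread.

```r
e1 <- estimate_evidence(ds$design, suite$M1, smc_config(500, 4, seed = 1))
e0 <- estimate_evidence(ds$design, suite$M0, smc_config(500, 4, seed = 1))
bayes_factor(e1, e0)
#> <bayes_factor> log BF(M1 vs M0) = 15.879 (very strong)

st <- sufficient_stats(ds$design)
mahalanobis_integrated(ds$true$b, e1, st, suite$M1)
#> [1] 9.38   # average quadratic-form distance of the true coefficients
```

A radon-style grouped survey runs through `load_radon()`,
`build_radon_model("M0".."M5", ...)`, `aic()` and `radon_table()`; a
synthetic stand-in with the survey's shape is available as
`synthetic_radon()`. The command-line interface (`inst/cli/intlik`) exposes
`simulate`, `evidence`, `aic`, `study`, `radon` and `compare`.

## Design notes

The methods vignette (`vignettes/integrated-evidence.Rmd`) documents the
integrated-likelihood algebra, the SMC design choices (adaptive tempering,
systematic resampling, random-walk mutation, log-scale variance sampling),
the numerical contract (Cholesky everywhere, logged jitter retry, -Inf for
invalid parameter points), what the synthetic generators do and do not
emulate, and the parameter-counting conventions for AIC.
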