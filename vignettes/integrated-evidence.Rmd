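---
title: "Model evidence for multilevel Gaussian linear models via integrated likelihoods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model evidence for multilevel Gaussian linear models via integrated likelihoods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Choosing among competing linear models for grouped (hierarchical) data —
complete pooling, a varying intercept per group, varying slopes with a
correlated group covariance — is naturally framed in Bayesian terms through
the model evidence $p(D \mid M)$, the likelihood integrated over all
parameters with respect to their priors, and through Bayes factors, ratios of
evidences. The evidence integral is analytically available only in the fully
conjugate single-level case; otherwise it must be estimated, typically with
sequential Monte Carlo (SMC). Sampling the full parameter space
$(\beta, \eta, \text{variances})$ becomes unreliable as the coefficient
dimension $d$ and the number of groups $J$ grow: evidence estimates acquire
bias and large run-to-run spread.

`intlik` reduces the sampled space before any Monte Carlo runs. Under a
Gaussian prior $\beta \sim N(\mu, \Sigma)$ the regression coefficients — and,
in multilevel models, the group deviations $\eta_j$ — integrate out in closed
form, leaving an *integrated likelihood* that depends only on the variance
parameters (one to four dimensions for the models here). SMC then bridges
from the variance prior to the variance posterior, and every evaluation of
the target costs one Cholesky factorisation of a $d \times d$ precision
matrix plus $J$ factorisations of $m \times m$ per-group precisions.

## The three integrated likelihoods

All three forms are pure functions of precomputed data summaries
("sufficient statistics": $\sum_i x_i x_i^T$, $\sum_i x_i y_i$, $\sum_i y_i^2$
and their per-group analogues), computed once by `sufficient_stats()`.

**Single level.** For $y_i = \beta^T x_i + \epsilon_i$,
$\epsilon_i \sim N(0, \sigma^2)$, the conditional coefficient posterior is
Gaussian with precision $\tilde\Sigma^{-1} = \Sigma^{-1} + \sigma^{-2}\sum_i x_i x_i^T$
and mean $\tilde\mu = \tilde\Sigma(\Sigma^{-1}\mu + \sigma^{-2}\sum_i x_i y_i)$, and

$$\log p(D \mid M, \sigma^2) = -\tfrac12\Big(\log|\tilde\Sigma^{-1}| + \log|\Sigma|
 + n\log 2\pi\sigma^2 + \mu^T\Sigma^{-1}\mu + \sigma^{-2}\textstyle\sum_i y_i^2
 - \tilde\mu^T\tilde\Sigma^{-1}\tilde\mu\Big).$$

**Varying intercept.** With $y_{ij} = \beta^T x_{ij} + \eta_j + \epsilon_{ij}$,
$\eta_j \sim N(0, \sigma_\eta^2)$, integrating each $\eta_j$ contributes a
factor $\big(\sigma_y^2/(\sigma_y^2 + n_j\sigma_\eta^2)\big)^{1/2}$ per group
and a per-group correction proportional to $(\sum_i y_{ij})^2$; the
conditional precision acquires the rank-one group deflations
$-\sigma_y^{-2} w_j (\sum_i x_{ij})(\sum_i x_{ij})^T$ with
$w_j = \sigma_\eta^2/(\sigma_y^2 + n_j\sigma_\eta^2)$. Setting
$\sigma_\eta^2 = 0$ recovers the single-level expression exactly (a tested
identity, not an approximation).

**General group effects.** With $m$-dimensional deviations
$\eta_j \sim N(0, \Sigma_\eta(\nu))$ on group-varying covariates $z_{ij}$, each
group contributes the conditional precision
$\hat\Sigma_{\eta,j}^{-1} = \Sigma_\eta^{-1} + \sigma_y^{-2}\sum_i z_{ij} z_{ij}^T$,
whose log-determinants and quadratic forms enter the likelihood along with
$J \log |\Sigma_\eta|$. With $m = 1$, $z \equiv 1$ this reduces to the varying-
intercept form to $10^{-10}$.

**Conjugate case.** Under the joint normal-inverse-gamma prior
$\sigma^2 \sim IG(a, b)$, $\beta \mid \sigma^2 \sim N(\mu, \gamma\sigma^2\Sigma)$,
the evidence is fully analytic (`log_evidence_nig()`), which provides both a
fast dispatch path and the calibration oracle for the SMC engine. The
integrated likelihood in this case is the single-level formula evaluated at
the coefficient covariance $\gamma\sigma^2\Sigma$; the package treats that
substitution as the defining identity and verifies it in the tests, so the
two printed forms of the conjugate integrated likelihood cannot drift apart.

## Sequential Monte Carlo choices

The evidence is estimated by tempered (static) SMC: particles start at the
prior, and stage $k$ targets prior $\times$ likelihood$^{\beta_k}$ with
$0 = \beta_0 < \dots < \beta_K = 1$. The design decisions, all standard, are:

* **Adaptive tempering.** The next exponent is found by bisection so the
  relative effective sample size of the incremental weights is approximately
  `ess_threshold` (default 0.5); the final step is clamped to exactly 1.
* **Systematic resampling at every stage**, so ESS returns to the particle
  count after each stage.
* **Mutation**: `mh_steps` (default 5) random-walk Metropolis sweeps with
  proposal covariance $2.38^2/\text{dim}$ times the empirical particle
  covariance, floored by a small diagonal.
* **Transformations.** Variance components are sampled as logarithms (the
  prior density carries the Jacobian); correlations stay on their natural
  scale and out-of-range or non-positive-definite proposals receive prior
  density $-\infty$, i.e. are rejected rather than raised as errors.
* **Seeds.** One master seed spawns per-run streams deterministically, so
  `estimate_evidence()` is bit-reproducible and reports a mean and an
  across-run standard deviation over `n_runs` (default 8) independent runs.
* **Full mode.** The identical engine can sample
  $(\beta, \eta, \text{variances})$ against the unintegrated likelihood (the
  group-effect density stays in the prior so stage-0 particles are genuine
  prior draws). It exists for the bias/variance comparison with the
  integrated mode and shares every engine default, making the comparison
  fair.

Numerical contract: every log-determinant and quadratic form goes through a
Cholesky factorisation of a precision matrix; explicit inverses are avoided
in all likelihood paths. A factorisation that fails is retried once with a
relative jitter of $10^{-10}\,\mathrm{tr}(P)/d$ (counted, and surfaced by the
compiled kernels); a point that still fails is treated as zero-probability.
Invalid variance points return $-\infty$ rather than raising, which is the
convention samplers need.

## Coefficient recovery diagnostics

From an integrated-mode variance trace the coefficient posterior is recovered
by averaging the conditional posteriors: the pooled mean averages
$\tilde\mu(\sigma^2_{(s)})$, and the distance diagnostic is the average
quadratic form

$$d_{M,i}(b) = \frac1N \sum_s \big(b - \tilde\mu_{(s)}\big)^T \tilde\Sigma^{-1}_{(s)} \big(b - \tilde\mu_{(s)}\big),$$

which is the canonical output (it matches the definition used for the
reference tables). A pooled-covariance alternative is available and clearly
labelled: `pooled_beta_posterior()` offers the plain average of conditional
covariances (`"average"`) and the law-of-total-variance form adding the
between-draw spread of the conditional means (`"total"`); which variant
produced a given summary is recorded in the object, since the averaging
definition alone omits between-draw mean variability. For full-mode traces
the distance is the ordinary Mahalanobis form under the sample mean and
$1/(N-1)$-normalised sample covariance of the coefficient draws.

## What the synthetic generator emulates

The simulation study turns a scalar time $t \sim U[0,1]$ into covariates
through a piecewise-linear-plus-Fourier basis (five hinges at
$0, 0.2, \dots, 0.8$; twenty harmonic pairs; $d = 46$ at defaults), with
group membership drawn from Dirichlet$(2, \dots, J{+}1)$ weights so group
sizes are systematically unequal ($J = 15$, $n = 1000$ at defaults). Four
generators share one covariate draw and differ in their outcome process:
single level (D0), varying intercept (D1), correlated varying slopes with a
banded $4 \times 4$ group covariance and $\rho = 0.2$ (D2), and the conjugate
prior coupling $b \mid s^2 \sim N(0, 5 s^2 S)$ (D3). True coefficients are
drawn from a block covariance $S$ whose $6 \times 6$ piecewise block allows
large changes in segment gradients while the Fourier block is shrunk to
$0.001 I$; model priors use the diagonal of $S$. Noise variances are drawn
from inverse-gamma priors whose means make
$E[\mathrm{var}(y - b^T x)] = 0.2$ for every generator — a calibration that
keeps prior mismatch from dominating structure when models are compared
across datasets, and the quantity the acceptance script recomputes.

What the generator does **not** emulate: real covariate collinearity,
non-Gaussian noise, missingness, or group sizes of one to a hundred-plus as
in survey data (the synthetic radon-like generator covers that shape
separately). Passing tests therefore demonstrate internal consistency of the
method under its own assumptions, not robustness to their violation.

Two transcription choices are worth recording. The banded group covariance
is realised exactly as specified for the study: component 1 independent,
adjacent pairs $(2,3), (3,4)$ sharing one $\rho$ — four variance components
with $IG(3, 0.1)$ priors. And the Dirichlet parameterisation is taken as
authoritative for the group weights, giving $E[p_j] = (j{+}1)/\sum_k (k{+}1)$.

## Problem sizes used by the test-suite studies

The shipped studies run at a reduced scale chosen so a complete
dataset-by-model evidence table with both modes remains a desk-scale
computation: $n = 300$, $J = 8$, five harmonic pairs ($d = 16$), 500
particles, 4 runs, replicated over 8 data-plus-sampler seeds. At this scale
the variance-reduction claim (integrated-mode across-run spread below
full-mode spread for the multilevel models) reproduces robustly — typically
by one to two orders of magnitude — and the coefficient-recovery pattern
(integrated distance below full distance) holds in 8 of 8 replicates.

Model *recovery*, by contrast, is genuinely marginal at reduced scale, and
the suite reports it honestly rather than tuning it green. Two effects are at
work. First, the single-level pair M0/M3 differ only through the
prior coupling between $b$ and $s^2$; their evidences on any single-level
dataset differ by hundredths of a nat (the reference full-scale table
separates them by 0.02), so which of the two tops a D0 or D3 column is close
to a coin flip at any sample size. Second, the group-effect variances are
drawn from $IG(3, 0.1)$ (mean 0.05), so with 8 groups and 300 observations
some replicates carry almost no group signal and the multilevel dataset is
best explained by a smaller model. Quadrature cross-checks confirm these are
true properties of the evidence surface, not sampler error.

## Case-study conventions (radon-style pipeline)

The survey loader standardises the log outcome to mean 0, sd 1 across
measurements and standardises the log county-level covariate across the
county values (the transform applied is recorded in the loader's summary
output). The floor indicator enters every design as the pair $(1-t, t)$
rather than an intercept plus slope, so the prior expresses equal uncertainty
for basement and first-floor measurements. The unpooled-intercept model keeps
the printed design — county indicators plus both floor columns — for the
Bayesian fit, where the $N(0, I)$ prior regularises the redundant direction;
the maximum-likelihood fit absorbs the redundancy through rank detection, so
its parameter count is the design rank (86 for 85 counties plus two floor
columns). AIC follows the convention that single-level models count only the
identifiable regression coefficients while multilevel models count
coefficients plus variance components (including a free correlation). The
multilevel maximum likelihood profiles $\beta$ by generalised least squares
per group and optimises the variance components on the log scale
($\tanh^{-1}$ for the correlation) from several restarts.

## Known limitations

* Gaussian likelihoods with identity link only; no heteroscedastic
  individual-level noise; at most two levels of nesting.
* The analytic-evidence path exists only for the conjugate single-level
  prior; all other evidences are SMC estimates whose across-run spread should
  always be inspected (it is part of every result object).
* The full-likelihood mode is a comparison baseline, not a recommended
  estimator: in higher-dimensional models its estimates are visibly biased
  and widely spread, which is precisely the behaviour the integrated mode is
  designed to remove.
* Evidence values depend on the prior specification by construction;
  comparing models only makes sense with priors chosen before seeing the
  comparison.

## A worked example

```{r, eval = FALSE}
library(intlik)

cfg <- sim_study_config(J = 8, n = 300, basis = basis_config(n_harmonics = 5),
                        covariate_seed = 1L,
                        data_seeds = 1L + c(D0 = 1L, D1 = 2L, D2 = 3L, D3 = 4L))
ds <- generate_dataset("D1", cfg)
suite <- default_model_suite(cfg$basis)
res <- run_simulation_study(cfg, smc_config(n_particles = 500, n_runs = 4, seed = 1),
                            models = suite, datasets = "D1")
res[order(res$rank), c("model", "log_evidence", "sd", "rank")]
```

The varying-intercept model should attain rank 1 on its own dataset, with the
single-level models several nats behind; the Bayes factor between the top two
rows is their evidence difference.
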