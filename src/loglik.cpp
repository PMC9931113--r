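// Vectorised integrated / full log-likelihood kernels. Each function
// evaluates a closed-form log likelihood at a vector of variance-parameter
// points, using Cholesky factorisations throughout (no explicit inverses of
// the d x d precision). A failed factorisation is retried once with a small
// relative jitter (1e-10 * trace / dim); points that still fail, and points
// flagged invalid, return -Inf. The number of jitter retries is returned as
// an attribute so callers can log it.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);
static const double NEGINF = -std::numeric_limits<double>::infinity();

// Lower Cholesky with one jitter retry; returns false if it still fails.
static bool chol_lower(mat& L, const mat& P, int& jitter) {
  if (chol(L, P, "lower")) return true;
  double eps = 1e-10 * trace(P) / P.n_rows;
  if (chol(L, P + eps * eye<mat>(P.n_rows, P.n_rows), "lower")) {
    ++jitter;
    return true;
  }
  return false;
}

// Core: -0.5 * (logdet(P) + logdet_prior + const_term - b' P^-1 b)
// where P is the conditional precision and b its linear term.
static double finish_ll(const mat& P, const vec& b, double logdet_prior,
                        double const_term, int& jitter) {
  mat L;
  if (!chol_lower(L, P, jitter)) return NEGINF;
  vec z = solve(trimatl(L), b);
  double logdetP = 2.0 * sum(log(L.diag()));
  return -0.5 * (logdetP + logdet_prior + const_term - dot(z, z));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_ll_linear(const arma::mat& Sxx, const arma::vec& Sxy,
                                  double Syy, double n, const arma::vec& mu,
                                  const arma::mat& prior_prec, double logdet_prior,
                                  const arma::vec& sigma2) {
  int k = sigma2.n_elem, jitter = 0;
  vec pm = prior_prec * mu;
  double mu_quad = dot(mu, pm);
  Rcpp::NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    double s2 = sigma2[i];
    if (!(std::isfinite(s2) && s2 > 0.0)) { out[i] = NEGINF; continue; }
    mat P = prior_prec + Sxx / s2;
    vec b = pm + Sxy / s2;
    double cterm = n * (LOG2PI + std::log(s2)) + mu_quad + Syy / s2;
    out[i] = finish_ll(P, b, logdet_prior, cterm, jitter);
  }
  out.attr("jitter") = jitter;
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_ll_nig(const arma::mat& Sxx, const arma::vec& Sxy,
                               double Syy, double n, const arma::vec& mu,
                               const arma::mat& prior_prec, double logdet_prior,
                               double gamma, const arma::vec& sigma2) {
  int k = sigma2.n_elem, jitter = 0;
  int d = mu.n_elem;
  vec pm = prior_prec * mu;
  double mu_quad = dot(mu, pm);
  Rcpp::NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    double s2 = sigma2[i];
    if (!(std::isfinite(s2) && s2 > 0.0)) { out[i] = NEGINF; continue; }
    double g = gamma * s2;  // coefficient covariance is g * Sigma
    mat P = prior_prec / g + Sxx / s2;
    vec b = pm / g + Sxy / s2;
    double cterm = n * (LOG2PI + std::log(s2)) + mu_quad / g + Syy / s2;
    out[i] = finish_ll(P, b, logdet_prior + d * std::log(g), cterm, jitter);
  }
  out.attr("jitter") = jitter;
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_ll_ml_intercept(const arma::mat& Sxx, const arma::vec& Sxy,
                                        double Syy, const arma::mat& gx,
                                        const arma::vec& gy, const arma::vec& nj,
                                        double n, const arma::vec& mu,
                                        const arma::mat& prior_prec, double logdet_prior,
                                        const arma::vec& s2y, const arma::vec& s2e) {
  int k = s2y.n_elem, jitter = 0;
  int J = gy.n_elem;
  vec pm = prior_prec * mu;
  double mu_quad = dot(mu, pm);
  Rcpp::NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    double sy = s2y[i], se = s2e[i];
    if (!(std::isfinite(sy) && sy > 0.0) || !(std::isfinite(se) && se >= 0.0)) {
      out[i] = NEGINF; continue;
    }
    mat P = prior_prec + Sxx / sy;
    vec b = pm + Sxy / sy;
    double extra = 0.0, ycorr = 0.0;
    for (int j = 0; j < J; ++j) {
      double w = se / (sy + nj[j] * se);
      if (w > 0.0) {
        P -= (w / sy) * (gx.col(j) * gx.col(j).t());
        b -= (w / sy) * gy[j] * gx.col(j);
        ycorr += w * gy[j] * gy[j];
      }
      extra += std::log1p(nj[j] * se / sy);
    }
    double cterm = n * (LOG2PI + std::log(sy)) + extra + mu_quad + (Syy - ycorr) / sy;
    out[i] = finish_ll(P, b, logdet_prior, cterm, jitter);
  }
  out.attr("jitter") = jitter;
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_ll_ml_general(const arma::mat& Sxx, const arma::vec& Sxy,
                                      double Syy, const arma::cube& Szz,
                                      const arma::mat& Szy, const arma::cube& Sxz,
                                      double n, const arma::vec& mu,
                                      const arma::mat& prior_prec, double logdet_prior,
                                      const arma::vec& s2y, const arma::cube& Sigma_eta,
                                      const Rcpp::LogicalVector& valid) {
  int k = s2y.n_elem, jitter = 0;
  int J = Szy.n_cols;
  vec pm = prior_prec * mu;
  double mu_quad = dot(mu, pm);
  Rcpp::NumericVector out(k);
  for (int i = 0; i < k; ++i) {
    double sy = s2y[i];
    if (!valid[i] || !(std::isfinite(sy) && sy > 0.0)) { out[i] = NEGINF; continue; }
    mat Se = Sigma_eta.slice(i);
    mat Le;
    if (!chol(Le, Se, "lower")) { out[i] = NEGINF; continue; }
    double logdet_Se = 2.0 * sum(log(Le.diag()));
    mat prec_eta = inv_sympd(Se);
    mat P = prior_prec + Sxx / sy;
    vec b = pm + Sxy / sy;
    double sum_logdet_A = 0.0, yterm = 0.0;
    bool ok = true;
    double sy2 = sy * sy;
    for (int j = 0; j < J; ++j) {
      mat A = prec_eta + Szz.slice(j) / sy;
      mat LA;
      if (!chol_lower(LA, A, jitter)) { ok = false; break; }
      sum_logdet_A += 2.0 * sum(log(LA.diag()));
      // W = A^-1 * Sxz_j', V = A^-1 * Szy_j
      mat Wl = solve(trimatl(LA), Sxz.slice(j).t());
      vec vl = solve(trimatl(LA), Szy.col(j));
      P -= (Wl.t() * Wl) / sy2;
      b -= (Wl.t() * vl) / sy2;
      yterm += dot(vl, vl);
    }
    if (!ok) { out[i] = NEGINF; continue; }
    double cterm = n * (LOG2PI + std::log(sy)) + J * logdet_Se + sum_logdet_A +
      mu_quad + Syy / sy - yterm / sy2;
    out[i] = finish_ll(P, b, logdet_prior, cterm, jitter);
  }
  out.attr("jitter") = jitter;
  return out;
}

// Data term of the full (unintegrated) Gaussian log likelihood, vectorised
// over particles. beta is P x d; eta is P x (J*m) laid out group-major
// (columns (j-1)*m + 1 .. j*m hold eta_j), or 0 x 0 when m = 0.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_ll_full_data(const arma::mat& X, const arma::vec& y,
                                     const arma::ivec& group, const arma::mat& Z,
                                     const arma::mat& beta, const arma::mat& eta,
                                     int m, const arma::vec& s2y) {
  int P = beta.n_rows;
  int n = y.n_elem;
  Rcpp::NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    double sy = s2y[p];
    if (!(std::isfinite(sy) && sy > 0.0)) { out[p] = NEGINF; continue; }
    vec r = y - X * beta.row(p).t();
    if (m > 0) {
      for (int i = 0; i < n; ++i) {
        int off = (group[i] - 1) * m;
        double acc = 0.0;
        for (int q = 0; q < m; ++q) acc += Z(i, q) * eta(p, off + q);
        r[i] -= acc;
      }
    }
    out[p] = -0.5 * (n * (LOG2PI + std::log(sy)) + dot(r, r) / sy);
  }
  return out;
}
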