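// Data-augmentation MCMC for multivariate normal imputation.
//
// I-step: for each missingness pattern, the conditional normal of the
// missing block given the observed block is obtained by sweeping the
// augmented moment matrix [[-1, mu'], [mu, Sigma]] on the observed indices;
// missing cells are drawn from that conditional.
// P-step (uniform prior): Sigma ~ inverse-Wishart(n - 1, S) with S the
// completed-data sum of squares about the mean, then mu | Sigma ~
// N(ybar, Sigma / n).
//
// Uses R's RNG throughout so results are reproducible under set.seed().

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

// Beaton sweep of a symmetric matrix on pivot k.
static void sweep_sym(arma::mat& G, arma::uword k) {
  double d = G(k, k);
  if (std::abs(d) < 1e-300) stop("sweep pivot is numerically zero");
  arma::vec col = G.col(k);
  G -= col * col.t() / d;
  G.col(k) = col / d;
  G.row(k) = (col / d).t();
  G(k, k) = -1.0 / d;
}

struct Pattern {
  arma::uvec rows;
  arma::uvec mis;
  arma::uvec obs;
};

static std::vector<Pattern> find_patterns(const arma::mat& Y) {
  const arma::uword n = Y.n_rows, p = Y.n_cols;
  std::map<std::string, std::vector<arma::uword> > groups;
  for (arma::uword i = 0; i < n; ++i) {
    std::string key(p, '0');
    bool any = false;
    for (arma::uword j = 0; j < p; ++j) {
      if (!arma::is_finite(Y(i, j))) { key[j] = '1'; any = true; }
    }
    if (any) groups[key].push_back(i);
  }
  std::vector<Pattern> pats;
  for (std::map<std::string, std::vector<arma::uword> >::iterator it =
         groups.begin(); it != groups.end(); ++it) {
    Pattern pat;
    pat.rows = arma::uvec(it->second);
    std::vector<arma::uword> mis, obs;
    for (arma::uword j = 0; j < p; ++j) {
      if (it->first[j] == '1') mis.push_back(j); else obs.push_back(j);
    }
    pat.mis = arma::uvec(mis);
    pat.obs = arma::uvec(obs);
    pats.push_back(pat);
  }
  return pats;
}

// Augmented moment matrix swept on the observed indices of a pattern.
static arma::mat swept_theta(const arma::vec& mu, const arma::mat& Sigma,
                             const arma::uvec& obs) {
  const arma::uword p = mu.n_elem;
  arma::mat theta(p + 1, p + 1);
  theta(0, 0) = -1.0;
  for (arma::uword j = 0; j < p; ++j) {
    theta(0, j + 1) = mu(j);
    theta(j + 1, 0) = mu(j);
  }
  theta.submat(1, 1, p, p) = Sigma;
  for (arma::uword k = 0; k < obs.n_elem; ++k) sweep_sym(theta, obs(k) + 1);
  return theta;
}

// Draw missing cells from the conditional normal; with draw = false the
// conditional mean is filled in instead (EM E-step) and the per-pattern
// conditional covariance is accumulated into C.
static void i_step(arma::mat& Y, const arma::vec& mu, const arma::mat& Sigma,
                   const std::vector<Pattern>& pats, bool draw,
                   arma::mat* C = 0) {
  const arma::uword p = Y.n_cols;
  for (size_t g = 0; g < pats.size(); ++g) {
    const Pattern& pat = pats[g];
    const arma::uword pm = pat.mis.n_elem;
    arma::mat theta = swept_theta(mu, Sigma, pat.obs);
    // intercepts, slopes, conditional covariance of the missing block
    arma::vec a(pm);
    arma::mat Bcoef(pat.obs.n_elem, pm);
    arma::mat V(pm, pm);
    for (arma::uword j = 0; j < pm; ++j) {
      a(j) = theta(0, pat.mis(j) + 1);
      for (arma::uword o = 0; o < pat.obs.n_elem; ++o)
        Bcoef(o, j) = theta(pat.obs(o) + 1, pat.mis(j) + 1);
      for (arma::uword j2 = 0; j2 < pm; ++j2)
        V(j, j2) = theta(pat.mis(j) + 1, pat.mis(j2) + 1);
    }
    V = 0.5 * (V + V.t());
    arma::mat L;
    if (draw && !arma::chol(L, V, "lower"))
      stop("conditional covariance not positive definite during the I-step");
    if (!draw && C) {
      for (arma::uword j = 0; j < pm; ++j)
        for (arma::uword j2 = 0; j2 < pm; ++j2)
          (*C)(pat.mis(j), pat.mis(j2)) += pat.rows.n_elem * V(j, j2);
    }
    for (arma::uword r = 0; r < pat.rows.n_elem; ++r) {
      const arma::uword i = pat.rows(r);
      arma::vec yobs(pat.obs.n_elem);
      for (arma::uword o = 0; o < pat.obs.n_elem; ++o)
        yobs(o) = Y(i, pat.obs(o));
      arma::vec mcond = a + Bcoef.t() * yobs;
      if (draw) {
        arma::vec z(pm);
        for (arma::uword j = 0; j < pm; ++j) z(j) = norm_rand();
        mcond += L * z;
      }
      for (arma::uword j = 0; j < pm; ++j) Y(i, pat.mis(j)) = mcond(j);
    }
    (void)p;
  }
}

// Draw (mu, Sigma) from the uniform-prior posterior given completed data.
static void p_step(const arma::mat& Y, arma::vec& mu, arma::mat& Sigma) {
  const arma::uword n = Y.n_rows, p = Y.n_cols;
  if (n < p + 2) stop("too few rows for the posterior draw (need n > p + 1)");
  arma::rowvec ybar = arma::mean(Y, 0);
  arma::mat Yc = Y.each_row() - ybar;
  arma::mat S = Yc.t() * Yc;
  arma::mat Ls;
  if (!arma::chol(Ls, S, "lower"))
    stop("singular completed-data covariance; consider ridge inflation or dropping collinear columns");
  const double nu = (double)n - 1.0;
  arma::mat A(p, p, arma::fill::zeros);
  for (arma::uword i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(nu - (double)i));
    for (arma::uword j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat B = arma::solve(arma::trimatl(A), Ls.t());
  Sigma = B.t() * B;
  Sigma = 0.5 * (Sigma + Sigma.t());
  arma::mat Lsig;
  if (!arma::chol(Lsig, Sigma, "lower"))
    stop("posterior covariance draw not positive definite");
  arma::vec z(p);
  for (arma::uword j = 0; j < p; ++j) z(j) = norm_rand();
  mu = ybar.t() + Lsig * z / std::sqrt((double)n);
}

static void moments_init(const arma::mat& Y0, arma::mat& Yfill, arma::vec& mu,
                         arma::mat& Sigma) {
  const arma::uword n = Y0.n_rows, p = Y0.n_cols;
  Yfill = Y0;
  for (arma::uword j = 0; j < p; ++j) {
    double s = 0.0; arma::uword k = 0;
    for (arma::uword i = 0; i < n; ++i)
      if (arma::is_finite(Y0(i, j))) { s += Y0(i, j); ++k; }
    if (k == 0) stop("column fully missing: cannot initialise");
    const double mbar = s / k;
    for (arma::uword i = 0; i < n; ++i)
      if (!arma::is_finite(Yfill(i, j))) Yfill(i, j) = mbar;
  }
  mu = arma::mean(Yfill, 0).t();
  arma::mat Yc = Yfill.each_row() - mu.t();
  Sigma = Yc.t() * Yc / (double)n;
}

// [[Rcpp::export(name = ".da_impute_cpp")]]
List da_impute_cpp(NumericMatrix Ymat, int m, int burn_in, int between,
                   std::string init, int em_maxit, double em_tol) {
  arma::mat Y0(Ymat.begin(), Ymat.nrow(), Ymat.ncol(), true);
  const arma::uword n = Y0.n_rows, p = Y0.n_cols;
  if (m < 2) stop("m must be at least 2");
  if (burn_in < 1 || between < 1) stop("burn_in and between must be >= 1");
  std::vector<Pattern> pats = find_patterns(Y0);

  arma::mat Y;
  arma::vec mu;
  arma::mat Sigma;
  moments_init(Y0, Y, mu, Sigma);

  if (init == "em") {
    for (int it = 0; it < em_maxit; ++it) {
      arma::mat C(p, p, arma::fill::zeros);
      arma::mat Yprev = Y;
      i_step(Y, mu, Sigma, pats, false, &C);
      arma::vec mu_new = arma::mean(Y, 0).t();
      arma::mat Yc = Y.each_row() - mu_new.t();
      arma::mat Sigma_new = (Yc.t() * Yc + C) / (double)n;
      double delta = arma::abs(mu_new - mu).max() +
        arma::abs(Sigma_new - Sigma).max();
      mu = mu_new; Sigma = Sigma_new;
      if (delta < em_tol) break;
    }
  } else if (init != "complete_case_moments" && init != "moments") {
    stop("unknown init method '%s'", init.c_str());
  }

  const int total = burn_in + m * between;
  List datasets(m);
  arma::mat mu_trace(total, p);
  int kept = 0;
  for (int it = 1; it <= total; ++it) {
    i_step(Y, mu, Sigma, pats, true);
    if (it > burn_in && (it - burn_in) % between == 0) {
      datasets[kept++] = wrap(Y);
    }
    p_step(Y, mu, Sigma);
    mu_trace.row(it - 1) = mu.t();
  }
  (void)n;
  return List::create(_["datasets"] = datasets,
                      _["mu_trace"] = wrap(mu_trace),
                      _["n_patterns"] = (int)pats.size());
}
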