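// Forward-filter backward-sampling Gibbs sampler for the phenophase
// state-space model: states x_t = (mu, beta[, gamma]) follow independent
// Gaussian random walks, y_t = F_t' x_t + noise with missing y allowed.
// Variance SDs are updated by univariate slice sampling on the log scale.
// Uses R's RNG so results are reproducible via set.seed().
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// log full-conditional kernel of an SD parameter, theta = log(sigma).
// k: number of Gaussian increments, ss: their sum of squares.
// prior_type 0 = half-normal(scale), 1 = flat on (0, inf).
static double sd_logpost(double theta, double k, double ss, double scale,
                         int prior_type) {
  double sigma = std::exp(theta);
  double lp = -k * theta - ss / (2.0 * sigma * sigma);
  if (prior_type == 0) lp += -(sigma * sigma) / (2.0 * scale * scale);
  lp += theta; // Jacobian
  return lp;
}

// Stepping-out slice sampler (Neal 2003) on theta = log(sigma).
static double slice_sd(double sigma0, double k, double ss, double scale,
                       int prior_type) {
  const double w = 1.0;
  const int m = 50;
  double theta0 = std::log(sigma0);
  double logy = sd_logpost(theta0, k, ss, scale, prior_type) +
                std::log(unif_rand());
  double L = theta0 - w * unif_rand();
  double Rgt = L + w;
  int j = static_cast<int>(std::floor(m * unif_rand()));
  int kk = m - 1 - j;
  while (j-- > 0 && sd_logpost(L, k, ss, scale, prior_type) > logy) L -= w;
  while (kk-- > 0 && sd_logpost(Rgt, k, ss, scale, prior_type) > logy) Rgt += w;
  for (int tries = 0; tries < 1000; ++tries) {
    double theta1 = L + unif_rand() * (Rgt - L);
    if (sd_logpost(theta1, k, ss, scale, prior_type) > logy)
      return std::exp(theta1);
    if (theta1 < theta0) L = theta1; else Rgt = theta1;
  }
  return sigma0; // shrinkage failed to move; keep current value
}

static arma::vec mvn_draw(const arma::vec& mean, arma::mat cov) {
  cov = arma::symmatu(cov);
  // jitter scaled to the covariance magnitude: the diffuse initial state
  // (variance ~1e4) makes smoothing subtractions cancel to ~1e-8 precision
  double scale = std::max(cov.diag().max(), 1e-300);
  cov.diag() += 1e-10 * scale;
  arma::vec z(mean.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  arma::mat Lc;
  if (arma::chol(Lc, cov, "lower")) return mean + Lc * z;
  // fall back to an eigendecomposition with negative eigenvalues clipped
  arma::vec eigval;
  arma::mat eigvec;
  if (!arma::eig_sym(eigval, eigvec, cov))
    stop("propagated covariance is numerically singular");
  eigval.clamp(0.0, arma::datum::inf);
  return mean + eigvec * (arma::sqrt(eigval) % z);
}

// [[Rcpp::export]]
List gibbs_dlm_cpp(const arma::vec& y, const arma::uvec& observed,
                   const arma::mat& X, double initial_sd,
                   const arma::vec& sigma_init, bool fix_sigma,
                   double sigma_scale, int prior_type,
                   int n_iter, int burnin, int thin) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  const int n_keep = (n_iter - burnin) / thin;

  arma::vec sig = sigma_init;          // p process SDs then sigma_phi
  arma::mat states(n, p, arma::fill::zeros);

  arma::cube keep_states(n_keep, n, p);
  arma::mat keep_sigma(n_keep, p + 1);
  arma::mat keep_alpha(n_keep, n);

  arma::mat m(p, n), a(p, n);
  arma::cube C(p, p, n), Rp(p, p, n);

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    // --- FFBS draw of the state path given variances ---
    arma::mat W = arma::diagmat(arma::square(sig.head(p)));
    double v_phi = sig(p) * sig(p);
    for (int t = 0; t < n; ++t) {
      if (t == 0) {
        a.col(0).zeros();
        Rp.slice(0) = arma::eye(p, p) * (initial_sd * initial_sd);
      } else {
        a.col(t) = m.col(t - 1);
        Rp.slice(t) = C.slice(t - 1) + W;
      }
      if (observed(t)) {
        arma::vec Ft = X.row(t).t();
        arma::vec RF = Rp.slice(t) * Ft;
        double Q = arma::dot(Ft, RF) + v_phi;
        if (!std::isfinite(Q) || Q <= 0.0)
          stop("non-finite or non-positive innovation variance at step %d", t + 1);
        arma::vec K = RF / Q;
        m.col(t) = a.col(t) + K * (y(t) - arma::dot(Ft, a.col(t)));
        arma::mat Ct = Rp.slice(t) - K * RF.t();
        C.slice(t) = arma::symmatu(Ct);
      } else {
        m.col(t) = a.col(t);
        C.slice(t) = Rp.slice(t);
      }
    }
    states.row(n - 1) = mvn_draw(m.col(n - 1), C.slice(n - 1)).t();
    for (int t = n - 2; t >= 0; --t) {
      arma::mat Rinv = arma::inv_sympd(arma::symmatu(Rp.slice(t + 1)) +
                                       arma::eye(p, p) * 1e-12);
      arma::mat B = C.slice(t) * Rinv;
      arma::vec h = m.col(t) + B * (states.row(t + 1).t() - a.col(t + 1));
      arma::mat H = C.slice(t) - B * Rp.slice(t + 1) * B.t();
      states.row(t) = mvn_draw(h, H).t();
    }

    // --- slice updates of the SDs given the state path ---
    if (!fix_sigma) {
      for (int j = 0; j < p; ++j) {
        double ss = 0.0;
        for (int t = 1; t < n; ++t) {
          double d = states(t, j) - states(t - 1, j);
          ss += d * d;
        }
        sig(j) = slice_sd(sig(j), n - 1, ss, sigma_scale, prior_type);
      }
      double ss = 0.0;
      double k = 0.0;
      for (int t = 0; t < n; ++t) {
        if (observed(t)) {
          double r = y(t) - arma::dot(X.row(t), states.row(t));
          ss += r * r;
          k += 1.0;
        }
      }
      sig(p) = slice_sd(sig(p), k, ss, sigma_scale, prior_type);
    }

    if (it >= burnin && (it - burnin) % thin == 0 && kept < n_keep) {
      for (int j = 0; j < p; ++j)
        keep_states.slice(j).row(kept) = states.col(j).t();
      keep_sigma.row(kept) = sig.t();
      keep_alpha.row(kept) = arma::sum(X % states, 1).t();
      ++kept;
    }
  }

  return List::create(_["states"] = keep_states,
                      _["sigma"] = keep_sigma,
                      _["alpha"] = keep_alpha);
}
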