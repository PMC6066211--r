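// Gibbs samplers for the two-stage model: (1) latent-Gaussian graphical
// model with an adaptive Bayesian graphical lasso prior informed by a
// prior graph, (2) clique-structured spike-and-slab regression with
// Laplace coefficient priors.  All randomness goes through R's RNG so
// set.seed() on the R side gives bit-reproducible chains.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------
// scalar samplers

// one-sided tail sampler for standard normal truncated to (a, b), a > 0
// (Robert 1995 shifted-exponential rejection)
static double rtail_std(double a, double b) {
  double lambda = 0.5 * (a + std::sqrt(a * a + 4.0));
  for (int it = 0; it < 10000; ++it) {
    double x = a - std::log(unif_rand()) / lambda;
    if (x > b) continue;
    double rho = std::exp(-0.5 * (x - lambda) * (x - lambda));
    if (unif_rand() <= rho) return x;
  }
  return a; // unreachable in practice
}

// N(mu, sd^2) truncated to (lo, hi]
static double rtnorm1(double mu, double sd, double lo, double hi) {
  double a = (lo - mu) / sd, b = (hi - mu) / sd;
  double x;
  if (a > 5.0) {
    x = rtail_std(a, b);
  } else if (b < -5.0) {
    x = -rtail_std(-b, -a);
  } else {
    double pa = (a <= -37.0) ? 0.0 : R::pnorm(a, 0.0, 1.0, 1, 0);
    double pb = (b >= 37.0) ? 1.0 : R::pnorm(b, 0.0, 1.0, 1, 0);
    double p = pa + unif_rand() * (pb - pa);
    if (p <= 0.0) p = 1e-300;
    if (p >= 1.0) p = 1.0 - 1e-16;
    x = R::qnorm(p, 0.0, 1.0, 1, 0);
    if (!std::isfinite(x)) x = (a > 0.0) ? a : ((b < 0.0) ? b : 0.0);
    if (x < a) x = a;
    if (x > b) x = b;
  }
  return mu + sd * x;
}

// inverse-Gaussian(mu, lambda), Michael-Schucany-Haas transform
static double rinvgauss1(double mu, double lambda) {
  if (!std::isfinite(mu) || mu <= 0.0) mu = 1e12;
  double z = norm_rand();
  double zz = z * z;
  double r = mu / (2.0 * lambda);
  double x = mu + mu * zz * r -
             r * std::sqrt(4.0 * mu * lambda * zz + mu * mu * zz * zz);
  if (x <= 0.0 || !std::isfinite(x)) x = 1e-12; // cancellation guard
  double u = unif_rand();
  double out = (u <= mu / (mu + x)) ? x : mu * mu / x;
  if (out < 1e-12) out = 1e-12;
  if (out > 1e12) out = 1e12;
  return out;
}

static double rgamma1(double shape, double rate) {
  return R::rgamma(shape, 1.0 / rate);
}

// ---------------------------------------------------------------------
// stage 1: latent-variable / cutpoint / precision / shrinkage sweeps

// Redraw latent values for ordinal columns from their univariate Gaussian
// full conditionals (mean and variance read off Omega), truncated to the
// cutpoint interval of the observed code.
static void latent_sweep(arma::mat& W, const arma::mat& Omega,
                         const IntegerMatrix& codes,
                         const IntegerVector& ord_cols, const List& cutpoints) {
  int n = W.n_rows;
  for (int jj = 0; jj < ord_cols.size(); ++jj) {
    int j = ord_cols[jj];
    NumericVector cut = cutpoints[jj];
    double ojj = Omega(j, j);
    if (!(ojj > 0.0) || !std::isfinite(ojj))
      stop("non-positive conditional precision: Omega is broken");
    double sd = std::sqrt(1.0 / ojj);
    for (int i = 0; i < n; ++i) {
      double s = arma::dot(Omega.col(j), W.row(i).t()) - ojj * W(i, j);
      double mu = -s / ojj;
      int l = codes(i, jj); // 0-based code
      W(i, j) = rtnorm1(mu, sd, cut[l], cut[l + 1]);
    }
  }
}

// Redraw free interior cutpoints uniformly between the extreme latent
// values of adjacent codes; levels with no observations fall back to the
// neighbouring cutpoints so the ordering is preserved.
static void cutpoint_sweep(const arma::mat& W, const IntegerMatrix& codes,
                           const IntegerVector& ord_cols,
                           List& cutpoints, const LogicalVector& free_cut) {
  int n = W.n_rows;
  for (int jj = 0; jj < ord_cols.size(); ++jj) {
    if (!free_cut[jj]) continue;
    int j = ord_cols[jj];
    NumericVector cut = cutpoints[jj]; // length M + 1, modified in place
    int M = cut.size() - 1;
    for (int l = 1; l <= M - 1; ++l) {
      double zL = R_NegInf, zU = R_PosInf;
      for (int i = 0; i < n; ++i) {
        int c = codes(i, jj);
        if (c == l - 1 && W(i, j) > zL) zL = W(i, j);
        if (c == l && W(i, j) < zU) zU = W(i, j);
      }
      if (!std::isfinite(zL)) zL = std::isfinite(cut[l - 1]) ? cut[l - 1]
                                 : (std::isfinite(zU) ? zU - 1.0 : cut[l]);
      if (!std::isfinite(zU)) zU = std::isfinite(cut[l + 1]) ? cut[l + 1]
                                 : (std::isfinite(zL) ? zL + 1.0 : cut[l]);
      if (zU > zL) cut[l] = zL + unif_rand() * (zU - zL);
      // else: degenerate interval, keep current cutpoint
    }
  }
}

// Identifiability restriction for the latent scale: with cutpoints free
// (or fixed at 0 for binary), the scale of a latent column is not
// identified by the likelihood, so each latent column is rescaled to unit
// variance after the latent sweep, with the compensating transformation
// applied to Omega (z -> z/s maps Omega -> D Omega D, D_jj = s) and to
// the free cutpoints.
static void rescale_latent(arma::mat& W, arma::mat& Omega,
                           const IntegerVector& ord_cols, List& cutpoints,
                           const LogicalVector& free_cut) {
  int n = W.n_rows;
  for (int jj = 0; jj < ord_cols.size(); ++jj) {
    int j = ord_cols[jj];
    double s = std::sqrt(arma::accu(arma::square(W.col(j))) / n);
    if (!(s > 1e-8) || !std::isfinite(s)) continue;
    W.col(j) /= s;
    Omega.row(j) *= s;
    Omega.col(j) *= s;
    if (free_cut[jj]) {
      NumericVector cut = cutpoints[jj];
      for (int l = 1; l < cut.size() - 1; ++l) cut[l] /= s;
    }
  }
}

// Column-wise block Gibbs update of Omega under element-wise Laplace
// (off-diagonal, latent scales Tlat) and exponential (diagonal) priors;
// the construction keeps Omega in the positive-definite cone.
static void precision_sweep(arma::mat& Omega, const arma::mat& S,
                            const arma::mat& Tlat, const arma::vec& lam_diag,
                            int n) {
  int p = Omega.n_rows;
  if (p == 1) {
    Omega(0, 0) = rgamma1(0.5 * n + 1.0, 0.5 * S(0, 0) + lam_diag[0]);
    return;
  }
  arma::uvec all = arma::regspace<arma::uvec>(0, p - 1);
  for (int i = 0; i < p; ++i) {
    arma::uvec others = all.elem(arma::find(all != (unsigned)i));
    arma::mat O11inv = arma::inv_sympd(Omega.submat(others, others));
    double s22 = S(i, i);
    arma::vec s12 = S.col(i);
    s12 = s12.elem(others);
    double gam = rgamma1(0.5 * n + 1.0, 0.5 * s22 + lam_diag[i]);
    arma::vec tvec = Tlat.col(i);
    tvec = tvec.elem(others);
    arma::mat Cinv = (s22 + 2.0 * lam_diag[i]) * O11inv;
    Cinv.diag() += 1.0 / tvec;
    arma::mat C = arma::inv_sympd(Cinv);
    arma::vec z(p - 1);
    for (int k = 0; k < p - 1; ++k) z[k] = norm_rand();
    arma::mat U = arma::chol(C); // C = U'U
    arma::vec beta = -C * s12 + U.t() * z;
    for (int k = 0; k < p - 1; ++k) {
      Omega(others[k], i) = beta[k];
      Omega(i, others[k]) = beta[k];
    }
    Omega(i, i) = gam + arma::as_scalar(beta.t() * O11inv * beta);
  }
}

// latent scales of the Laplace representation: 1/t_ij | - ~ IG(lam/|w|, lam^2)
static void latent_scale_sweep(arma::mat& Tlat, const arma::mat& Omega,
                               const arma::mat& Lam) {
  int p = Omega.n_rows;
  for (int i = 0; i < p - 1; ++i) {
    for (int j = i + 1; j < p; ++j) {
      double aw = std::fabs(Omega(i, j));
      if (aw < 1e-12) aw = 1e-12;
      double lam = Lam(i, j);
      double inv_t = rinvgauss1(lam / aw, lam * lam);
      double t = 1.0 / inv_t;
      Tlat(i, j) = t;
      Tlat(j, i) = t;
    }
  }
}

// mixture component indicators delta, mixing weights p_ij, and shrinkage
// parameters lambda (off-diagonal Gamma mixture, diagonal Gamma).
// delta is drawn from its conditional given (p_ij, omega_ij) with lambda
// integrated out analytically (partially collapsed update): the two Gamma
// components can be nearly non-overlapping for large belief values, and
// conditioning on the current lambda would freeze the indicator.
// Integral: int DE(w; l) Ga(l; a, b) dl = (a b^a / 2) / (|w| + b)^(a+1).
static void shrinkage_sweep(arma::mat& Lam, arma::vec& lam_diag,
                            arma::mat& Pmix, arma::imat& Delta,
                            const arma::mat& Omega, const arma::imat& A0,
                            const arma::mat& Belief,
                            double a_lam, double b_lam, double a_p, double b_p,
                            double a_diag, double b_diag) {
  int p = Omega.n_rows;
  for (int i = 0; i < p; ++i)
    lam_diag[i] = rgamma1(1.0 + a_diag, Omega(i, i) + b_diag);
  double logb = std::log(b_lam);
  for (int i = 0; i < p - 1; ++i) {
    for (int j = i + 1; j < p; ++j) {
      double kap = Belief(i, j);
      double pij = Pmix(i, j);
      double aw = std::fabs(Omega(i, j));
      // delta | p, omega (lambda marginalised), in log space
      double lm1 = std::log(a_lam) + a_lam * logb -
                   (a_lam + 1.0) * std::log(aw + b_lam);
      double lm0 = std::log(kap + a_lam) + (kap + a_lam) * logb -
                   (kap + a_lam + 1.0) * std::log(aw + b_lam);
      double l1 = std::log(pij) + lm1;
      double l0 = std::log1p(-pij) + lm0;
      double pr1 = 1.0 / (1.0 + std::exp(l0 - l1));
      int del = (unif_rand() < pr1) ? 1 : 0;
      // p | delta
      double a_post = A0(i, j) * kap + a_p + (del == 1 ? 1.0 : 0.0);
      double b_post = (1 - A0(i, j)) * kap + b_p + (del == 0 ? 1.0 : 0.0);
      pij = R::rbeta(a_post, b_post);
      // lambda | delta, omega
      double shape = (del == 1) ? (1.0 + a_lam) : (1.0 + kap + a_lam);
      double lam = rgamma1(shape, aw + b_lam);
      Delta(i, j) = del; Delta(j, i) = del;
      Pmix(i, j) = pij; Pmix(j, i) = pij;
      Lam(i, j) = lam;  Lam(j, i) = lam;
    }
  }
}

// ---- exported single-sweep wrappers (used by the R layer and tests) ----

// [[Rcpp::export]]
arma::mat sample_latent_cpp(arma::mat W, const arma::mat& Omega,
                            const IntegerMatrix& codes,
                            const IntegerVector& ord_cols, const List& cutpoints) {
  latent_sweep(W, Omega, codes, ord_cols, cutpoints);
  return W;
}

// [[Rcpp::export]]
List sample_cutpoints_cpp(const arma::mat& W, const IntegerMatrix& codes,
                          const IntegerVector& ord_cols, List cutpoints,
                          const LogicalVector& free_cut) {
  List out = clone(cutpoints);
  cutpoint_sweep(W, codes, ord_cols, out, free_cut);
  return out;
}

// [[Rcpp::export]]
arma::mat sample_precision_cpp(arma::mat Omega, const arma::mat& S,
                               const arma::mat& Tlat, const arma::vec& lam_diag,
                               int n) {
  precision_sweep(Omega, S, Tlat, lam_diag, n);
  return Omega;
}

// [[Rcpp::export]]
arma::mat sample_latent_scales_cpp(arma::mat Tlat, const arma::mat& Omega,
                                   const arma::mat& Lam) {
  latent_scale_sweep(Tlat, Omega, Lam);
  return Tlat;
}

// [[Rcpp::export]]
List sample_shrinkage_cpp(arma::mat Lam, arma::vec lam_diag, arma::mat Pmix,
                          arma::imat Delta, const arma::mat& Omega,
                          const arma::imat& A0, const arma::mat& Belief,
                          double a_lam, double b_lam, double a_p, double b_p,
                          double a_diag, double b_diag) {
  shrinkage_sweep(Lam, lam_diag, Pmix, Delta, Omega, A0, Belief,
                  a_lam, b_lam, a_p, b_p, a_diag, b_diag);
  return List::create(_["lam_offdiag"] = Lam, _["lam_diag"] = lam_diag,
                      _["pmix"] = Pmix, _["delta"] = Delta);
}

// Full stage-1 chain.  Accumulates posterior means of Omega and of the
// absolute partial correlations, plus the mean completed data matrix used
// for the Wishart reference computed on the R side.
// [[Rcpp::export]]
List graph_mcmc_cpp(arma::mat W, const IntegerMatrix& codes,
                    const IntegerVector& ord_cols, List cutpoints,
                    const LogicalVector& free_cut,
                    arma::mat Omega, arma::mat Tlat, arma::mat Lam,
                    arma::vec lam_diag, arma::mat Pmix, arma::imat Delta,
                    const arma::imat& A0, const arma::mat& Belief,
                    double a_lam, double b_lam, double a_p, double b_p,
                    double a_diag, double b_diag,
                    int n_iter, int burn_in) {
  int n = W.n_rows, p = W.n_cols;
  bool any_ord = ord_cols.size() > 0;
  List cuts = clone(cutpoints);
  arma::mat omega_sum(p, p, arma::fill::zeros);
  arma::mat rho_sum(p, p, arma::fill::zeros);
  arma::mat rho_signed_sum(p, p, arma::fill::zeros);
  arma::mat W_sum(n, p, arma::fill::zeros);
  arma::mat delta_sum(p, p, arma::fill::zeros);
  arma::mat S = W.t() * W;
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    if (any_ord) {
      latent_sweep(W, Omega, codes, ord_cols, cuts);
      cutpoint_sweep(W, codes, ord_cols, cuts, free_cut);
      rescale_latent(W, Omega, ord_cols, cuts, free_cut);
      S = W.t() * W;
    }
    latent_scale_sweep(Tlat, Omega, Lam);
    precision_sweep(Omega, S, Tlat, lam_diag, n);
    shrinkage_sweep(Lam, lam_diag, Pmix, Delta, Omega, A0, Belief,
                    a_lam, b_lam, a_p, b_p, a_diag, b_diag);
    if (it >= burn_in) {
      ++kept;
      omega_sum += Omega;
      W_sum += W;
      delta_sum += arma::conv_to<arma::mat>::from(Delta);
      for (int i = 0; i < p; ++i) {
        rho_sum(i, i) += 1.0;
        rho_signed_sum(i, i) += 1.0;
        for (int j = i + 1; j < p; ++j) {
          double rs = -Omega(i, j) / std::sqrt(Omega(i, i) * Omega(j, j));
          rho_sum(i, j) += std::fabs(rs);
          rho_sum(j, i) += std::fabs(rs);
          rho_signed_sum(i, j) += rs;
          rho_signed_sum(j, i) += rs;
        }
      }
    }
  }
  if (kept < 1) stop("no kept iterations");
  return List::create(
      _["omega_mean"] = omega_sum / kept, _["rho_mean_abs"] = rho_sum / kept,
      _["rho_signed_mean"] = rho_signed_sum / kept,
      _["W_mean"] = W_sum / kept, _["delta_mean"] = delta_sum / kept,
      _["n_samples_kept"] = kept,
      _["state"] = List::create(_["Omega"] = Omega, _["W"] = W,
                                _["cutpoints"] = cuts, _["Tlat"] = Tlat,
                                _["lam_offdiag"] = Lam, _["lam_diag"] = lam_diag,
                                _["pmix"] = Pmix, _["delta"] = Delta));
}

// ---------------------------------------------------------------------
// stage 2: clique-structured spike-and-slab Gibbs sampler
//
// State layout (list passed from R): gamma (q, int 0/1), beta (p),
// tau2 (p, the diagonal loadings of A = X'X + diag(tau2)), alpha, eta,
// eta1_sq, pi.

struct VsHyper {
  double a_pi, b_pi, a_eta, b_eta, e1_shape, e1_rate, mu_alpha, sig2_alpha;
};

// active-clique count per variable given gamma
static arma::ivec clique_counts(const arma::ivec& gamma,
                                const std::vector<arma::uvec>& cl, int p) {
  arma::ivec cnt(p, arma::fill::zeros);
  for (size_t k = 0; k < cl.size(); ++k)
    if (gamma[k] == 1)
      for (unsigned m = 0; m < cl[k].n_elem; ++m) cnt[cl[k][m]] += 1;
  return cnt;
}

// Step 1: clique inclusion indicators.  For each clique the coefficients
// of its exclusive (toggled) variables are integrated out analytically
// given tau2 and eta, giving a Gaussian marginal-likelihood Bayes factor.
static void clique_sweep(arma::ivec& gamma, arma::vec& beta,
                         const arma::vec& tau2, double eta, double pi,
                         const std::vector<arma::uvec>& cl,
                         const arma::mat& X, arma::vec& res,
                         arma::ivec& cnt) {
  int q = cl.size();
  double lp1 = std::log(pi), lp0 = std::log1p(-pi);
  for (int k = 0; k < q; ++k) {
    const arma::uvec& Ck = cl[k];
    int g = gamma[k];
    // toggled set: members whose activity flips with gamma_k
    std::vector<arma::uword> Ev;
    for (unsigned m = 0; m < Ck.n_elem; ++m)
      if (cnt[Ck[m]] - g == 0) Ev.push_back(Ck[m]);
    arma::uvec E(Ev);
    int g_new;
    if (E.n_elem == 0) {
      if (pi <= 0.0) g_new = 0;
      else if (pi >= 1.0) g_new = 1;
      else g_new = (unif_rand() < pi) ? 1 : 0;
    } else {
      arma::vec r = res;
      if (g == 1) r += X.cols(E) * beta.elem(E); // remove clique k's fit
      arma::mat XE = X.cols(E);
      arma::vec b = XE.t() * r;
      arma::mat M = XE.t() * XE;
      M.diag() += tau2.elem(E);
      arma::mat U = arma::chol(M);
      arma::vec w = arma::solve(arma::trimatl(U.t()), b);
      double quad = arma::dot(w, w);
      double logdetM = 2.0 * arma::sum(arma::log(U.diag()));
      double logBF = 0.5 * (arma::sum(arma::log(tau2.elem(E))) - logdetM) +
                     0.5 * eta * quad;
      double lo;
      if (pi <= 0.0) lo = R_NegInf;
      else if (pi >= 1.0) lo = R_PosInf;
      else lo = lp1 - lp0 + logBF;
      double pr = 1.0 / (1.0 + std::exp(-lo));
      g_new = (unif_rand() < pr) ? 1 : 0;
      if (g_new == 0) {
        beta.elem(E).zeros();
        res = r;
      } else if (g == 0) {
        res = r; // beta_E currently zero; step 2 redraws it
      }
      // if g == 1 && g_new == 1: res unchanged
    }
    if (g_new != g) {
      for (unsigned m = 0; m < Ck.n_elem; ++m)
        cnt[Ck[m]] += (g_new == 1) ? 1 : -1;
      gamma[k] = g_new;
    }
  }
}

// Steps 2-6 given gamma: beta_gamma, tau2, eta, eta1^2, pi, alpha
static void regression_sweep(arma::ivec& gamma, arma::vec& beta,
                             arma::vec& tau2, double& alpha, double& eta,
                             double& eta1_sq, double& pi,
                             const std::vector<arma::uvec>& cl,
                             const arma::vec& y, const arma::mat& X,
                             const VsHyper& h, arma::vec& res,
                             arma::ivec& cnt,
                             bool up_beta, bool up_tau, bool up_eta,
                             bool up_eta1, bool up_pi, bool up_alpha) {
  int n = y.n_elem, p = X.n_cols, q = cl.size();
  arma::uvec A = arma::find(cnt > 0);
  arma::vec ytil = y - alpha;
  // Step 2: beta_gamma ~ N(A^{-1} X'ytil, eta^{-1} A^{-1})
  if (up_beta) {
    beta.zeros();
    if (A.n_elem > 0) {
      arma::mat XA = X.cols(A);
      arma::mat M = XA.t() * XA;
      M.diag() += tau2.elem(A);
      arma::mat U = arma::chol(M);
      arma::vec mu = arma::solve(M, XA.t() * ytil);
      arma::vec z(A.n_elem);
      for (unsigned k = 0; k < A.n_elem; ++k) z[k] = norm_rand();
      // cov = eta^{-1} M^{-1}; M = U'U so M^{-1} = U^{-1} U^{-T}
      arma::vec dev = arma::solve(arma::trimatu(U), z) / std::sqrt(eta);
      beta.elem(A) = mu + dev;
    }
    res = ytil - X * beta;
  } else {
    res = ytil - X * beta;
  }
  // Step 3: residual precision
  double rss = arma::dot(res, res);
  if (up_eta) eta = rgamma1(0.5 * n + h.a_eta, 0.5 * rss + h.b_eta);
  // latent scales of the Laplace prior (inverse-Gaussian for active,
  // prior refresh for inactive)
  if (up_tau) {
    for (int j = 0; j < p; ++j) {
      if (cnt[j] > 0) {
        double b2 = beta[j] * beta[j];
        if (b2 < 1e-20) b2 = 1e-20;
        double t = rinvgauss1(std::sqrt(eta1_sq / (eta * b2)), eta1_sq);
        tau2[j] = t;
      } else {
        double s = rgamma1(1.0, 0.5 * eta1_sq); // Exp(eta1_sq / 2)
        if (s < 1e-12) s = 1e-12;
        tau2[j] = 1.0 / s;
      }
    }
  }
  // Step 5: eta1^2 under its conjugate Gamma hyperprior
  if (up_eta1) {
    double ssum = 0.0;
    int m = 0;
    for (int j = 0; j < p; ++j)
      if (cnt[j] > 0) { ssum += 1.0 / tau2[j]; ++m; }
    eta1_sq = rgamma1(h.e1_shape + m, h.e1_rate + 0.5 * ssum);
  }
  // Step 4: clique sparsity
  if (up_pi) {
    int qstar = arma::accu(gamma);
    pi = R::rbeta(qstar + h.a_pi, (double)(q - qstar) + h.b_pi);
  }
  // Step 6: intercept
  if (up_alpha) {
    arma::vec fit = y - res - alpha; // X beta
    double prec = n * eta + 1.0 / h.sig2_alpha;
    double mean = (eta * arma::accu(y - fit) + h.mu_alpha / h.sig2_alpha) / prec;
    alpha = mean + norm_rand() / std::sqrt(prec);
    res = y - alpha - fit;
  }
}

static std::vector<arma::uvec> unpack_cliques(const List& cliques) {
  std::vector<arma::uvec> cl;
  for (int k = 0; k < cliques.size(); ++k) {
    IntegerVector ck = cliques[k]; // 1-based from R
    arma::uvec u(ck.size());
    for (int m = 0; m < ck.size(); ++m) u[m] = ck[m] - 1;
    cl.push_back(u);
  }
  return cl;
}

// [[Rcpp::export]]
List varsel_sweep_cpp(List state, const arma::vec& y, const arma::mat& X,
                      const List& cliques, const List& hyper,
                      const LogicalVector& update) {
  // update flags: gamma, beta, tau, eta, eta1, pi, alpha
  VsHyper h = {as<double>(hyper["a_pi"]), as<double>(hyper["b_pi"]),
               as<double>(hyper["a_eta"]), as<double>(hyper["b_eta"]),
               as<double>(hyper["eta1_sq_shape"]), as<double>(hyper["eta1_sq_rate"]),
               as<double>(hyper["mu_alpha"]), as<double>(hyper["sigma2_alpha"])};
  std::vector<arma::uvec> cl = unpack_cliques(cliques);
  arma::ivec gamma = as<arma::ivec>(state["gamma"]);
  arma::vec beta = as<arma::vec>(state["beta"]);
  arma::vec tau2 = as<arma::vec>(state["tau2"]);
  double alpha = as<double>(state["alpha"]);
  double eta = as<double>(state["eta"]);
  double eta1_sq = as<double>(state["eta1_sq"]);
  double pi = as<double>(state["pi"]);
  int p = X.n_cols;
  arma::ivec cnt = clique_counts(gamma, cl, p);
  // zero betas inconsistent with gamma
  for (int j = 0; j < p; ++j) if (cnt[j] == 0) beta[j] = 0.0;
  arma::vec res = (y - alpha) - X * beta;
  if (update[0])
    clique_sweep(gamma, beta, tau2, eta, pi, cl, X, res, cnt);
  regression_sweep(gamma, beta, tau2, alpha, eta, eta1_sq, pi, cl, y, X, h,
                   res, cnt, update[1], update[2], update[3], update[4],
                   update[5], update[6]);
  return List::create(_["gamma"] = gamma, _["beta"] = beta, _["tau2"] = tau2,
                      _["alpha"] = alpha, _["eta"] = eta,
                      _["eta1_sq"] = eta1_sq, _["pi"] = pi);
}

// Full stage-2 chain; returns kept draws of gamma, beta, alpha, eta.
// [[Rcpp::export]]
List varsel_mcmc_cpp(const arma::vec& y, const arma::mat& X,
                     const List& cliques, const List& hyper,
                     int n_iter, int burn_in) {
  VsHyper h = {as<double>(hyper["a_pi"]), as<double>(hyper["b_pi"]),
               as<double>(hyper["a_eta"]), as<double>(hyper["b_eta"]),
               as<double>(hyper["eta1_sq_shape"]), as<double>(hyper["eta1_sq_rate"]),
               as<double>(hyper["mu_alpha"]), as<double>(hyper["sigma2_alpha"])};
  std::vector<arma::uvec> cl = unpack_cliques(cliques);
  int n = y.n_elem, p = X.n_cols, q = cl.size();
  arma::ivec gamma(q, arma::fill::zeros);
  arma::vec beta(p, arma::fill::zeros);
  arma::vec tau2(p, arma::fill::ones);
  double ybar = arma::mean(y);
  double yvar = arma::var(y);
  if (!(yvar > 0.0)) yvar = 1.0;
  double alpha = ybar, eta = 1.0 / yvar, eta1_sq = 1.0;
  double pi = h.a_pi / (h.a_pi + h.b_pi);
  arma::ivec cnt = clique_counts(gamma, cl, p);
  arma::vec res = (y - alpha) - X * beta;
  int n_keep = n_iter - burn_in;
  arma::imat gamma_draws(n_keep, q);
  arma::mat beta_draws(n_keep, p);
  arma::vec alpha_draws(n_keep), eta_draws(n_keep);
  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {
    clique_sweep(gamma, beta, tau2, eta, pi, cl, X, res, cnt);
    regression_sweep(gamma, beta, tau2, alpha, eta, eta1_sq, pi, cl, y, X, h,
                     res, cnt, true, true, true, true, true, true);
    if (it >= burn_in) {
      gamma_draws.row(kept) = gamma.t();
      beta_draws.row(kept) = beta.t();
      alpha_draws[kept] = alpha;
      eta_draws[kept] = eta;
      ++kept;
    }
  }
  (void)n;
  return List::create(_["gamma_draws"] = gamma_draws,
                      _["beta_draws"] = beta_draws,
                      _["alpha_draws"] = alpha_draws,
                      _["eta_draws"] = eta_draws);
}
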