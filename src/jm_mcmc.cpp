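// Adaptive Metropolis-within-Gibbs sampler for the joint model.
//
// Global parameters are sampled on an unconstrained, covariate-centred
// parameterization (log Weibull shape; the Weibull log-scale is shifted by
// phi*log(t0) + alpha1*mu_c + alpha2*s2_c to break the strong posterior
// ridges between lambda, phi and the association parameters). Subject
// random effects are updated one subject at a time (conditionally
// independent given the globals), and the random-effects covariance has a
// conjugate inverse-Wishart Gibbs step. Proposal scales adapt during
// warm-up only, so the post-warm-up chain is a valid Markov chain.
//
// Internal global layout (d = mels ? 9 : 8):
//   0..2 theta1..theta3
//   3    mels: theta4, reference: log(sigma^2)
//   4    nu
//   5    lam_cc  (centred Weibull log-scale)
//   6    log(phi)
//   7    alpha1
//   8    alpha2  (mels only)
// Natural lam = lam_cc - phi*log(t0) - alpha1*mu_c - alpha2*s2_c.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct JMData {
  arma::vec y, tobs;
  arma::ivec sub_start, sub_len;  // 0-based offsets into y/tobs
  arma::ivec cens;                // 0 interval, 1 right
  arma::vec tL, tR, tc;
  int N;
  bool mels;
  arma::vec qx, qw;               // Gauss-Legendre on (0,1), weights sum 1
  double t0, mu_c, s2_c;
};

const double LOG2PI = 1.837877066409345483560659472811;

inline double mu3pl(double t, double a1, double a2, double a3) {
  return a1 / (1.0 + std::exp(-(t - a2) / a3));
}

// survival factor helpers ------------------------------------------------
// Z-augmented likelihood: right-censored subjects carry a latent cure
// indicator Z (1 = immune). Interval-censored subjects are known
// susceptible. The marginal version integrates Z out and is what gets
// recorded as the pointwise log-likelihood.

// data log-likelihood of subject i; aug < 0 -> marginal over cure status,
// aug in {0,1} -> conditional on Z_i = aug (right-censored subjects only)
double subj_loglik(const JMData& D, int i, const arma::vec& g,
                   const arma::rowvec& b, int aug = -1) {
  const double a1 = std::exp(g[0] + b[0]);
  const double a2 = std::exp(g[1] + b[1]);
  const double a3 = std::exp(g[2] + b[2]);
  const int n = D.sub_len[i];
  double sig, s2;
  if (D.mels) {
    const double lsig = (n >= 2) ? g[3] + b[3] : g[3];
    sig = std::exp(lsig);
  } else {
    sig = std::exp(0.5 * g[3]);
  }
  s2 = sig * sig;

  double ll = 0.0;
  const int st = D.sub_start[i];
  for (int j = 0; j < n; ++j) {
    const double m = mu3pl(D.tobs[st + j], a1, a2, a3);
    const double z = (D.y[st + j] - m) / sig;
    ll += -0.5 * LOG2PI - std::log(sig) - 0.5 * z * z;
  }

  const double phi = std::exp(g[6]);
  const double lamcc = g[5];
  const double al1 = g[7];
  const double al2 = D.mels ? g[8] : 0.0;
  const double eta = 1.0 / (1.0 + std::exp(-g[4]));

  // cumulative hazard via fixed-order quadrature in centred form
  auto H = [&](double T) -> double {
    if (T <= 0.0) return 0.0;
    double acc = 0.0;
    const int Q = D.qx.n_elem;
    for (int k = 0; k < Q; ++k) {
      const double u = T * D.qx[k];
      const double m = mu3pl(u, a1, a2, a3);
      double e = lamcc + al1 * (m - D.mu_c) + al2 * (s2 - D.s2_c);
      e += (phi - 1.0) * std::log(u / D.t0);
      if (e > 700.0) e = 700.0;
      acc += D.qw[k] * (phi / D.t0) * std::exp(e);
    }
    return T * acc;
  };

  if (D.cens[i] == 0) {
    double d = std::exp(-H(D.tL[i])) - std::exp(-H(D.tR[i]));
    if (!(d > 1e-300)) d = 1e-300;
    ll += std::log1p(-eta) + std::log(d);
  } else if (aug < 0) {
    ll += std::log(eta + (1.0 - eta) * std::exp(-H(D.tc[i])));
  } else if (aug == 1) {
    ll += std::log(eta);
  } else {
    ll += std::log1p(-eta) - H(D.tc[i]);
  }
  if (!std::isfinite(ll)) ll = -1e300;
  return ll;
}

// latency survival S(tc) of a right-censored subject (for the Z update)
double surv_tc(const JMData& D, int i, const arma::vec& g,
               const arma::rowvec& b) {
  const double a1 = std::exp(g[0] + b[0]);
  const double a2 = std::exp(g[1] + b[1]);
  const double a3 = std::exp(g[2] + b[2]);
  const int n = D.sub_len[i];
  double sig = D.mels ? std::exp((n >= 2) ? g[3] + b[3] : g[3])
                      : std::exp(0.5 * g[3]);
  const double s2 = sig * sig;
  const double phi = std::exp(g[6]);
  const double lamcc = g[5];
  const double al1 = g[7];
  const double al2 = D.mels ? g[8] : 0.0;
  const double T = D.tc[i];
  if (T <= 0.0) return 1.0;
  double acc = 0.0;
  const int Q = D.qx.n_elem;
  for (int k = 0; k < Q; ++k) {
    const double u = T * D.qx[k];
    const double m = mu3pl(u, a1, a2, a3);
    double e = lamcc + al1 * (m - D.mu_c) + al2 * (s2 - D.s2_c);
    e += (phi - 1.0) * std::log(u / D.t0);
    if (e > 700.0) e = 700.0;
    acc += D.qw[k] * (phi / D.t0) * std::exp(e);
  }
  return std::exp(-T * acc);
}

double total_loglik(const JMData& D, const arma::vec& g, const arma::mat& B,
                    const arma::ivec& Z, arma::vec& sll, bool prior_only) {
  if (prior_only) { sll.zeros(); return 0.0; }
  double tot = 0.0;
  for (int i = 0; i < D.N; ++i) {
    sll[i] = subj_loglik(D, i, g, B.row(i),
                         D.cens[i] == 1 ? Z[i] : -1);
    tot += sll[i];
  }
  return tot;
}

inline double dnorm_log(double x, double sd) {
  return -0.5 * LOG2PI - std::log(sd) - 0.5 * (x / sd) * (x / sd);
}

// log-prior of the global vector on the internal scale, incl. Jacobians
double global_logprior(const JMData& D, const arma::vec& g) {
  const double phi = std::exp(g[6]);
  const double al1 = g[7];
  const double al2 = D.mels ? g[8] : 0.0;
  const double lam = g[5] - phi * std::log(D.t0) - al1 * D.mu_c -
                     al2 * D.s2_c;
  double lp = dnorm_log(g[0], 10.0) + dnorm_log(g[1], 10.0) +
              dnorm_log(g[2], 10.0) + dnorm_log(g[4], 10.0) +
              dnorm_log(lam, 10.0) + dnorm_log(al1, 10.0);
  // half-Cauchy(0,1) on phi, + log-Jacobian of phi = exp(log_phi)
  lp += std::log(2.0 / M_PI) - std::log1p(phi * phi) + g[6];
  if (D.mels) {
    lp += dnorm_log(g[3], 10.0) + dnorm_log(g[8], 10.0);
  } else {
    // half-Cauchy(0,1) on sigma^2, + Jacobian of sigma^2 = exp(g3)
    const double s2 = std::exp(g[3]);
    lp += std::log(2.0 / M_PI) - std::log1p(s2 * s2) + g[3];
  }
  return lp;
}

inline double re_logprior(const arma::rowvec& b, const arma::mat& Sig_inv,
                          double ldet, int p) {
  const double q = arma::as_scalar(b * Sig_inv * b.t());
  return -0.5 * (p * LOG2PI + ldet + q);
}

// draw from inverse-Wishart(S, df) by Bartlett decomposition (R's RNG)
arma::mat riwish(const arma::mat& S, double df) {
  const int p = S.n_rows;
  arma::mat V = arma::inv_sympd(S);
  arma::mat L = arma::chol(V, "lower");
  arma::mat A(p, p, arma::fill::zeros);
  for (int i = 0; i < p; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat W = LA * LA.t();
  return arma::inv_sympd(W);
}

}  // namespace

// Runs a single chain; RNG state is R's (seed with set.seed before calling).
// [[Rcpp::export]]
List run_jm_chain(List data, int iterations, int warmup,
                  arma::vec g_init, arma::mat B_init, arma::mat Sigma_init,
                  arma::vec qx, arma::vec qw,
                  double t0, double mu_c, double s2_c,
                  bool mels, bool prior_only, bool save_re,
                  double iw_df0) {
  JMData D;
  D.y = as<arma::vec>(data["y"]);
  D.tobs = as<arma::vec>(data["tobs"]);
  D.sub_start = as<arma::ivec>(data["sub_start"]);
  D.sub_len = as<arma::ivec>(data["sub_len"]);
  D.cens = as<arma::ivec>(data["cens"]);
  D.tL = as<arma::vec>(data["tL"]);
  D.tR = as<arma::vec>(data["tR"]);
  D.tc = as<arma::vec>(data["tc"]);
  D.N = D.sub_len.n_elem;
  D.mels = mels;
  D.qx = qx; D.qw = qw;
  D.t0 = t0; D.mu_c = mu_c; D.s2_c = s2_c;

  const int d = g_init.n_elem;
  const int p = Sigma_init.n_rows;
  const int N = D.N;
  const int n_keep = iterations - warmup;

  arma::vec g = g_init;
  arma::mat B = B_init;
  arma::mat Sigma = Sigma_init;
  arma::mat Sig_inv = arma::inv_sympd(Sigma);
  double Sig_ldet = std::log(arma::det(Sigma));
  arma::mat Sig_cholU = arma::chol(Sigma);  // upper: U'U = Sigma

  // latent cure indicators for right-censored subjects (1 = immune);
  // interval-censored subjects are known susceptible (Z = 0)
  arma::ivec Z(N, arma::fill::zeros);
  for (int i = 0; i < N; ++i) if (D.cens[i] == 1) Z[i] = 1;

  arma::vec sll(N, arma::fill::zeros);
  double cur_ll = total_loglik(D, g, B, Z, sll, prior_only);
  double cur_lp = global_logprior(D, g);

  // adaptation state
  arma::vec ls(d);
  ls.fill(std::log(0.1));
  arma::vec leps(N);
  leps.fill(std::log(0.5));
  arma::vec lshift(4);
  lshift.fill(std::log(0.1));
  double ls_joint = std::log(1.0);
  arma::vec am_mean(d, arma::fill::zeros);
  arma::mat am_cov(d, d, arma::fill::zeros);
  arma::mat am_chol;
  long am_n = 0;
  const int am_start = std::max(50, warmup / 4);
  const int joint_start = std::max(100, warmup / 2);
  bool have_chol = false;

  arma::vec acc_comp(d, arma::fill::zeros);
  double acc_joint = 0.0, n_joint = 0.0;
  arma::vec acc_re(N, arma::fill::zeros);

  const int n_sig = p * (p + 1) / 2;
  arma::mat keep_g(n_keep, d + n_sig);
  arma::mat keep_ll(n_keep, N);
  arma::vec keep_tot(n_keep);
  arma::mat B_sum(N, p, arma::fill::zeros);
  arma::cube B_keep;
  if (save_re) B_keep.set_size(N, p, n_keep);

  arma::vec sll_prop(N);

  for (int it = 0; it < iterations; ++it) {
    const bool adapting = it < warmup;
    const double gam = std::min(0.25, 5.0 / std::sqrt(it + 1.0));

    // --- componentwise global updates ---
    for (int k = 0; k < d; ++k) {
      arma::vec gp = g;
      // occasional large jumps help traverse weakly identified, near-flat
      // directions (notably the variance-association parameter)
      const double mix = (unif_rand() < 0.1) ? 4.0 : 1.0;
      gp[k] += mix * std::exp(ls[k]) * norm_rand();
      const double lp_p = global_logprior(D, gp);
      double ll_p = cur_ll;
      if (std::isfinite(lp_p)) {
        ll_p = total_loglik(D, gp, B, Z, sll_prop, prior_only);
      }
      const double lacc = (ll_p + lp_p) - (cur_ll + cur_lp);
      const bool acc = std::isfinite(lp_p) &&
                       std::log(unif_rand()) < lacc;
      if (acc) {
        g = gp; cur_ll = ll_p; cur_lp = lp_p; sll = sll_prop;
        if (!adapting) acc_comp[k] += 1.0;
      }
      if (adapting) ls[k] += gam * ((acc ? 1.0 : 0.0) - 0.44);
    }

    // --- interweaved shift moves ---
    // theta_k -> theta_k + delta with b_{.k} -> b_{.k} - delta keeps every
    // a_ik = exp(theta_k + b_ik) fixed, so the data likelihood is invariant
    // for k = 0..2 (and, for MELS theta4, invariant except for subjects
    // with a single measurement, whose sigma_i = exp(theta4)). This breaks
    // the slow random walk of the location parameters against N coupled
    // random effects.
    const int n_shift = D.mels ? 4 : 3;
    for (int k = 0; k < n_shift; ++k) {
      const double delta = std::exp(lshift[k]) * norm_rand();
      arma::vec gp = g;
      gp[k] += delta;
      arma::mat Bp = B;
      Bp.col(k) -= delta;
      double lacc = dnorm_log(gp[k], 10.0) - dnorm_log(g[k], 10.0);
      lacc += -0.5 * (arma::accu((Bp * Sig_inv) % Bp) -
                      arma::accu((B * Sig_inv) % B));
      double ll_new = cur_ll;
      arma::vec sll_new;
      bool partial = (k == 3) && D.mels && !prior_only;
      if (partial) {
        sll_new = sll;
        for (int i = 0; i < N; ++i) {
          if (D.sub_len[i] == 1) {
            sll_new[i] = subj_loglik(D, i, gp, Bp.row(i),
                                     D.cens[i] == 1 ? Z[i] : -1);
            ll_new += sll_new[i] - sll[i];
          }
        }
        lacc += ll_new - cur_ll;
      }
      const bool acc = std::log(unif_rand()) < lacc;
      if (acc) {
        g = gp;
        B = Bp;
        if (partial) { cur_ll = ll_new; sll = sll_new; }
        cur_lp = global_logprior(D, g);
      }
      if (adapting) lshift[k] += gam * ((acc ? 1.0 : 0.0) - 0.44);
    }

    // --- adaptive-metropolis running moments ---
    if (it >= am_start) {
      ++am_n;
      arma::vec delta = g - am_mean;
      am_mean += delta / am_n;
      am_cov += (delta * (g - am_mean).t() - am_cov) / am_n;
    }

    // --- joint global update ---
    if (it >= joint_start && am_n > 2 * d) {
      if (adapting && (!have_chol || it % 25 == 0)) {
        arma::mat C = am_cov + 1e-8 * arma::eye(d, d);
        have_chol = arma::chol(am_chol, C);
      }
      if (have_chol) {
        arma::vec z(d);
        for (int k = 0; k < d; ++k) z[k] = norm_rand();
        arma::vec gp = g + std::exp(ls_joint) * (2.38 / std::sqrt((double)d)) *
                       (am_chol.t() * z);
        const double lp_p = global_logprior(D, gp);
        double ll_p = cur_ll;
        if (std::isfinite(lp_p)) {
          ll_p = total_loglik(D, gp, B, Z, sll_prop, prior_only);
        }
        const double lacc = (ll_p + lp_p) - (cur_ll + cur_lp);
        const bool acc = std::isfinite(lp_p) &&
                         std::log(unif_rand()) < lacc;
        if (acc) {
          g = gp; cur_ll = ll_p; cur_lp = lp_p; sll = sll_prop;
          if (!adapting) acc_joint += 1.0;
        }
        if (!adapting) n_joint += 1.0;
        if (adapting) ls_joint += gam * ((acc ? 1.0 : 0.0) - 0.25);
      }
    }

    // --- random-effects updates (conditionally independent subjects) ---
    for (int i = 0; i < N; ++i) {
      arma::rowvec bi = B.row(i);
      arma::rowvec z(p);
      for (int k = 0; k < p; ++k) z[k] = norm_rand();
      arma::rowvec bp = bi + std::exp(leps[i]) * (z * Sig_cholU);
      const double cur_i = (prior_only ? 0.0 : sll[i]) +
                           re_logprior(bi, Sig_inv, Sig_ldet, p);
      const double ll_i = prior_only ? 0.0 :
          subj_loglik(D, i, g, bp, D.cens[i] == 1 ? Z[i] : -1);
      const double prop_i = ll_i + re_logprior(bp, Sig_inv, Sig_ldet, p);
      const bool acc = std::log(unif_rand()) < (prop_i - cur_i);
      if (acc) {
        B.row(i) = bp;
        if (!prior_only) { cur_ll += ll_i - sll[i]; sll[i] = ll_i; }
        if (!adapting) acc_re[i] += 1.0;
      }
      if (adapting) leps[i] += gam * ((acc ? 1.0 : 0.0) - 0.30);
    }

    // --- Sigma Gibbs step (conjugate inverse-Wishart) ---
    arma::mat S_post = arma::eye(p, p) + B.t() * B;
    Sigma = riwish(S_post, iw_df0 + N);
    Sig_inv = arma::inv_sympd(Sigma);
    Sig_ldet = std::log(arma::det(Sigma));
    Sig_cholU = arma::chol(Sigma);

    // --- cure-status Gibbs step ---
    // P(Z=1 | rest) = eta / (eta + (1-eta) S(tc)) for right-censored
    // subjects; this data augmentation decouples the cure logit from the
    // Weibull parameters and removes the spurious eta ~ 0 trap.
    // Z stays at its initialization (right-censored = immune) throughout
    // warm-up so the Weibull parameters calibrate against the observed
    // events; releasing Z while proposal scales are still adapting can
    // trap a chain in a low-cure-fraction basin. The Z-Gibbs step is
    // exact and needs no adaptation, so switching it on at the end of
    // warm-up leaves the post-warm-up kernel a valid Markov chain.
    if (!prior_only && it >= warmup) {
      const double eta = 1.0 / (1.0 + std::exp(-g[4]));
      for (int i = 0; i < N; ++i) {
        if (D.cens[i] != 1) continue;
        const double Si = surv_tc(D, i, g, B.row(i));
        const double p1 = eta / (eta + (1.0 - eta) * Si);
        const int znew = (unif_rand() < p1) ? 1 : 0;
        if (znew != Z[i]) {
          Z[i] = znew;
          const double ll_i = subj_loglik(D, i, g, B.row(i), znew);
          cur_ll += ll_i - sll[i];
          sll[i] = ll_i;
        }
      }
    }

    // --- record ---
    if (it >= warmup) {
      const int r = it - warmup;
      const double phi = std::exp(g[6]);
      const double al2 = D.mels ? g[8] : 0.0;
      const double lam = g[5] - phi * std::log(D.t0) - g[7] * D.mu_c -
                         al2 * D.s2_c;
      int c = 0;
      keep_g(r, c++) = g[0];
      keep_g(r, c++) = g[1];
      keep_g(r, c++) = g[2];
      if (D.mels) keep_g(r, c++) = g[3];           // theta4
      else        keep_g(r, c++) = std::exp(0.5 * g[3]);  // sigma
      keep_g(r, c++) = g[4];                       // nu
      keep_g(r, c++) = lam;
      keep_g(r, c++) = phi;
      keep_g(r, c++) = g[7];
      if (D.mels) keep_g(r, c++) = g[8];
      for (int a = 0; a < p; ++a)
        for (int bcol = a; bcol < p; ++bcol) keep_g(r, c++) = Sigma(a, bcol);
      // pointwise log-likelihoods are recorded with the cure status
      // marginalized out (the quantity LOO needs)
      for (int i = 0; i < N; ++i) {
        keep_ll(r, i) = (D.cens[i] == 1 && !prior_only)
                            ? subj_loglik(D, i, g, B.row(i), -1)
                            : sll[i];
      }
      keep_tot[r] = cur_ll;
      B_sum += B;
      if (save_re) B_keep.slice(r) = B;
    }
  }

  List out = List::create(
      Named("draws") = keep_g,
      Named("pointwise") = keep_ll,
      Named("total_loglik") = keep_tot,
      Named("b_mean") = B_sum / std::max(1, n_keep),
      Named("accept_component") = acc_comp / std::max(1, n_keep),
      Named("accept_joint") = n_joint > 0 ? acc_joint / n_joint : NA_REAL,
      Named("accept_re_mean") =
          arma::mean(acc_re) / std::max(1, n_keep));
  if (save_re) out["b_draws"] = B_keep;
  return out;
}

// Fast total data log-likelihood (used for cross-checking against the
// R implementation and for utilities that need many evaluations).
// [[Rcpp::export]]
double jm_loglik_cpp(List data, arma::vec g, arma::mat B,
                     arma::vec qx, arma::vec qw,
                     double t0, double mu_c, double s2_c, bool mels) {
  JMData D;
  D.y = as<arma::vec>(data["y"]);
  D.tobs = as<arma::vec>(data["tobs"]);
  D.sub_start = as<arma::ivec>(data["sub_start"]);
  D.sub_len = as<arma::ivec>(data["sub_len"]);
  D.cens = as<arma::ivec>(data["cens"]);
  D.tL = as<arma::vec>(data["tL"]);
  D.tR = as<arma::vec>(data["tR"]);
  D.tc = as<arma::vec>(data["tc"]);
  D.N = D.sub_len.n_elem;
  D.mels = mels;
  D.qx = qx; D.qw = qw;
  D.t0 = t0; D.mu_c = mu_c; D.s2_c = s2_c;
  arma::vec sll(D.N);
  arma::ivec Z(D.N);
  Z.fill(-1);  // marginal over cure status
  return total_loglik(D, g, B, Z, sll, false);
}
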