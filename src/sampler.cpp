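// Gibbs-within-Metropolis sampler for the hierarchical beta regression with
// estimated drought-index timescales.
//
// Sweep order follows the fitting algorithm: (1) Metropolis-Hastings on the
// per-observation logit-mean and log-dispersion latents, (2) Gibbs on the
// normal-linear hierarchy (coefficients, wetland effects, precisions),
// (3) Metropolis-Hastings on the discrete timescales, repeat.
//
// All randomness comes from R's RNG so chains are reproducible from set.seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static inline double inv_logit(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// log Beta(y; mu*phi, (1-mu)*phi)
static inline double beta_lpdf(double y, double mu, double phi) {
  double a = mu * phi, b = (1.0 - mu) * phi;
  return (a - 1.0) * std::log(y) + (b - 1.0) * std::log1p(-y) -
         (std::lgamma(a) + std::lgamma(b) - std::lgamma(a + b));
}

// symmetric integer window proposal, reflected at the grid edges
static inline int propose_t(int t, int w, int K) {
  int r = (int)(R::unif_rand() * (2 * w));
  if (r >= 2 * w) r = 2 * w - 1;  // guard unif_rand() == 1
  int u = r - w;
  if (u >= 0) u += 1;
  // reflect about the half-integer boundaries 0.5 and K + 0.5; this keeps
  // the proposal symmetric (q(t -> t') = q(t' -> t)) at the grid edges
  int j = t + u;
  while (j < 1 || j > K) {
    if (j < 1) j = 1 - j;
    else j = 2 * K + 1 - j;
  }
  return j;
}

// linear predictor of the mean model given the era-specific SPEI covariate s
// and the SPI covariate p
static arma::vec lin_pred(const arma::vec& beta, const arma::ivec& era,
                          const arma::vec& s, const arma::vec& p) {
  int N = era.n_elem;
  arma::vec lp(N);
  for (int i = 0; i < N; ++i) {
    double e = era[i];
    lp[i] = beta[0] + beta[1] * e + s[i] * (beta[2] + beta[4] * e) +
            beta[3] * p[i] + s[i] * p[i] * (beta[5] + beta[6] * e);
  }
  return lp;
}

// [[Rcpp::export]]
List run_chain_cpp(const arma::vec& y, const arma::ivec& wid,
                   const arma::ivec& era, const arma::mat& spei,
                   const arma::mat& spi, List init, List priors, List ctrl) {
  const int N = y.n_elem;
  const int I = arma::max(wid) + 1;
  const int Ks = spei.n_cols, Kp = spi.n_cols;

  // --- control ---------------------------------------------------------
  const int n_burn = as<int>(ctrl["burnin"]);
  const int n_iter = as<int>(ctrl["iter"]);
  const int thin = as<int>(ctrl["thin"]);
  double step_mu = as<double>(ctrl["step_mu"]);
  double step_phi = as<double>(ctrl["step_phi"]);
  int win_s = as<int>(ctrl["window_spei"]);
  int win_p = as<int>(ctrl["window_spi"]);
  const bool adapt = as<bool>(ctrl["adapt"]);
  const bool store_latents = as<bool>(ctrl["store_latents"]);
  List upd = ctrl["updates"];
  const bool upd_l = as<bool>(upd["latent_mu"]);
  const bool upd_m = as<bool>(upd["latent_phi"]);
  const bool upd_beta = as<bool>(upd["beta_mu"]);
  const bool upd_gamma = as<bool>(upd["gamma"]);
  const bool upd_bphi = as<bool>(upd["beta_phi"]);
  const bool upd_eps = as<bool>(upd["eps"]);
  const bool upd_prec = as<bool>(upd["precisions"]);
  const bool upd_t = as<bool>(upd["timescales"]);
  const bool upd_iw = as<bool>(upd["interweave"]);
  if (win_s > Ks - 1) win_s = Ks > 1 ? Ks - 1 : 1;
  if (win_p > Kp - 1) win_p = Kp > 1 ? Kp - 1 : 1;

  // --- priors ----------------------------------------------------------
  arma::vec bmean = as<arma::vec>(priors["beta_mean"]);
  arma::vec bprec = as<arma::vec>(priors["beta_precision"]);
  const double bphi_mean = as<double>(priors["bphi_mean"]);
  const double bphi_prec = as<double>(priors["bphi_precision"]);
  const double ta = as<double>(priors["tau_shape"]);
  const double tb = as<double>(priors["tau_rate"]);

  // --- state -----------------------------------------------------------
  arma::vec beta = as<arma::vec>(init["beta"]);
  double bphi = as<double>(init["bphi"]);
  arma::vec gam = as<arma::vec>(init["gamma"]);
  arma::vec eps = as<arma::vec>(init["eps"]);
  arma::vec l = as<arma::vec>(init["l"]);
  arma::vec m = as<arma::vec>(init["m"]);
  double tau_g = as<double>(init["tau_gamma"]);
  double tau_d = as<double>(init["tau_delta"]);
  double tau_e = as<double>(init["tau_eps"]);
  double tau_z = as<double>(init["tau_zeta"]);
  int t_h = as<int>(init["t_hist"]);
  int t_c = as<int>(init["t_cont"]);
  int t_s = as<int>(init["t_spi"]);

  arma::ivec ni(I, arma::fill::zeros);
  for (int i = 0; i < N; ++i) ni[wid[i]] += 1;

  arma::vec s(N), p(N);
  for (int i = 0; i < N; ++i) {
    s[i] = era[i] == 0 ? spei(i, t_h - 1) : spei(i, t_c - 1);
    p[i] = spi(i, t_s - 1);
  }
  arma::vec lp = lin_pred(beta, era, s, p);

  // cached per-observation beta log-likelihood at the current latents
  arma::vec ll(N);
  for (int i = 0; i < N; ++i)
    ll[i] = beta_lpdf(y[i], inv_logit(l[i]), std::exp(m[i]));

  // initialization sanity: the joint must be finite
  {
    double check = 0.0;
    for (int i = 0; i < N; ++i)
      check += ll[i] - 0.5 * tau_d * std::pow(l[i] - lp[i] - gam[wid[i]], 2);
    if (!std::isfinite(check))
      stop("non-finite log-joint at initialization (latent mean/dispersion)");
  }

  // rows belonging to each era, for timescale updates
  std::vector<int> rows0, rows1;
  for (int i = 0; i < N; ++i) (era[i] == 0 ? rows0 : rows1).push_back(i);

  const int n_keep = n_iter / thin;
  const int n_scalar = 7 + 1 + 4 + 3;
  arma::mat draws(n_keep, n_scalar);
  arma::mat gamma_draws(n_keep, I), eps_draws(n_keep, I);
  arma::mat l_draws, m_draws;
  if (store_latents) { l_draws.set_size(n_keep, N); m_draws.set_size(n_keep, N); }

  long acc_l = 0, acc_m = 0, acc_th = 0, acc_tc = 0, acc_ts = 0;
  long win_acc_l = 0, win_acc_m = 0;  // adaptation windows (burn-in only)
  int kept = 0;

  for (int it = 1; it <= n_burn + n_iter; ++it) {
    const bool post = it > n_burn;

    // ---- step 1a: M-H on logit-mean latents --------------------------
    if (upd_l) {
      for (int i = 0; i < N; ++i) {
        double em = lp[i] + gam[wid[i]];
        double phi_i = std::exp(m[i]);
        double lcur = l[i];
        double lnew = lcur + step_mu * R::norm_rand();
        double ll_new = beta_lpdf(y[i], inv_logit(lnew), phi_i);
        double d = ll_new - ll[i] -
                   0.5 * tau_d * (std::pow(lnew - em, 2) -
                                  std::pow(lcur - em, 2));
        if (d >= 0.0 || R::unif_rand() < std::exp(d)) {
          l[i] = lnew;
          ll[i] = ll_new;
          if (post) acc_l++; else win_acc_l++;
        }
      }
    }

    // ---- step 1b: M-H on log-dispersion latents ----------------------
    if (upd_m) {
      for (int i = 0; i < N; ++i) {
        double ep = bphi + eps[wid[i]];
        double mu_i = inv_logit(l[i]);
        double mcur = m[i];
        double mnew = mcur + step_phi * R::norm_rand();
        double ll_new = beta_lpdf(y[i], mu_i, std::exp(mnew));
        double d = ll_new - ll[i] -
                   0.5 * tau_z * (std::pow(mnew - ep, 2) -
                                  std::pow(mcur - ep, 2));
        if (d >= 0.0 || R::unif_rand() < std::exp(d)) {
          m[i] = mnew;
          ll[i] = ll_new;
          if (post) acc_m++; else win_acc_m++;
        }
      }
    }

    // burn-in-only step adaptation toward 0.44 acceptance
    if (adapt && !post && it % 50 == 0) {
      if (upd_l) {
        double r = (double)win_acc_l / (50.0 * N);
        step_mu = std::min(5.0, std::max(0.01, step_mu * std::exp(r - 0.44)));
      }
      if (upd_m) {
        double r = (double)win_acc_m / (50.0 * N);
        step_phi = std::min(5.0, std::max(0.01, step_phi * std::exp(r - 0.44)));
      }
      win_acc_l = win_acc_m = 0;
    }

    // ---- step 2: Gibbs on the normal-linear hierarchy ----------------
    if (upd_beta) {
      arma::mat X(N, 7);
      for (int i = 0; i < N; ++i) {
        double e = era[i];
        X(i, 0) = 1.0; X(i, 1) = e; X(i, 2) = s[i]; X(i, 3) = p[i];
        X(i, 4) = s[i] * e; X(i, 5) = s[i] * p[i]; X(i, 6) = s[i] * p[i] * e;
      }
      arma::vec resp = l;
      for (int i = 0; i < N; ++i) resp[i] -= gam[wid[i]];
      arma::mat A = tau_d * (X.t() * X);
      A.diag() += bprec;
      arma::vec rhs = tau_d * (X.t() * resp) + bprec % bmean;
      arma::mat R = arma::chol(A);  // A = R'R, R upper
      arma::vec z(7);
      for (int k = 0; k < 7; ++k) z[k] = R::norm_rand();
      beta = arma::solve(A, rhs, arma::solve_opts::likely_sympd) +
             arma::solve(arma::trimatu(R), z);
      lp = lin_pred(beta, era, s, p);
    }

    if (upd_gamma) {
      arma::vec sum_res(I, arma::fill::zeros);
      for (int i = 0; i < N; ++i) sum_res[wid[i]] += l[i] - lp[i];
      for (int g = 0; g < I; ++g) {
        double prec = tau_g + ni[g] * tau_d;
        double mean = tau_d * sum_res[g] / prec;
        gam[g] = mean + R::norm_rand() / std::sqrt(prec);
      }
    }

    if (upd_bphi) {
      double sum_res = 0.0;
      for (int i = 0; i < N; ++i) sum_res += m[i] - eps[wid[i]];
      double prec = bphi_prec + N * tau_z;
      double mean = (bphi_prec * bphi_mean + tau_z * sum_res) / prec;
      bphi = mean + R::norm_rand() / std::sqrt(prec);
    }

    if (upd_eps) {
      arma::vec sum_res(I, arma::fill::zeros);
      for (int i = 0; i < N; ++i) sum_res[wid[i]] += m[i] - bphi;
      for (int g = 0; g < I; ++g) {
        double prec = tau_e + ni[g] * tau_z;
        double mean = tau_z * sum_res[g] / prec;
        eps[g] = mean + R::norm_rand() / std::sqrt(prec);
      }
    }

    if (upd_prec) {
      double ss_g = arma::dot(gam, gam);
      double ss_e = arma::dot(eps, eps);
      double ss_d = 0.0, ss_z = 0.0;
      for (int i = 0; i < N; ++i) {
        double d1 = l[i] - lp[i] - gam[wid[i]];
        double d2 = m[i] - bphi - eps[wid[i]];
        ss_d += d1 * d1;
        ss_z += d2 * d2;
      }
      tau_g = R::rgamma(ta + 0.5 * I, 1.0 / (tb + 0.5 * ss_g));
      tau_d = R::rgamma(ta + 0.5 * N, 1.0 / (tb + 0.5 * ss_d));
      tau_e = R::rgamma(ta + 0.5 * I, 1.0 / (tb + 0.5 * ss_e));
      tau_z = R::rgamma(ta + 0.5 * N, 1.0 / (tb + 0.5 * ss_z));
    }

    // ---- interweaving (ASIS) re-update of the precisions -------------
    // After the sufficient-parameterization Gibbs draw, each precision is
    // re-updated by a scalar M-H step in which the ANCILLARY effects
    // (effects rescaled by the current precision) are held fixed. This
    // breaks the precision/effect funnel that makes plain Gibbs mix slowly
    // when a variance component is weakly identified.
    if (upd_iw && upd_prec) {
      // wetland mean effects: gamma_t = sqrt(tau_g) * gamma fixed
      if (upd_gamma) {
        arma::vec S(I, arma::fill::zeros);
        for (int i = 0; i < N; ++i) S[wid[i]] += l[i] - lp[i];
        double sum_gS = 0.0, sum_ng2 = 0.0;
        for (int g = 0; g < I; ++g) {
          double gt = std::sqrt(tau_g) * gam[g];
          sum_gS += gt * S[g];
          sum_ng2 += ni[g] * gt * gt;
        }
        double lt = std::log(tau_g);
        double ltn = lt + 0.5 * R::norm_rand();
        double tn = std::exp(ltn);
        double c0 = 1.0 / std::sqrt(tau_g), c1 = 1.0 / std::sqrt(tn);
        double d = -0.5 * tau_d * ((c1 * c1 - c0 * c0) * sum_ng2 -
                                   2.0 * (c1 - c0) * sum_gS) +
                   ta * (ltn - lt) - tb * (tn - tau_g);
        if (d >= 0.0 || R::unif_rand() < std::exp(d)) {
          gam *= std::sqrt(tau_g) * c1;
          tau_g = tn;
        }
      }
      // wetland dispersion effects: eps_t = sqrt(tau_e) * eps fixed
      if (upd_eps) {
        arma::vec S(I, arma::fill::zeros);
        for (int i = 0; i < N; ++i) S[wid[i]] += m[i] - bphi;
        double sum_eS = 0.0, sum_ne2 = 0.0;
        for (int g = 0; g < I; ++g) {
          double et = std::sqrt(tau_e) * eps[g];
          sum_eS += et * S[g];
          sum_ne2 += ni[g] * et * et;
        }
        double lt = std::log(tau_e);
        double ltn = lt + 0.5 * R::norm_rand();
        double tn = std::exp(ltn);
        double c0 = 1.0 / std::sqrt(tau_e), c1 = 1.0 / std::sqrt(tn);
        double d = -0.5 * tau_z * ((c1 * c1 - c0 * c0) * sum_ne2 -
                                   2.0 * (c1 - c0) * sum_eS) +
                   ta * (ltn - lt) - tb * (tn - tau_e);
        if (d >= 0.0 || R::unif_rand() < std::exp(d)) {
          eps *= std::sqrt(tau_e) * c1;
          tau_e = tn;
        }
      }
      // translation move for the dispersion intercept: the ancillary
      // residuals zeta (and eps) ride along, so all m shift together and
      // the move is limited only by the beta likelihood, not by the random
      // walk speed of the latents
      if (upd_bphi && upd_m) {
        for (int rep = 0; rep < 2; ++rep) {
          double shift = 0.15 * R::norm_rand();
          double bphi_new = bphi + shift;
          double d = -0.5 * bphi_prec * (std::pow(bphi_new - bphi_mean, 2) -
                                         std::pow(bphi - bphi_mean, 2));
          arma::vec ll_new(N);
          for (int i = 0; i < N; ++i) {
            ll_new[i] = beta_lpdf(y[i], inv_logit(l[i]),
                                  std::exp(m[i] + shift));
            d += ll_new[i] - ll[i];
          }
          if (std::isfinite(d) &&
              (d >= 0.0 || R::unif_rand() < std::exp(d))) {
            bphi = bphi_new; m += shift; ll = ll_new;
          }
        }
      }
      // per-wetland translation of the dispersion effect with its
      // observations' residuals held fixed
      if (upd_eps && upd_m) {
        for (int g = 0; g < I; ++g) {
          double shift = 0.4 * R::norm_rand();
          double en = eps[g] + shift;
          double d = -0.5 * tau_e * (en * en - eps[g] * eps[g]);
          // likelihood over this wetland's observations
          bool ok = true;
          std::vector<std::pair<int, double> > upd_ll;
          for (int i = 0; i < N; ++i) {
            if (wid[i] != g) continue;
            double lln = beta_lpdf(y[i], inv_logit(l[i]),
                                   std::exp(m[i] + shift));
            if (!std::isfinite(lln)) { ok = false; break; }
            upd_ll.push_back(std::make_pair(i, lln));
            d += lln - ll[i];
          }
          if (ok && std::isfinite(d) &&
              (d >= 0.0 || R::unif_rand() < std::exp(d))) {
            eps[g] = en;
            for (size_t r = 0; r < upd_ll.size(); ++r) {
              m[upd_ll[r].first] += shift;
              ll[upd_ll[r].first] = upd_ll[r].second;
            }
          }
        }
      }
      // observation-level dispersion residuals: zeta_t = sqrt(tau_z) * zeta
      if (upd_m) {
        double lt = std::log(tau_z);
        double ltn = lt + 0.5 * R::norm_rand();
        double tn = std::exp(ltn);
        double ratio = std::sqrt(tau_z / tn);
        double d = ta * (ltn - lt) - tb * (tn - tau_z);
        arma::vec m_new(N), ll_new(N);
        for (int i = 0; i < N; ++i) {
          double base = bphi + eps[wid[i]];
          m_new[i] = base + ratio * (m[i] - base);
          ll_new[i] = beta_lpdf(y[i], inv_logit(l[i]), std::exp(m_new[i]));
          d += ll_new[i] - ll[i];
        }
        if (std::isfinite(d) &&
            (d >= 0.0 || R::unif_rand() < std::exp(d))) {
          m = m_new; ll = ll_new; tau_z = tn;
        }
      }
    }

    // ---- step 3: M-H on the discrete timescales ----------------------
    if (upd_t) {
      // era-specific SPEI timescales: only that era's rows change
      for (int which = 0; which < 2 && Ks > 1; ++which) {
        const std::vector<int>& rows = which == 0 ? rows0 : rows1;
        int tcur = which == 0 ? t_h : t_c;
        int tn = propose_t(tcur, win_s, Ks);
        if (tn == tcur) { if (post) { if (which == 0) acc_th++; else acc_tc++; } continue; }
        double e = (double)which;
        double d = 0.0;
        for (size_t r = 0; r < rows.size(); ++r) {
          int i = rows[r];
          double sn = spei(i, tn - 1);
          double lp_new = beta[0] + beta[1] * e +
                          sn * (beta[2] + beta[4] * e) + beta[3] * p[i] +
                          sn * p[i] * (beta[5] + beta[6] * e);
          double g = gam[wid[i]];
          d -= 0.5 * tau_d * (std::pow(l[i] - lp_new - g, 2) -
                              std::pow(l[i] - lp[i] - g, 2));
        }
        if (d >= 0.0 || R::unif_rand() < std::exp(d)) {
          for (size_t r = 0; r < rows.size(); ++r) {
            int i = rows[r];
            s[i] = spei(i, tn - 1);
            lp[i] = beta[0] + beta[1] * e + s[i] * (beta[2] + beta[4] * e) +
                    beta[3] * p[i] + s[i] * p[i] * (beta[5] + beta[6] * e);
          }
          if (which == 0) t_h = tn; else t_c = tn;
          if (post) { if (which == 0) acc_th++; else acc_tc++; }
        }
      }
      // shared SPI timescale: all rows change
      if (Kp > 1) {
        int tn = propose_t(t_s, win_p, Kp);
        if (tn != t_s) {
          double d = 0.0;
          for (int i = 0; i < N; ++i) {
            double e = era[i];
            double pn = spi(i, tn - 1);
            double lp_new = beta[0] + beta[1] * e +
                            s[i] * (beta[2] + beta[4] * e) + beta[3] * pn +
                            s[i] * pn * (beta[5] + beta[6] * e);
            double g = gam[wid[i]];
            d -= 0.5 * tau_d * (std::pow(l[i] - lp_new - g, 2) -
                                std::pow(l[i] - lp[i] - g, 2));
          }
          if (d >= 0.0 || R::unif_rand() < std::exp(d)) {
            t_s = tn;
            p = spi.col(tn - 1);
            lp = lin_pred(beta, era, s, p);
            if (post) acc_ts++;
          }
        } else if (post) acc_ts++;
      }
    }

    // ---- storage ------------------------------------------------------
    if (post && (it - n_burn) % thin == 0 && kept < n_keep) {
      int r = kept++;
      for (int k = 0; k < 7; ++k) draws(r, k) = beta[k];
      draws(r, 7) = bphi;
      draws(r, 8) = tau_g; draws(r, 9) = tau_d;
      draws(r, 10) = tau_e; draws(r, 11) = tau_z;
      draws(r, 12) = t_h; draws(r, 13) = t_c; draws(r, 14) = t_s;
      gamma_draws.row(r) = gam.t();
      eps_draws.row(r) = eps.t();
      if (store_latents) { l_draws.row(r) = l.t(); m_draws.row(r) = m.t(); }
    }
  }

  double denom = (double)n_iter * N;
  List acc = List::create(
    _["latent_mu"] = upd_l ? acc_l / denom : NA_REAL,
    _["latent_phi"] = upd_m ? acc_m / denom : NA_REAL,
    _["t_hist"] = (upd_t && Ks > 1) ? acc_th / (double)n_iter : NA_REAL,
    _["t_cont"] = (upd_t && Ks > 1) ? acc_tc / (double)n_iter : NA_REAL,
    _["t_spi"] = (upd_t && Kp > 1) ? acc_ts / (double)n_iter : NA_REAL);

  List out = List::create(
    _["draws"] = draws, _["gamma"] = gamma_draws, _["eps"] = eps_draws,
    _["acceptance"] = acc,
    _["steps"] = NumericVector::create(step_mu, step_phi));
  if (store_latents) { out["l"] = l_draws; out["m"] = m_draws; }
  return out;
}
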