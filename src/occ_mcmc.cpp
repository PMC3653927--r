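// Metropolis-within-Gibbs sampler for the data-augmented hierarchical
// multispecies multiyear occupancy model.
//
// Data: d[i,l,j] = number of detections of species i at point l in year j
// over K exchangeable visits (binary per-visit detections collapsed to a
// binomial count). Augmented species (all-zero histories) extend the n
// observed species to a superpopulation of M.
//
// Model:
//   w_i ~ Bern(Omega)                       (community membership)
//   z_ilj | w_i ~ Bern(w_i * psi_il),  logit(psi_il) = u_i + X_l' beta_i
//   d_ilj | z_ilj ~ Binomial(K, z_ilj * p_il), logit(p_il) = v_i + X_l' betap_i
//   (u_i, v_i) ~ BVN((mu_u, mu_v), Sigma(sigma_u, sigma_v, rho))
//   beta_ic ~ N(mu_beta_c, sigma_beta_c),  betap_ic ~ N(mu_betap_c, sigma_betap_c)
// Priors: Omega ~ U(0,1); means ~ N(0, 10^2); SDs ~ U(0, 10); rho ~ U(-1,1).
//
// Updates: w marginal over z (exact Bernoulli), z exact Bernoulli, Omega
// conjugate Beta, community means conjugate normal, species-level and
// remaining hyperparameters by Gaussian random-walk Metropolis with
// Robbins-Monro adaptation (target acceptance 0.44) during burn-in only.
// Species with w = 0 and no detections have no likelihood contribution and
// are redrawn from the community distribution (exact Gibbs).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double invlogit(double x) { return 1.0 / (1.0 + std::exp(-x)); }
static inline double clamp01(double p) {
  const double eps = 1e-12;
  if (p < eps) return eps;
  if (p > 1.0 - eps) return 1.0 - eps;
  return p;
}

struct Adapt {
  double lscale;      // log proposal sd
  double acc, try_;   // batch counters
  int batch;
  Adapt(double s0 = -0.7) : lscale(s0), acc(0), try_(0), batch(0) {}
  double sd() const { return std::exp(lscale); }
  void tally(bool a) { try_ += 1; if (a) acc += 1; }
  void maybe_adapt(bool burning) {
    if (try_ >= 50) {
      if (burning) {
        ++batch;
        double rate = acc / try_;
        lscale += (rate - 0.44) / std::sqrt((double)batch);
        if (lscale < -8) lscale = -8;
        if (lscale > 3) lscale = 3;
      }
      acc = 0; try_ = 0;
    }
  }
};

// log N(x; m, s)
static inline double ldnorm(double x, double m, double s) {
  double z = (x - m) / s;
  return -0.91893853320467274 - std::log(s) - 0.5 * z * z;
}

// log BVN(u, v) with means mu, mv, sds su, sv, correlation rho
static inline double ldbvn(double u, double v, double mu, double mv,
                           double su, double sv, double rho) {
  double zu = (u - mu) / su, zv = (v - mv) / sv;
  double om = 1.0 - rho * rho;
  return -std::log(2.0 * M_PI * su * sv * std::sqrt(om)) -
         (zu * zu - 2.0 * rho * zu * zv + zv * zv) / (2.0 * om);
}

// [[Rcpp::export(name = ".occ_mcmc_chain")]]
List occ_mcmc_chain(const IntegerVector& d_flat, // n_obs * L * J, i fastest
                    int n_obs, int L, int J, int K,
                    const NumericMatrix& X,      // L x C standardized covariates
                    int n_aug, int n_iter, int n_burn, int thin,
                    double prior_mean_sd, double prior_sd_max) {
  const int M = n_obs + n_aug;
  const int C = X.ncol();
  RNGScope scope;

  // --- data summaries ---------------------------------------------------
  std::vector<int> d(M * L * J, 0);           // detections per (i,l,j)
  for (int j = 0; j < J; ++j)
    for (int l = 0; l < L; ++l)
      for (int i = 0; i < n_obs; ++i)
        d[(size_t)i + (size_t)M * (l + (size_t)L * j)] =
            d_flat[i + n_obs * (l + L * j)];
  std::vector<int> dsum(M * L, 0);            // detections per (i,l) over years
  std::vector<bool> everdet(M, false);
  for (int i = 0; i < M; ++i)
    for (int l = 0; l < L; ++l) {
      int s = 0;
      for (int j = 0; j < J; ++j) s += d[(size_t)i + (size_t)M * (l + (size_t)L * j)];
      dsum[i + M * l] = s;
      if (s > 0) everdet[i] = true;
    }

  // --- state ------------------------------------------------------------
  std::vector<double> u(M), v(M), B(M * C), Bp(M * C);
  std::vector<int> w(M, 0);
  std::vector<int> z(M * L * J, 0);
  double mu_u = R::rnorm(0.0, 1.0), mu_v = R::rnorm(0.0, 1.0);
  double sig_u = R::runif(0.5, 2.0), sig_v = R::runif(0.5, 2.0);
  double rho = R::runif(-0.5, 0.5);
  std::vector<double> mu_b(C), sig_b(C), mu_bp(C), sig_bp(C);
  for (int c = 0; c < C; ++c) {
    mu_b[c] = R::rnorm(0.0, 0.5);  sig_b[c] = R::runif(0.3, 1.0);
    mu_bp[c] = R::rnorm(0.0, 0.5); sig_bp[c] = R::runif(0.3, 1.0);
  }
  double Omega = R::runif(0.2, 0.8);
  // species params from the community distribution given initial hypers
  for (int i = 0; i < M; ++i) {
    double z1 = R::norm_rand(), z2 = R::norm_rand();
    u[i] = mu_u + sig_u * z1;
    v[i] = mu_v + sig_v * (rho * z1 + std::sqrt(1.0 - rho * rho) * z2);
    for (int c = 0; c < C; ++c) {
      B[i + M * c] = R::rnorm(mu_b[c], sig_b[c]);
      Bp[i + M * c] = R::rnorm(mu_bp[c], sig_bp[c]);
    }
  }
  for (int i = 0; i < M; ++i)
    w[i] = everdet[i] ? 1 : (R::unif_rand() < 0.5 ? 1 : 0);
  for (int i = 0; i < M; ++i)
    for (int l = 0; l < L; ++l)
      for (int j = 0; j < J; ++j) {
        size_t id = (size_t)i + (size_t)M * (l + (size_t)L * j);
        z[id] = d[id] > 0 ? 1 : 0;
      }

  // adaptation state: one scale per parameter block
  Adapt ad_u, ad_v, ad_su(-1.6), ad_sv(-1.6), ad_rho(-1.6);
  std::vector<Adapt> ad_B(C), ad_Bp(C), ad_sb(C, Adapt(-1.6)),
      ad_sbp(C, Adapt(-1.6));

  // workspaces
  std::vector<double> psi(M * L), p(M * L);
  std::vector<int> nz(M * L);                 // years occupied per (i,l)

  // --- output -----------------------------------------------------------
  const int n_keep = (n_iter - n_burn) / thin;
  NumericMatrix out_u(n_keep, M), out_v(n_keep, M);
  NumericMatrix out_B(n_keep, M * C), out_Bp(n_keep, M * C);
  IntegerMatrix out_w(n_keep, M);
  const int NH = 5 + 4 * C + 2;               // hypers + Omega + Ntot
  NumericMatrix out_h(n_keep, NH);
  IntegerVector out_zok(n_keep); // 1 iff z = 1 at every observed detection
  int keep = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool burning = iter <= n_burn;

    // linear predictors -> psi, p
    for (int i = 0; i < M; ++i)
      for (int l = 0; l < L; ++l) {
        double ep = u[i], edet = v[i];
        for (int c = 0; c < C; ++c) {
          ep += X(l, c) * B[i + M * c];
          edet += X(l, c) * Bp[i + M * c];
        }
        psi[i + M * l] = clamp01(invlogit(ep));
        p[i + M * l] = clamp01(invlogit(edet));
      }

    // ---- w: marginal over z for never-detected species ----
    for (int i = 0; i < M; ++i) {
      if (everdet[i]) { w[i] = 1; continue; }
      double logq = 0.0;
      for (int l = 0; l < L; ++l) {
        double ps = psi[i + M * l], pd = p[i + M * l];
        double q0 = ps * std::pow(1.0 - pd, K) + (1.0 - ps);
        logq += J * std::log(q0);
      }
      double a = std::log(Omega) + logq, b = std::log1p(-Omega);
      double pw = 1.0 / (1.0 + std::exp(b - a));
      w[i] = (R::unif_rand() < pw) ? 1 : 0;
    }

    // ---- z | w ----
    for (int i = 0; i < M; ++i) {
      if (w[i] == 0) {
        for (int l = 0; l < L; ++l) {
          nz[i + M * l] = 0;
          for (int j = 0; j < J; ++j)
            z[(size_t)i + (size_t)M * (l + (size_t)L * j)] = 0;
        }
        continue;
      }
      for (int l = 0; l < L; ++l) {
        double ps = psi[i + M * l], pd = p[i + M * l];
        double num = ps * std::pow(1.0 - pd, K);
        double pz = num / (num + (1.0 - ps));
        int cnt = 0;
        for (int j = 0; j < J; ++j) {
          size_t id = (size_t)i + (size_t)M * (l + (size_t)L * j);
          if (d[id] > 0) z[id] = 1;
          else z[id] = (R::unif_rand() < pz) ? 1 : 0;
          cnt += z[id];
        }
        nz[i + M * l] = cnt;
      }
    }

    // ---- Omega ----
    int sw = 0;
    for (int i = 0; i < M; ++i) sw += w[i];
    Omega = R::rbeta(1.0 + sw, 1.0 + M - sw);

    // ---- species-level parameters ----
    const double om = 1.0 - rho * rho;
    const double cond_s_u = sig_u * std::sqrt(om);
    const double cond_s_v = sig_v * std::sqrt(om);
    for (int i = 0; i < M; ++i) {
      if (w[i] == 0 && !everdet[i]) {
        // no data: exact draw from the community distribution
        double z1 = R::norm_rand(), z2 = R::norm_rand();
        u[i] = mu_u + sig_u * z1;
        v[i] = mu_v + sig_v * (rho * z1 + std::sqrt(om) * z2);
        for (int c = 0; c < C; ++c) {
          B[i + M * c] = R::rnorm(mu_b[c], sig_b[c]);
          Bp[i + M * c] = R::rnorm(mu_bp[c], sig_bp[c]);
        }
        continue;
      }

      // occupancy loglik as a function of (u_i, B_i.)
      // ll_occ = sum_l nz*log(psi) + (J - nz)*log(1 - psi)
      // detection loglik as a function of (v_i, Bp_i.)
      // ll_det = sum_l dsum*log(p) + (K*nz - dsum)*log(1 - p)

      // u_i
      {
        double prop = u[i] + R::norm_rand() * ad_u.sd();
        double ll0 = 0.0, ll1 = 0.0;
        for (int l = 0; l < L; ++l) {
          double eta = 0.0;
          for (int c = 0; c < C; ++c) eta += X(l, c) * B[i + M * c];
          double ps0 = clamp01(invlogit(u[i] + eta));
          double ps1 = clamp01(invlogit(prop + eta));
          int k = nz[i + M * l];
          ll0 += k * std::log(ps0) + (J - k) * std::log1p(-ps0);
          ll1 += k * std::log(ps1) + (J - k) * std::log1p(-ps1);
        }
        double m = mu_u + rho * (sig_u / sig_v) * (v[i] - mu_v);
        double lp = ldnorm(prop, m, cond_s_u) - ldnorm(u[i], m, cond_s_u);
        bool acc = std::log(R::unif_rand()) < (ll1 - ll0 + lp);
        if (acc) u[i] = prop;
        ad_u.tally(acc);
      }
      // beta_ic
      for (int c = 0; c < C; ++c) {
        double cur = B[i + M * c];
        double prop = cur + R::norm_rand() * ad_B[c].sd();
        double ll0 = 0.0, ll1 = 0.0;
        for (int l = 0; l < L; ++l) {
          double eta = u[i];
          for (int c2 = 0; c2 < C; ++c2)
            if (c2 != c) eta += X(l, c2) * B[i + M * c2];
          double ps0 = clamp01(invlogit(eta + X(l, c) * cur));
          double ps1 = clamp01(invlogit(eta + X(l, c) * prop));
          int k = nz[i + M * l];
          ll0 += k * std::log(ps0) + (J - k) * std::log1p(-ps0);
          ll1 += k * std::log(ps1) + (J - k) * std::log1p(-ps1);
        }
        double lp = ldnorm(prop, mu_b[c], sig_b[c]) -
                    ldnorm(cur, mu_b[c], sig_b[c]);
        bool acc = std::log(R::unif_rand()) < (ll1 - ll0 + lp);
        if (acc) B[i + M * c] = prop;
        ad_B[c].tally(acc);
      }
      // v_i
      {
        double prop = v[i] + R::norm_rand() * ad_v.sd();
        double ll0 = 0.0, ll1 = 0.0;
        for (int l = 0; l < L; ++l) {
          int k = nz[i + M * l];
          if (k == 0) continue;
          int s = dsum[i + M * l];
          double eta = 0.0;
          for (int c = 0; c < C; ++c) eta += X(l, c) * Bp[i + M * c];
          double p0 = clamp01(invlogit(v[i] + eta));
          double p1 = clamp01(invlogit(prop + eta));
          ll0 += s * std::log(p0) + (K * k - s) * std::log1p(-p0);
          ll1 += s * std::log(p1) + (K * k - s) * std::log1p(-p1);
        }
        double m = mu_v + rho * (sig_v / sig_u) * (u[i] - mu_u);
        double lp = ldnorm(prop, m, cond_s_v) - ldnorm(v[i], m, cond_s_v);
        bool acc = std::log(R::unif_rand()) < (ll1 - ll0 + lp);
        if (acc) v[i] = prop;
        ad_v.tally(acc);
      }
      // betap_ic
      for (int c = 0; c < C; ++c) {
        double cur = Bp[i + M * c];
        double prop = cur + R::norm_rand() * ad_Bp[c].sd();
        double ll0 = 0.0, ll1 = 0.0;
        for (int l = 0; l < L; ++l) {
          int k = nz[i + M * l];
          if (k == 0) continue;
          int s = dsum[i + M * l];
          double eta = v[i];
          for (int c2 = 0; c2 < C; ++c2)
            if (c2 != c) eta += X(l, c2) * Bp[i + M * c2];
          double p0 = clamp01(invlogit(eta + X(l, c) * cur));
          double p1 = clamp01(invlogit(eta + X(l, c) * prop));
          ll0 += s * std::log(p0) + (K * k - s) * std::log1p(-p0);
          ll1 += s * std::log(p1) + (K * k - s) * std::log1p(-p1);
        }
        double lp = ldnorm(prop, mu_bp[c], sig_bp[c]) -
                    ldnorm(cur, mu_bp[c], sig_bp[c]);
        bool acc = std::log(R::unif_rand()) < (ll1 - ll0 + lp);
        if (acc) Bp[i + M * c] = prop;
        ad_Bp[c].tally(acc);
      }
    }
    ad_u.maybe_adapt(burning); ad_v.maybe_adapt(burning);
    for (int c = 0; c < C; ++c) {
      ad_B[c].maybe_adapt(burning); ad_Bp[c].maybe_adapt(burning);
    }

    // ---- hyperparameters ----
    const double prior_prec = 1.0 / (prior_mean_sd * prior_mean_sd);
    // mu_u | rest: residuals r_i = u_i - rho*su/sv*(v_i - mu_v) ~ N(mu_u, su^2(1-rho^2))
    {
      double s2 = sig_u * sig_u * (1.0 - rho * rho);
      double sum = 0.0;
      for (int i = 0; i < M; ++i)
        sum += u[i] - rho * (sig_u / sig_v) * (v[i] - mu_v);
      double prec = M / s2 + prior_prec;
      mu_u = R::rnorm((sum / s2) / prec, std::sqrt(1.0 / prec));
    }
    {
      double s2 = sig_v * sig_v * (1.0 - rho * rho);
      double sum = 0.0;
      for (int i = 0; i < M; ++i)
        sum += v[i] - rho * (sig_v / sig_u) * (u[i] - mu_u);
      double prec = M / s2 + prior_prec;
      mu_v = R::rnorm((sum / s2) / prec, std::sqrt(1.0 / prec));
    }
    // sigma_u, sigma_v, rho by Metropolis on the joint BVN likelihood
    {
      double cur_ll = 0.0;
      for (int i = 0; i < M; ++i)
        cur_ll += ldbvn(u[i], v[i], mu_u, mu_v, sig_u, sig_v, rho);
      // sigma_u
      double prop = sig_u + R::norm_rand() * ad_su.sd();
      if (prop > 0 && prop < prior_sd_max) {
        double ll1 = 0.0;
        for (int i = 0; i < M; ++i)
          ll1 += ldbvn(u[i], v[i], mu_u, mu_v, prop, sig_v, rho);
        bool acc = std::log(R::unif_rand()) < (ll1 - cur_ll);
        if (acc) { sig_u = prop; cur_ll = ll1; }
        ad_su.tally(acc);
      } else ad_su.tally(false);
      // sigma_v
      prop = sig_v + R::norm_rand() * ad_sv.sd();
      if (prop > 0 && prop < prior_sd_max) {
        double ll1 = 0.0;
        for (int i = 0; i < M; ++i)
          ll1 += ldbvn(u[i], v[i], mu_u, mu_v, sig_u, prop, rho);
        bool acc = std::log(R::unif_rand()) < (ll1 - cur_ll);
        if (acc) { sig_v = prop; cur_ll = ll1; }
        ad_sv.tally(acc);
      } else ad_sv.tally(false);
      // rho
      prop = rho + R::norm_rand() * ad_rho.sd();
      if (prop > -1.0 && prop < 1.0) {
        double ll1 = 0.0;
        for (int i = 0; i < M; ++i)
          ll1 += ldbvn(u[i], v[i], mu_u, mu_v, sig_u, sig_v, prop);
        bool acc = std::log(R::unif_rand()) < (ll1 - cur_ll);
        if (acc) rho = prop;
        ad_rho.tally(acc);
      } else ad_rho.tally(false);
      ad_su.maybe_adapt(burning); ad_sv.maybe_adapt(burning);
      ad_rho.maybe_adapt(burning);
    }
    // slope hypers
    for (int c = 0; c < C; ++c) {
      double sum = 0.0, sum2 = 0.0;
      for (int i = 0; i < M; ++i) sum += B[i + M * c];
      double s2 = sig_b[c] * sig_b[c];
      double prec = M / s2 + prior_prec;
      mu_b[c] = R::rnorm((sum / s2) / prec, std::sqrt(1.0 / prec));
      // sigma_b
      for (int i = 0; i < M; ++i) {
        double e = B[i + M * c] - mu_b[c]; sum2 += e * e;
      }
      double prop = sig_b[c] + R::norm_rand() * ad_sb[c].sd();
      if (prop > 0 && prop < prior_sd_max) {
        double ll0 = -M * std::log(sig_b[c]) - sum2 / (2.0 * s2);
        double ll1 = -M * std::log(prop) - sum2 / (2.0 * prop * prop);
        bool acc = std::log(R::unif_rand()) < (ll1 - ll0);
        if (acc) sig_b[c] = prop;
        ad_sb[c].tally(acc);
      } else ad_sb[c].tally(false);
      ad_sb[c].maybe_adapt(burning);

      sum = 0.0; sum2 = 0.0;
      for (int i = 0; i < M; ++i) sum += Bp[i + M * c];
      s2 = sig_bp[c] * sig_bp[c];
      prec = M / s2 + prior_prec;
      mu_bp[c] = R::rnorm((sum / s2) / prec, std::sqrt(1.0 / prec));
      for (int i = 0; i < M; ++i) {
        double e = Bp[i + M * c] - mu_bp[c]; sum2 += e * e;
      }
      prop = sig_bp[c] + R::norm_rand() * ad_sbp[c].sd();
      if (prop > 0 && prop < prior_sd_max) {
        double ll0 = -M * std::log(sig_bp[c]) - sum2 / (2.0 * s2);
        double ll1 = -M * std::log(prop) - sum2 / (2.0 * prop * prop);
        bool acc = std::log(R::unif_rand()) < (ll1 - ll0);
        if (acc) sig_bp[c] = prop;
        ad_sbp[c].tally(acc);
      } else ad_sbp[c].tally(false);
      ad_sbp[c].maybe_adapt(burning);
    }

    // ---- record ----
    if (iter > n_burn && (iter - n_burn) % thin == 0) {
      for (int i = 0; i < M; ++i) {
        out_u(keep, i) = u[i];
        out_v(keep, i) = v[i];
        out_w(keep, i) = w[i];
        for (int c = 0; c < C; ++c) {
          out_B(keep, i + M * c) = B[i + M * c];
          out_Bp(keep, i + M * c) = Bp[i + M * c];
        }
      }
      int col = 0;
      out_h(keep, col++) = mu_u;  out_h(keep, col++) = sig_u;
      out_h(keep, col++) = mu_v;  out_h(keep, col++) = sig_v;
      out_h(keep, col++) = rho;
      for (int c = 0; c < C; ++c) out_h(keep, col++) = mu_b[c];
      for (int c = 0; c < C; ++c) out_h(keep, col++) = sig_b[c];
      for (int c = 0; c < C; ++c) out_h(keep, col++) = mu_bp[c];
      for (int c = 0; c < C; ++c) out_h(keep, col++) = sig_bp[c];
      out_h(keep, col++) = Omega;
      out_h(keep, col++) = sw;
      int zok = 1;
      for (int i = 0; i < n_obs && zok; ++i)
        for (int l = 0; l < L && zok; ++l)
          for (int j = 0; j < J; ++j) {
            size_t id = (size_t)i + (size_t)M * (l + (size_t)L * j);
            if (d[id] > 0 && z[id] == 0) { zok = 0; break; }
          }
      out_zok[keep] = zok;
      ++keep;
    }
    if (iter % 1000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["u"] = out_u, _["v"] = out_v, _["beta"] = out_B,
                      _["betap"] = out_Bp, _["w"] = out_w,
                      _["hypers"] = out_h, _["z_respects_data"] = out_zok,
                      _["n_keep"] = n_keep);
}
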