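// Compiled engine for the reversible-jump epistasis sampler.  This is a
// statement-by-statement port of rjmcmc_engine_r(); both engines draw from
// R's RNG in the same order and realise the same chain for a given seed
// (agreement to near machine precision over a short horizon is asserted in
// the test suite; beyond that, floating-point round-off decouples them).

#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const double XC[3] = {1.0, 0.0, -1.0};
static const double WC[3] = {-0.5, 0.5, -0.5};

// log P(marker | QTL), 3x3 row-major [qtl][marker], codes ordered (1,0,-1)
static void log_mgq_c(double r, bool f23, double out[3][3]) {
  double M[3][3];
  if (!f23) {
    M[0][0] = (1 - r) * (1 - r); M[0][1] = 2 * r * (1 - r); M[0][2] = r * r;
    M[1][0] = r * (1 - r); M[1][1] = 1 - 2 * r + 2 * r * r;
    M[1][2] = r * (1 - r);
    M[2][0] = r * r; M[2][1] = 2 * r * (1 - r);
    M[2][2] = (1 - r) * (1 - r);
  } else {
    double h11 = (1 - r) * (2 - r) / 2;
    double h12 = r * (1 - r);
    double h13 = r * (1 + r) / 2;
    double h21 = (1 + 2 * r - 2 * r * r) / 4;
    double h22 = (1 - 2 * r + 2 * r * r) / 2;
    double H[3][3] = {{h11, h12, h13}, {h21, h22, h21}, {h13, h12, h11}};
    double pm[3] = {0.25, 0.5, 0.25};
    double pg[3] = {0.375, 0.25, 0.375};
    for (int g = 0; g < 3; ++g)
      for (int m = 0; m < 3; ++m)
        M[g][m] = H[m][g] * pm[m] / pg[g];
  }
  for (int g = 0; g < 3; ++g)
    for (int m = 0; m < 3; ++m)
      out[g][m] = std::log(M[g][m]);
}

static inline int unif_index1_c(int m) {
  int k = (int)std::floor(unif_rand() * m);
  if (k > m - 1) k = m - 1;
  return k;                       // 0-based
}

// [[Rcpp::export(name = "rjmcmc_engine_cpp")]]
List rjmcmc_engine_cpp(NumericVector y, IntegerMatrix iL, IntegerMatrix iR,
                       NumericVector low, NumericVector upp,
                       IntegerVector pair_k1, IntegerVector pair_k2,
                       bool f23, bool kosambi, NumericVector lprior,
                       double n_a, double eps, double p_a, double p_d,
                       double dtune, double vy, double phi0,
                       bool update_phi, bool use_lik, int burn_in, int thin,
                       int retained) {
  const int n = y.size(), p = low.size(), np = pair_k1.size();
  const int total = burn_in + retained * thin;
  RNGScope scope;

  // flank indices, 0-based, with missing masks
  std::vector<std::vector<int> > jL(p, std::vector<int>(n, 0)),
      jR(p, std::vector<int>(n, 0));
  std::vector<std::vector<char> > mskL(p, std::vector<char>(n, 0)),
      mskR(p, std::vector<char>(n, 0));
  for (int k = 0; k < p; ++k)
    for (int i = 0; i < n; ++i) {
      int vl = iL(i, k), vr = iR(i, k);
      if (vl == NA_INTEGER) mskL[k][i] = 1; else jL[k][i] = vl - 1;
      if (vr == NA_INTEGER) mskR[k][i] = 1; else jR[k][i] = vr - 1;
    }

  const double lp[3] = {lprior[0], lprior[1], lprior[2]};

  // Each individual belongs to one of 16 flanking-marker classes per
  // interval (3 codes + missing on each side); prior-transition weights and
  // their log-normalisers are computed once per class, not per individual.
  std::vector<std::vector<unsigned char> > cls(p,
      std::vector<unsigned char>(n));
  for (int k = 0; k < p; ++k)
    for (int i = 0; i < n; ++i) {
      int cl = mskL[k][i] ? 3 : jL[k][i];
      int cr = mskR[k][i] ? 3 : jR[k][i];
      cls[k][i] = (unsigned char)(4 * cl + cr);
    }

  // class weights lwc[3*cls + g] and log-normaliser lsec[cls] for interval
  // k at position lam
  auto prior_lw_cls = [&](int k, double lam, double *lwc, double *lsec) {
    double dL = lam - low[k], dR = upp[k] - lam;
    double rL = kosambi ? 0.5 * std::tanh(0.02 * dL)
                        : 0.5 * (1 - std::exp(-0.02 * dL));
    double rR = kosambi ? 0.5 * std::tanh(0.02 * dR)
                        : 0.5 * (1 - std::exp(-0.02 * dR));
    double gL[3][3], gR[3][3];
    log_mgq_c(rL, f23, gL);
    log_mgq_c(rR, f23, gR);
    for (int cl = 0; cl < 4; ++cl)
      for (int cr = 0; cr < 4; ++cr) {
        double *v = lwc + 3 * (4 * cl + cr);
        for (int g = 0; g < 3; ++g)
          v[g] = lp[g] + (cl == 3 ? 0.0 : gL[g][cl]) +
                 (cr == 3 ? 0.0 : gR[g][cr]);
        double m = std::max(v[0], std::max(v[1], v[2]));
        lsec[4 * cl + cr] = m + std::log(std::exp(v[0] - m) +
                                         std::exp(v[1] - m) +
                                         std::exp(v[2] - m));
      }
  };

  // per-interval cache of the class weights at the current position
  std::vector<double> lwc_cache(48 * p), lsec_cache(16 * p);
  std::vector<double> lam_cached(p, -1.0);
  double lwc_star[48], lsec_star[16];

  // state
  double mu = mean(y);
  std::vector<double> a(p, 0.0), d(p, 0.0);
  std::vector<double> sa2(p, vy * 1e-5 / p), sd2(p, vy * 1e-5 / p);
  double sigma2 = vy, phi = phi0;
  std::vector<double> lambda(p);
  for (int k = 0; k < p; ++k) lambda[k] = (low[k] + upp[k]) / 2;
  std::vector<std::vector<int> > gq(p, std::vector<int>(n, 0)); // 0..2
  std::vector<std::vector<double> > x(p, std::vector<double>(n)),
      w(p, std::vector<double>(n));

  for (int k = 0; k < p; ++k) {
    {
      double *lwc = &lwc_cache[48 * k];
      prior_lw_cls(k, lambda[k], lwc, &lsec_cache[16 * k]);
      lam_cached[k] = lambda[k];
      double q[16][3];
      for (int c = 0; c < 16; ++c) {
        const double *v = lwc + 3 * c;
        double m = std::max(v[0], std::max(v[1], v[2]));
        for (int g = 0; g < 3; ++g) q[c][g] = std::exp(v[g] - m);
      }
      for (int i = 0; i < n; ++i) {
        const double *qq = q[cls[k][i]];
        double u = unif_rand() * (qq[0] + qq[1] + qq[2]);
        int idx = 0;
        if (u > qq[0]) idx = 1;
        if (u > qq[0] + qq[1]) idx = 2;
        gq[k][i] = idx;
        x[k][i] = XC[idx];
        w[k][i] = WC[idx];
      }
    }
  }

  std::vector<char> act(np, 0);
  std::vector<int> act_id;
  std::vector<double> theta;          // t x 4, row-major
  std::vector<double> evar;           // t x 4, row-major
  int t_cur = 0;

  std::vector<double> e(n), enew(n), ewo(n), cov(n);

  // chain storage
  NumericVector s_mu(retained), s_sig(retained), s_phi(retained);
  IntegerVector s_t(retained), s_it(retained);
  NumericMatrix s_a(retained, p), s_d(retained, p), s_lam(retained, p);
  NumericMatrix s_sa2(retained, p), s_sd2(retained, p);
  std::vector<double> epi_rec;
  IntegerMatrix incl(p, p);
  NumericMatrix xsum(n, p), wsum(n, p);
  IntegerVector t_trace(total);
  int kept = 0;

  auto ridge = [&](const std::vector<double> &cc,
                   const std::vector<double> &rp, double evr) {
    double S = 0.0, cr = 0.0;
    for (int i = 0; i < n; ++i) { S += cc[i] * cc[i]; cr += cc[i] * rp[i]; }
    S += sigma2 / evr;
    return R::rnorm(cr / S, std::sqrt(sigma2 / S));
  };

  std::vector<double> rp(n);

  for (int iter = 1; iter <= total; ++iter) {
    // full-model residual, rebuilt exactly once per iteration
    for (int i = 0; i < n; ++i) e[i] = y[i] - mu;
    for (int k = 0; k < p; ++k) {
      double ak = a[k], dk = d[k];
      for (int i = 0; i < n; ++i) e[i] -= x[k][i] * ak + w[k][i] * dk;
    }
    for (int j = 0; j < t_cur; ++j) {
      int k1 = pair_k1[act_id[j]] - 1, k2 = pair_k2[act_id[j]] - 1;
      const double *th = &theta[4 * j];
      for (int i = 0; i < n; ++i)
        e[i] -= x[k1][i] * x[k2][i] * th[0] + x[k1][i] * w[k2][i] * th[1] +
                w[k1][i] * x[k2][i] * th[2] + w[k1][i] * w[k2][i] * th[3];
    }

    // 1. grand mean
    double gm = 0.0;
    for (int i = 0; i < n; ++i) gm += e[i];
    gm = gm / n + mu;
    double mu_new = R::rnorm(gm, std::sqrt(sigma2 / n));
    for (int i = 0; i < n; ++i) e[i] += mu - mu_new;
    mu = mu_new;

    // 2. main effects, additive then dominance per interval
    for (int k = 0; k < p; ++k) {
      for (int i = 0; i < n; ++i) rp[i] = e[i] + x[k][i] * a[k];
      double anew = ridge(x[k], rp, sa2[k]);
      for (int i = 0; i < n; ++i) e[i] = rp[i] - x[k][i] * anew;
      a[k] = anew;
      for (int i = 0; i < n; ++i) rp[i] = e[i] + w[k][i] * d[k];
      double dnew = ridge(w[k], rp, sd2[k]);
      for (int i = 0; i < n; ++i) e[i] = rp[i] - w[k][i] * dnew;
      d[k] = dnew;
    }

    // 3. refresh active pairs' epistatic effects
    for (int j = 0; j < t_cur; ++j) {
      int k1 = pair_k1[act_id[j]] - 1, k2 = pair_k2[act_id[j]] - 1;
      for (int m = 0; m < 4; ++m) {
        for (int i = 0; i < n; ++i)
          cov[i] = (m == 0 ? x[k1][i] * x[k2][i] :
                    m == 1 ? x[k1][i] * w[k2][i] :
                    m == 2 ? w[k1][i] * x[k2][i] :
                             w[k1][i] * w[k2][i]);
        double &th = theta[4 * j + m];
        for (int i = 0; i < n; ++i) rp[i] = e[i] + cov[i] * th;
        double tnew = ridge(cov, rp, evar[4 * j + m]);
        for (int i = 0; i < n; ++i) e[i] = rp[i] - cov[i] * tnew;
        th = tnew;
      }
    }

    // 4. add proposal
    if (t_cur < np) {
      int id;
      if (t_cur == 0) {
        id = unif_index1_c(np);
      } else {
        int pick = unif_index1_c(np - t_cur), seen = -1;
        id = -1;
        for (int q = 0; q < np; ++q)
          if (!act[q] && ++seen == pick) { id = q; break; }
      }
      int k1 = pair_k1[id] - 1, k2 = pair_k2[id] - 1;
      double v0 = vy;  // birth variances at var(y); see R reference
      double th[4];
      for (int i = 0; i < n; ++i) enew[i] = e[i];
      for (int m = 0; m < 4; ++m) {
        for (int i = 0; i < n; ++i)
          cov[i] = (m == 0 ? x[k1][i] * x[k2][i] :
                    m == 1 ? x[k1][i] * w[k2][i] :
                    m == 2 ? w[k1][i] * x[k2][i] :
                             w[k1][i] * w[k2][i]);
        th[m] = ridge(cov, enew, v0);
        for (int i = 0; i < n; ++i) enew[i] -= cov[i] * th[m];
      }
      double llr = 0.0;
      if (use_lik) {
        double sn = 0.0, so = 0.0;
        for (int i = 0; i < n; ++i) {
          sn += enew[i] * enew[i];
          so += e[i] * e[i];
        }
        llr = -0.5 / sigma2 * (sn - so);
      }
      double la = llr + std::log(phi) - 2 * std::log((double)t_cur + 1) +
                  std::log(p_d) - std::log(p_a);
      if (std::log(unif_rand()) < la) {
        act[id] = 1;
        act_id.push_back(id);
        for (int m = 0; m < 4; ++m) theta.push_back(th[m]);
        for (int m = 0; m < 4; ++m) evar.push_back(v0);
        ++t_cur;
        e.swap(enew);
      }
    }

    // 5. delete proposal (likelihood ratio: proposed t-1 over current t)
    if (t_cur >= 1) {
      int j = unif_index1_c(t_cur);
      int k1 = pair_k1[act_id[j]] - 1, k2 = pair_k2[act_id[j]] - 1;
      const double *th = &theta[4 * j];
      for (int i = 0; i < n; ++i)
        ewo[i] = e[i] + x[k1][i] * x[k2][i] * th[0] +
                 x[k1][i] * w[k2][i] * th[1] + w[k1][i] * x[k2][i] * th[2] +
                 w[k1][i] * w[k2][i] * th[3];
      double llr = 0.0;
      if (use_lik) {
        double sn = 0.0, so = 0.0;
        for (int i = 0; i < n; ++i) {
          sn += ewo[i] * ewo[i];
          so += e[i] * e[i];
        }
        llr = -0.5 / sigma2 * (sn - so);
      }
      double la = llr + 2 * std::log((double)t_cur) - std::log(phi) +
                  std::log(p_a) - std::log(p_d);
      if (std::log(unif_rand()) < la) {
        act[act_id[j]] = 0;
        act_id.erase(act_id.begin() + j);
        theta.erase(theta.begin() + 4 * j, theta.begin() + 4 * j + 4);
        evar.erase(evar.begin() + 4 * j, evar.begin() + 4 * j + 4);
        --t_cur;
        e.swap(ewo);
      }
    }

    // 6. shrinkage variances (same draw order as the R engine:
    //    a_1..a_p, d_1..d_p, then theta column-major)
    for (int k = 0; k < p; ++k) {
      double v = a[k] * a[k] / R::rchisq(n_a);
      if (!std::isfinite(v)) v = 1e12;
      sa2[k] = std::max(v, eps);
    }
    for (int k = 0; k < p; ++k) {
      double v = d[k] * d[k] / R::rchisq(n_a);
      if (!std::isfinite(v)) v = 1e12;
      sd2[k] = std::max(v, eps);
    }
    for (int m = 0; m < 4; ++m)
      for (int j = 0; j < t_cur; ++j) {
        double th = theta[4 * j + m];
        double v = th * th / R::rchisq(n_a);
        if (!std::isfinite(v)) v = 1e12;
        evar[4 * j + m] = std::max(v, eps);
      }

    // 7. residual variance
    {
      double ee = 0.0;
      for (int i = 0; i < n; ++i) ee += e[i] * e[i];
      sigma2 = std::max(ee / R::rchisq(n_a + n - 1), eps);
    }

    // 8. genotype imputation per interval; per-class genotype counts are
    //    kept to price the position move afterwards.  Class weights are
    //    cached across iterations and recomputed only when the interval's
    //    position moved.
    std::vector<double> ll_keep(p, 0.0);
    std::vector<std::array<std::array<int, 3>, 16> > cnt_keep(p);
    double half_prec = 0.5 / sigma2;
    std::vector<double> A(n), D(n);
    for (int k = 0; k < p; ++k) {
      if (lam_cached[k] != lambda[k]) {
        prior_lw_cls(k, lambda[k], &lwc_cache[48 * k], &lsec_cache[16 * k]);
        lam_cached[k] = lambda[k];
      }
      const double *lwc = &lwc_cache[48 * k];
      const double *lsec = &lsec_cache[16 * k];
      for (int i = 0; i < n; ++i) { A[i] = a[k]; D[i] = d[k]; }
      for (int j = 0; j < t_cur; ++j) {
        int pk1 = pair_k1[act_id[j]] - 1, pk2 = pair_k2[act_id[j]] - 1;
        const double *th = &theta[4 * j];
        if (pk1 == k) {
          for (int i = 0; i < n; ++i) {
            A[i] += x[pk2][i] * th[0] + w[pk2][i] * th[1];
            D[i] += x[pk2][i] * th[2] + w[pk2][i] * th[3];
          }
        } else if (pk2 == k) {
          for (int i = 0; i < n; ++i) {
            A[i] += x[pk1][i] * th[0] + w[pk1][i] * th[2];
            D[i] += x[pk1][i] * th[1] + w[pk1][i] * th[3];
          }
        }
      }
      std::array<std::array<int, 3>, 16> &cnt = cnt_keep[k];
      for (int c = 0; c < 16; ++c) cnt[c] = {0, 0, 0};
      const std::vector<unsigned char> &ck = cls[k];
      for (int i = 0; i < n; ++i) {
        double base = e[i] + x[k][i] * A[i] + w[k][i] * D[i];
        double r1 = base - A[i] + 0.5 * D[i];
        double r2 = base - 0.5 * D[i];
        double r3 = base + A[i] + 0.5 * D[i];
        const double *pw = lwc + 3 * ck[i];
        double l1 = pw[0] - half_prec * r1 * r1;
        double l2 = pw[1] - half_prec * r2 * r2;
        double l3 = pw[2] - half_prec * r3 * r3;
        double m = std::max(l1, std::max(l2, l3));
        double q1 = std::exp(l1 - m), q2 = std::exp(l2 - m),
               q3 = std::exp(l3 - m);
        double u = unif_rand() * (q1 + q2 + q3);
        int idx = 0;
        if (u > q1) idx = 1;
        if (u > q1 + q2) idx = 2;
        gq[k][i] = idx;
        x[k][i] = XC[idx];
        w[k][i] = WC[idx];
        e[i] = base - x[k][i] * A[i] - w[k][i] * D[i];
        cnt[ck[i]][idx] += 1;
      }
      double ll = 0.0;
      for (int c = 0; c < 16; ++c) {
        int rc = cnt[c][0] + cnt[c][1] + cnt[c][2];
        if (!rc) continue;
        const double *v = lwc + 3 * c;
        ll += cnt[c][0] * v[0] + cnt[c][1] * v[1] + cnt[c][2] * v[2] -
              rc * lsec[c];
      }
      ll_keep[k] = ll;
    }

    // 9. M-H position update per interval, priced on the per-class counts
    for (int k = 0; k < p; ++k) {
      double L = low[k], U = upp[k];
      double lo = std::max(L, lambda[k] - dtune),
             hi = std::min(U, lambda[k] + dtune);
      double lam_star = lo + (hi - lo) * unif_rand();
      lam_star = std::min(std::max(lam_star, L + 1e-9), U - 1e-9);
      double lo2 = std::max(L, lam_star - dtune),
             hi2 = std::min(U, lam_star + dtune);
      prior_lw_cls(k, lam_star, lwc_star, lsec_star);
      const std::array<std::array<int, 3>, 16> &cnt = cnt_keep[k];
      double ll_new = 0.0;
      for (int c = 0; c < 16; ++c) {
        int rc = cnt[c][0] + cnt[c][1] + cnt[c][2];
        if (!rc) continue;
        const double *v = lwc_star + 3 * c;
        ll_new += cnt[c][0] * v[0] + cnt[c][1] * v[1] + cnt[c][2] * v[2] -
                  rc * lsec_star[c];
      }
      double la = ll_new - ll_keep[k] + std::log(hi - lo) -
                  std::log(hi2 - lo2);
      if (std::log(unif_rand()) < la) {
        lambda[k] = lam_star;
        std::copy(lwc_star, lwc_star + 48, &lwc_cache[48 * k]);
        std::copy(lsec_star, lsec_star + 16, &lsec_cache[16 * k]);
        lam_cached[k] = lam_star;
      }
    }

    // 10. Poisson mean (Gamma(t + 1, rate 2) = Gamma(shape, scale 1/2))
    if (update_phi) phi = R::rgamma(t_cur + 1.0, 0.5);

    t_trace[iter - 1] = t_cur;

    if (iter > burn_in && (iter - burn_in) % thin == 0) {
      s_it[kept] = iter;
      s_mu[kept] = mu; s_sig[kept] = sigma2;
      s_phi[kept] = phi; s_t[kept] = t_cur;
      for (int k = 0; k < p; ++k) {
        s_a(kept, k) = a[k]; s_d(kept, k) = d[k];
        s_lam(kept, k) = lambda[k];
        s_sa2(kept, k) = sa2[k]; s_sd2(kept, k) = sd2[k];
      }
      for (int j = 0; j < t_cur; ++j) {
        int k1 = pair_k1[act_id[j]], k2 = pair_k2[act_id[j]];
        incl(k1 - 1, k2 - 1) += 1;
        epi_rec.push_back(kept + 1);
        epi_rec.push_back(k1);
        epi_rec.push_back(k2);
        for (int m = 0; m < 4; ++m) epi_rec.push_back(theta[4 * j + m]);
      }
      for (int k = 0; k < p; ++k)
        for (int i = 0; i < n; ++i) {
          xsum(i, k) += x[k][i];
          wsum(i, k) += w[k][i];
        }
      ++kept;
    }
  }

  return List::create(
      _["s_mu"] = s_mu, _["s_sig"] = s_sig, _["s_phi"] = s_phi,
      _["s_t"] = s_t, _["s_it"] = s_it, _["s_a"] = s_a, _["s_d"] = s_d,
      _["s_lam"] = s_lam, _["s_sa2"] = s_sa2, _["s_sd2"] = s_sd2,
      _["epi"] = NumericVector(epi_rec.begin(), epi_rec.end()),
      _["incl"] = incl, _["t_trace"] = t_trace, _["xsum"] = xsum,
      _["wsum"] = wsum);
}
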