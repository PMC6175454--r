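// Gibbs sampler for the multi-trait animal model
//   y_k = X_k b_k + Z_k a_k + W_k c_k + e_k,  k = 1..t traits (environments)
//   (a_1..a_t) ~ N(0, G (x) A),  c_k ~ N(0, I sigc2_k),  e_k ~ N(0, I sige2_k)
// Cross-trait C and R covariances are fixed at zero: no animal or family is
// recorded in two environments. Single-site updates for breeding values use
// the sparse A-inverse; G has a conjugate inverse-Wishart conditional and the
// scalar variances scaled-inverse-chi-square conditionals.
// All randomness comes from R's RNG so set.seed() governs the chain.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Inverse-Wishart draw via Bartlett decomposition, using R's RNG.
// If W ~ Wishart(df, S^{ -1}) then inv(W) ~ IW(df, S).
static arma::mat riwish(double df, const arma::mat& S) {
  const int d = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;           // W = LA LA'
  arma::mat LAinv = arma::inv(arma::trimatl(LA));
  return LAinv.t() * LAinv;       // inv(W)
}

static double rscinv_chisq(double df, double scale_sum) {
  return scale_sum / R::rchisq(df);
}

// [[Rcpp::export]]
List mt_gibbs_cpp(List ys, List Xs, List zis, List wis,
                  IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                  int n_animals,
                  int n_iter, int burnin, int thin,
                  double nu_g, const arma::mat& S_g,
                  double nu_s, double s2_c, double s2_e,
                  List init) {
  const int t = ys.size();
  const int N = n_animals;

  std::vector<arma::vec> y(t), e(t), b(t), c(t);
  std::vector<arma::mat> X(t), XtX_chol(t);
  std::vector<std::vector<int>> zi(t), wi(t);
  std::vector<int> n(t), p(t), q(t);
  // rec_of[k][animal] = record index or -1
  std::vector<std::vector<int>> rec_of(t);
  // fam_recs[k][f] = record indices of family f; fam_anim = animal indices
  std::vector<std::vector<std::vector<int>>> fam_recs(t), fam_anim(t);

  for (int k = 0; k < t; ++k) {
    y[k] = as<arma::vec>(ys[k]);
    X[k] = as<arma::mat>(Xs[k]);
    IntegerVector z = zis[k], w = wis[k];
    n[k] = y[k].n_elem;
    p[k] = X[k].n_cols;
    zi[k].assign(z.begin(), z.end());
    wi[k].assign(w.begin(), w.end());
    int qk = 0;
    for (int r = 0; r < n[k]; ++r) if (wi[k][r] + 1 > qk) qk = wi[k][r] + 1;
    q[k] = qk;
    rec_of[k].assign(N, -1);
    for (int r = 0; r < n[k]; ++r) rec_of[k][zi[k][r]] = r;
    fam_recs[k].assign(qk, std::vector<int>());
    for (int r = 0; r < n[k]; ++r)
      if (wi[k][r] >= 0) fam_recs[k][wi[k][r]].push_back(r);
    fam_anim[k].assign(qk, std::vector<int>());
    for (int r = 0; r < n[k]; ++r)
      if (wi[k][r] >= 0) fam_anim[k][wi[k][r]].push_back(zi[k][r]);
    b[k] = arma::vec(p[k], arma::fill::zeros);
    c[k] = arma::vec(qk, arma::fill::zeros);
    if (init.containsElementNamed("b")) b[k] = as<arma::vec>(as<List>(init["b"])[k]);
    if (init.containsElementNamed("c")) c[k] = as<arma::vec>(as<List>(init["c"])[k]);
    if (p[k] > 0) XtX_chol[k] = arma::chol(X[k].t() * X[k] +
                                           1e-10 * arma::eye(p[k], p[k]));
  }

  // per-family quadratic forms 1_S' Ainv 1_S over the recorded members,
  // used by the exact reallocation move between c_f and the family's a
  std::vector<std::vector<double>> fam_qss(t);
  for (int k = 0; k < t; ++k) {
    fam_qss[k].assign(q[k], 0.0);
    std::vector<char> inS(N, 0);
    for (int f = 0; f < q[k]; ++f) {
      const std::vector<int>& S = fam_anim[k][f];
      for (size_t u = 0; u < S.size(); ++u) inS[S[u]] = 1;
      double qs = 0.0;
      for (size_t u = 0; u < S.size(); ++u) {
        const int i = S[u];
        for (int kk = Ap[i]; kk < Ap[i + 1]; ++kk)
          if (inS[Ai[kk]]) qs += Ax[kk];
      }
      fam_qss[k][f] = qs;
      for (size_t u = 0; u < S.size(); ++u) inS[S[u]] = 0;
    }
  }

  arma::mat a = as<arma::mat>(init["a"]);
  arma::mat G = as<arma::mat>(init["G"]);
  arma::vec sigc2 = as<arma::vec>(init["sigc2"]);
  arma::vec sige2 = as<arma::vec>(init["sige2"]);
  for (int k = 0; k < t; ++k) {
    e[k] = y[k];
    if (p[k] > 0) e[k] -= X[k] * b[k];
    for (int r = 0; r < n[k]; ++r) {
      e[k][r] -= a(zi[k][r], k);
      if (wi[k][r] >= 0) e[k][r] -= c[k][wi[k][r]];
    }
  }

  const int n_keep = (n_iter - burnin + thin - 1) / thin;
  const int n_gpar = t * (t + 1) / 2;
  arma::mat samples(n_keep, n_gpar + 2 * t, arma::fill::zeros);
  std::vector<arma::vec> b_mean(t);
  for (int k = 0; k < t; ++k) b_mean[k] = arma::vec(p[k], arma::fill::zeros);
  arma::mat a_mean(N, t, arma::fill::zeros);
  int kept = 0;

  arma::mat Ginv(t, t);
  arma::vec sv(t), rhs(t);
  arma::mat P(t, t);
  const int n_ltri = t * (t + 1) / 2;
  std::vector<double> scale_iw(n_ltri, 0.1);
  std::vector<long> bacc_iw(n_ltri, 0), batt_iw(n_ltri, 0);
  std::vector<double> scale_c(t, 0.3);
  std::vector<long> bacc_c(t, 0), batt_c(t, 0);
  arma::mat at(N, t);  // whitened breeding values for interweaving

  for (int it = 0; it < n_iter; ++it) {
    // --- fixed effects, per trait (homoskedastic conjugate block) ---
    for (int k = 0; k < t; ++k) {
      if (p[k] == 0) continue;
      arma::vec r = e[k] + X[k] * b[k];
      arma::vec mu = arma::solve(arma::trimatu(XtX_chol[k]),
                     arma::solve(arma::trimatl(XtX_chol[k].t()), X[k].t() * r));
      arma::vec zdraw(p[k]);
      for (int j = 0; j < p[k]; ++j) zdraw(j) = R::norm_rand();
      arma::vec bnew = mu + std::sqrt(sige2[k]) *
        arma::solve(arma::trimatu(XtX_chol[k]), zdraw);
      e[k] = r - X[k] * bnew;
      b[k] = bnew;
    }

    // --- breeding values, single site over animals ---
    // hand-rolled t x t Cholesky algebra: this loop dominates runtime and
    // per-animal armadillo temporaries are too expensive here
    Ginv = arma::inv_sympd(arma::symmatu(G));
    {
      std::vector<double> Pb(t * t), Lb(t * t), rv(t), svb(t), w1(t), w2(t);
      for (int i = 0; i < N; ++i) {
        double diag = 0.0;
        for (int k = 0; k < t; ++k) svb[k] = 0.0;
        for (int kk = Ap[i]; kk < Ap[i + 1]; ++kk) {
          const int j = Ai[kk];
          const double v = Ax[kk];
          if (j == i) { diag = v; continue; }
          for (int k = 0; k < t; ++k) svb[k] += v * a(j, k);
        }
        for (int k = 0; k < t; ++k) {
          for (int l = 0; l < t; ++l) Pb[k * t + l] = diag * Ginv(k, l);
          double rk = 0.0;
          for (int l = 0; l < t; ++l) rk -= Ginv(k, l) * svb[l];
          rv[k] = rk;
        }
        for (int k = 0; k < t; ++k) {
          const int r = rec_of[k][i];
          if (r >= 0) {
            Pb[k * t + k] += 1.0 / sige2[k];
            rv[k] += (e[k][r] + a(i, k)) / sige2[k];
          }
        }
        // lower Cholesky of P
        for (int k = 0; k < t; ++k) {
          for (int l = 0; l <= k; ++l) {
            double s = Pb[k * t + l];
            for (int m = 0; m < l; ++m) s -= Lb[k * t + m] * Lb[l * t + m];
            Lb[k * t + l] = (k == l) ? std::sqrt(s) : s / Lb[l * t + l];
          }
        }
        // mu = P^-1 rhs via forward + back solve
        for (int k = 0; k < t; ++k) {
          double s = rv[k];
          for (int m = 0; m < k; ++m) s -= Lb[k * t + m] * w1[m];
          w1[k] = s / Lb[k * t + k];
        }
        for (int k = t - 1; k >= 0; --k) {
          double s = w1[k];
          for (int m = k + 1; m < t; ++m) s -= Lb[m * t + k] * w2[m];
          w2[k] = s / Lb[k * t + k];
        }
        // draw: anew = mu + L^-T z
        for (int k = 0; k < t; ++k) w1[k] = R::norm_rand();
        for (int k = t - 1; k >= 0; --k) {
          double s = w1[k];
          for (int m = k + 1; m < t; ++m) s -= Lb[m * t + k] * w1[m];
          w1[k] = s / Lb[k * t + k];
        }
        for (int k = 0; k < t; ++k) {
          const double anew = w2[k] + w1[k];
          const int r = rec_of[k][i];
          if (r >= 0) e[k][r] += a(i, k) - anew;
          a(i, k) = anew;
        }
      }
    }

    // --- family (hapa) effects ---
    for (int k = 0; k < t; ++k) {
      for (int f = 0; f < q[k]; ++f) {
        const std::vector<int>& fr = fam_recs[k][f];
        double prec = 1.0 / sigc2[k];
        double r0 = 0.0;
        for (size_t u = 0; u < fr.size(); ++u) {
          prec += 1.0 / sige2[k];
          r0 += (e[k][fr[u]] + c[k][f]) / sige2[k];
        }
        double mu = r0 / prec;
        double cnew = mu + R::norm_rand() / std::sqrt(prec);
        for (size_t u = 0; u < fr.size(); ++u) e[k][fr[u]] += c[k][f] - cnew;
        c[k][f] = cnew;
      }
    }

    // --- reallocation move: exact Gibbs along (c_f + d, a_family - d) ---
    // residuals are unchanged along this direction, so the conditional of d
    // is Gaussian from the priors alone; this mixes the additive-vs-hapa
    // split that single-site updates leave almost frozen
    for (int k = 0; k < t; ++k) {
      for (int f = 0; f < q[k]; ++f) {
        const std::vector<int>& S = fam_anim[k][f];
        if (S.empty()) continue;
        double sm[8];  // 1_S' Ainv a_m per trait (t <= 8 supported)
        for (int m = 0; m < t; ++m) sm[m] = 0.0;
        for (size_t u = 0; u < S.size(); ++u) {
          const int i = S[u];
          for (int kk = Ap[i]; kk < Ap[i + 1]; ++kk) {
            const double v = Ax[kk];
            const int j = Ai[kk];
            for (int m = 0; m < t; ++m) sm[m] += v * a(j, m);
          }
        }
        double Aq = Ginv(k, k) * fam_qss[k][f] + 1.0 / sigc2[k];
        double Bl = c[k][f] / sigc2[k];
        for (int m = 0; m < t; ++m) Bl -= Ginv(k, m) * sm[m];
        const double mu_d = -Bl / Aq;
        const double d = mu_d + R::norm_rand() / std::sqrt(Aq);
        for (size_t u = 0; u < S.size(); ++u) a(S[u], k) -= d;
        c[k][f] += d;
      }
    }

    // --- genetic covariance matrix ---
    arma::mat Q(t, t, arma::fill::zeros);
    for (int j = 0; j < N; ++j) {
      for (int kk = Ap[j]; kk < Ap[j + 1]; ++kk) {
        const int r = Ai[kk];
        const double v = Ax[kk];
        for (int u = 0; u < t; ++u)
          for (int w = 0; w < t; ++w) Q(u, w) += v * a(r, u) * a(j, w);
      }
    }
    G = riwish(nu_g + N, S_g + arma::symmatu(0.5 * (Q + Q.t())));

    // ---- interweaving: non-centered re-update of G ----
    // Whitened effects at = a L^-T (per animal a_i = L at_i) held fixed;
    // random-walk MH on the Cholesky factor of G (log scale on diagonals)
    // moves (G, a) jointly, which decouples the variance-effect funnel.
    {
      arma::mat L = arma::chol(arma::symmatu(G), "lower");
      arma::mat Linv = arma::inv(arma::trimatl(L));
      at = a * Linv.t();
      auto logtarget = [&](const arma::mat& Lc) -> double {
        double lp = 0.0, logdet = 0.0;
        for (int i = 0; i < t; ++i) logdet += 2.0 * std::log(Lc(i, i));
        arma::mat Gc = Lc * Lc.t();
        arma::mat Gci = arma::inv_sympd(arma::symmatu(Gc));
        lp += -0.5 * (nu_g + t + 1.0) * logdet - 0.5 * arma::trace(S_g * Gci);
        for (int i = 0; i < t; ++i)
          lp += (t - i + 1.0) * std::log(Lc(i, i));  // Jacobian terms
        for (int k = 0; k < t; ++k) {
          const double inv2s = 0.5 / sige2[k];
          for (int r = 0; r < n[k]; ++r) {
            const int i = zi[k][r];
            double ai = 0.0;
            for (int m = 0; m <= k; ++m) ai += Lc(k, m) * at(i, m);
            const double er = e[k][r] + a(i, k) - ai;
            lp -= inv2s * er * er;
          }
        }
        return lp;
      };
      double lp_cur = logtarget(L);
      int cix = 0;
      for (int kk = 0; kk < t; ++kk) {
        for (int mm = 0; mm <= kk; ++mm) {
          arma::mat Lp = L;
          const double del = R::norm_rand() * scale_iw[cix];
          if (kk == mm) Lp(kk, kk) = std::exp(std::log(L(kk, kk)) + del);
          else Lp(kk, mm) += del;
          double lp_new = logtarget(Lp);
          ++batt_iw[cix];
          if (std::log(R::unif_rand()) < lp_new - lp_cur) {
            L = Lp;
            lp_cur = lp_new;
            ++bacc_iw[cix];
          }
          ++cix;
        }
      }
      // rebuild a, residuals and G from the accepted factorization
      arma::mat anew_all = at * L.t();
      for (int k = 0; k < t; ++k) {
        for (int r = 0; r < n[k]; ++r) {
          const int i = zi[k][r];
          e[k][r] += a(i, k) - anew_all(i, k);
        }
      }
      a = anew_all;
      G = L * L.t();
      if (it < burnin && (it + 1) % 50 == 0) {
        for (int j = 0; j < n_ltri; ++j) {
          if (batt_iw[j] > 0) {
            double rate = (double)bacc_iw[j] / batt_iw[j];
            scale_iw[j] *= std::exp(0.6 * (rate - 0.3));
            scale_iw[j] = std::min(std::max(scale_iw[j], 1e-4), 50.0);
            bacc_iw[j] = batt_iw[j] = 0;
          }
        }
      }
    }

    // --- scalar variances ---
    for (int k = 0; k < t; ++k) {
      if (q[k] > 0) {
        double ssc = arma::dot(c[k], c[k]);
        sigc2[k] = rscinv_chisq(nu_s + q[k], nu_s * s2_c + ssc);
      }
      double sse = arma::dot(e[k], e[k]);
      sige2[k] = rscinv_chisq(nu_s + n[k], nu_s * s2_e + sse);
    }

    // --- interweaving: non-centered re-update of each hapa variance ---
    // c held fixed on the whitened scale c / sigma_c; random-walk MH on
    // log sigc2 rescales the family effects jointly with their variance.
    for (int k = 0; k < t; ++k) {
      if (q[k] == 0) continue;
      const double th = std::log(sigc2[k]);
      const double del = R::norm_rand() * scale_c[k];
      const double ratio = std::exp(0.5 * del);  // sigma_c' / sigma_c
      double dll = 0.0;
      for (int r = 0; r < n[k]; ++r) {
        const int f = wi[k][r];
        if (f < 0) continue;
        const double en = e[k][r] + (1.0 - ratio) * c[k][f];
        dll += -0.5 * (en * en - e[k][r] * e[k][r]) / sige2[k];
      }
      // scaled-inv-chi2 prior on sigc2 plus the log-scale Jacobian
      const double s2o = sigc2[k], s2n = std::exp(th + del);
      dll += (-(0.5 * nu_s + 1.0) * (th + del) - 0.5 * nu_s * s2_c / s2n + (th + del))
           - (-(0.5 * nu_s + 1.0) * th - 0.5 * nu_s * s2_c / s2o + th);
      ++batt_c[k];
      if (std::log(R::unif_rand()) < dll) {
        for (int r = 0; r < n[k]; ++r) {
          const int f = wi[k][r];
          if (f >= 0) e[k][r] += (1.0 - ratio) * c[k][f];
        }
        for (int f = 0; f < q[k]; ++f) c[k][f] *= ratio;
        sigc2[k] = s2n;
        ++bacc_c[k];
      }
      if (it < burnin && (it + 1) % 50 == 0 && batt_c[k] > 0) {
        double rate = (double)bacc_c[k] / batt_c[k];
        scale_c[k] *= std::exp(0.6 * (rate - 0.3));
        scale_c[k] = std::min(std::max(scale_c[k], 1e-4), 50.0);
        bacc_c[k] = batt_c[k] = 0;
      }
    }

    // --- control floating-point drift in the incremental residuals ---
    if ((it + 1) % 1000 == 0) {
      for (int k = 0; k < t; ++k) {
        e[k] = y[k];
        if (p[k] > 0) e[k] -= X[k] * b[k];
        for (int r = 0; r < n[k]; ++r) {
          e[k][r] -= a(zi[k][r], k);
          if (wi[k][r] >= 0) e[k][r] -= c[k][wi[k][r]];
        }
      }
    }

    // --- store ---
    if (it >= burnin && (it - burnin) % thin == 0) {
      int col = 0;
      for (int k = 0; k < t; ++k)
        for (int l = k; l < t; ++l) samples(kept, col++) = G(k, l);
      for (int k = 0; k < t; ++k) samples(kept, col++) = sigc2[k];
      for (int k = 0; k < t; ++k) samples(kept, col++) = sige2[k];
      for (int k = 0; k < t; ++k) b_mean[k] += b[k];
      a_mean += a;
      ++kept;
    }
  }

  for (int k = 0; k < t; ++k) if (kept > 0) b_mean[k] /= kept;
  if (kept > 0) a_mean /= kept;
  List bml(t), bcur(t), ccur(t);
  for (int k = 0; k < t; ++k) {
    bml[k] = b_mean[k];
    bcur[k] = b[k];
    ccur[k] = c[k];
  }
  List state = List::create(_["b"] = bcur, _["a"] = a, _["c"] = ccur,
                            _["G"] = G, _["sigc2"] = sigc2,
                            _["sige2"] = sige2);
  return List::create(_["samples"] = samples,
                      _["state"] = state,
                      _["b_mean"] = bml,
                      _["a_mean"] = a_mean,
                      _["n_kept"] = kept);
}
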