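// Metropolis-within-Gibbs sampler for the genetically structured
// environmental variance model (single environment, single trait):
//   y | b,a,c ~ N(X b + Z a + W c, Diag(v)),  v_i = exp(xs_i' bs + as_z + cs_w)
//   (a, as) ~ N(0, G2 (x) A),  c ~ N(0, I sigc2),  cs ~ N(0, I sigcs2)
// Location parameters (b, a, c) have exact heteroskedastic normal
// conditionals; dispersion parameters (bs, as, cs) are updated by single-site
// random-walk Metropolis-Hastings with scales adapted only during burn-in;
// G2 is conjugate inverse-Wishart and the hapa variances conjugate
// scaled-inverse-chi-square. R's RNG throughout.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat riwish2(double df, const arma::mat& S) {
  const int d = S.n_rows;
  arma::mat Sinv = arma::inv_sympd(arma::symmatu(S));
  arma::mat L = arma::chol(Sinv, "lower");
  arma::mat A(d, d, arma::fill::zeros);
  for (int i = 0; i < d; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  arma::mat LAinv = arma::inv(arma::trimatl(LA));
  return LAinv.t() * LAinv;
}

static const double ETA_MAX = 40.0;  // proposals beyond exp(+-40) are rejected

// [[Rcpp::export]]
List gsevm_cpp(const arma::vec& y, const arma::mat& X, const arma::mat& Xs,
               IntegerVector zi_in, IntegerVector wi_in,
               IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
               int n_animals,
               int n_iter, int burnin, int thin,
               double nu_g, const arma::mat& S_g,
               double nu_s, double s2_c, double s2_cs,
               List init, double scale_as, double scale_cs,
               arma::vec scale_bs, bool adapt, bool return_state) {
  const int n = y.n_elem;
  const int N = n_animals;
  const int p = X.n_cols;
  const int ps = Xs.n_cols;
  std::vector<int> zi(zi_in.begin(), zi_in.end());
  std::vector<int> wi(wi_in.begin(), wi_in.end());
  int q = 0;
  for (int r = 0; r < n; ++r) if (wi[r] + 1 > q) q = wi[r] + 1;

  std::vector<int> rec_of(N, -1);
  for (int r = 0; r < n; ++r) rec_of[zi[r]] = r;
  std::vector<std::vector<int>> fam_recs(q), fam_anim(q);
  for (int r = 0; r < n; ++r) {
    if (wi[r] >= 0) {
      fam_recs[wi[r]].push_back(r);
      fam_anim[wi[r]].push_back(zi[r]);
    }
  }
  // per-family 1_S' Ainv 1_S over recorded members (for reallocation moves)
  std::vector<double> fam_qss(q, 0.0);
  {
    std::vector<char> inS(N, 0);
    for (int f = 0; f < q; ++f) {
      const std::vector<int>& S = fam_anim[f];
      for (size_t u = 0; u < S.size(); ++u) inS[S[u]] = 1;
      double qs = 0.0;
      for (size_t u = 0; u < S.size(); ++u) {
        const int i = S[u];
        for (int kk = Ap[i]; kk < Ap[i + 1]; ++kk)
          if (inS[Ai[kk]]) qs += Ax[kk];
      }
      fam_qss[f] = qs;
      for (size_t u = 0; u < S.size(); ++u) inS[S[u]] = 0;
    }
  }
  // column supports of Xs for the bs updates
  std::vector<std::vector<int>> bs_supp(ps);
  for (int j = 0; j < ps; ++j)
    for (int r = 0; r < n; ++r)
      if (Xs(r, j) != 0.0) bs_supp[j].push_back(r);

  arma::vec b = as<arma::vec>(init["b"]);
  arma::vec a = as<arma::vec>(init["a"]);
  arma::vec c = as<arma::vec>(init["c"]);
  arma::vec bs = as<arma::vec>(init["bs"]);
  arma::vec as_ = as<arma::vec>(init["as"]);
  arma::vec cs = as<arma::vec>(init["cs"]);
  arma::mat G2 = as<arma::mat>(init["G2"]);
  double sigc2 = as<double>(init["sigc2"]);
  double sigcs2 = as<double>(init["sigcs2"]);

  arma::vec eta(n), v(n), e(n);
  auto refresh = [&]() {
    eta = (ps > 0) ? arma::vec(Xs * bs) : arma::vec(n, arma::fill::zeros);
    for (int r = 0; r < n; ++r) {
      eta[r] += as_[zi[r]] + (wi[r] >= 0 ? cs[wi[r]] : 0.0);
      v[r] = std::exp(eta[r]);
    }
    e = y;
    if (p > 0) e -= X * b;
    for (int r = 0; r < n; ++r) e[r] -= a[zi[r]] + (wi[r] >= 0 ? c[wi[r]] : 0.0);
  };
  refresh();

  const int n_keep = (n_iter - burnin + thin - 1) / thin;
  // columns: sigma_a2, sigma_astar2, rho, sigc2, sigcs2, then b, then bs
  arma::mat samples(std::max(n_keep, 1), 5 + p + ps, arma::fill::zeros);
  arma::vec a_mean(N, arma::fill::zeros), as_mean(N, arma::fill::zeros);
  int kept = 0;

  long acc_as = 0, att_as = 0, acc_cs = 0, att_cs = 0;
  arma::vec acc_bs(ps, arma::fill::zeros), att_bs(ps, arma::fill::zeros);
  long bacc_as = 0, batt_as = 0, bacc_cs = 0, batt_cs = 0;
  arma::vec bacc_bs(ps, arma::fill::zeros), batt_bs(ps, arma::fill::zeros);
  double scale_iw[3] = {0.1, 0.1, 0.1};
  long acc_iw[3] = {0, 0, 0}, att_iw[3] = {0, 0, 0};
  long bacc_iw[3] = {0, 0, 0}, batt_iw[3] = {0, 0, 0};
  double scale_nc_c = 0.3, scale_nc_cs = 0.3;
  long bacc_nc_c = 0, batt_nc_c = 0, bacc_nc_cs = 0, batt_nc_cs = 0;
  arma::vec at1(N), at2(N);  // whitened genetic effects for interweaving
  const int adapt_batch = 50;

  for (int it = 0; it < n_iter; ++it) {
    // ---- location: fixed effects (heteroskedastic conjugate block) ----
    if (p > 0) {
      arma::vec w = 1.0 / v;
      arma::vec r = e + X * b;
      arma::mat Xw = X.each_col() % w;
      arma::mat P = X.t() * Xw + 1e-10 * arma::eye(p, p);
      arma::vec rhs = Xw.t() * r;
      arma::mat L = arma::chol(arma::symmatu(P), "lower");
      arma::vec mu = arma::solve(arma::trimatu(L.t()),
                                 arma::solve(arma::trimatl(L), rhs));
      arma::vec zdraw(p);
      for (int j = 0; j < p; ++j) zdraw(j) = R::norm_rand();
      arma::vec bnew = mu + arma::solve(arma::trimatu(L.t()), zdraw);
      e = r - X * bnew;
      b = bnew;
    }

    // ---- location: breeding values, single site ----
    double g11 = G2(0, 0), g12 = G2(0, 1), g22 = G2(1, 1);
    double gam = g12 / g22;                       // E[a | as] slope
    double kap = std::max(g11 - g12 * g12 / g22, 1e-12);
    for (int i = 0; i < N; ++i) {
      double diag = 0.0, dsum = 0.0;
      for (int kk = Ap[i]; kk < Ap[i + 1]; ++kk) {
        const int j = Ai[kk];
        if (j == i) { diag = Ax[kk]; continue; }
        dsum += Ax[kk] * (a[j] - gam * as_[j]);
      }
      double mu0 = gam * as_[i] - dsum / diag;
      double prec = diag / kap;
      double rhs = prec * mu0;
      const int r = rec_of[i];
      if (r >= 0) {
        prec += 1.0 / v[r];
        rhs += (e[r] + a[i]) / v[r];
      }
      double anew = rhs / prec + R::norm_rand() / std::sqrt(prec);
      if (r >= 0) e[r] += a[i] - anew;
      a[i] = anew;
    }

    // ---- location: hapa effects ----
    for (int f = 0; f < q; ++f) {
      double prec = 1.0 / sigc2, rhs = 0.0;
      const std::vector<int>& fr = fam_recs[f];
      for (size_t u = 0; u < fr.size(); ++u) {
        prec += 1.0 / v[fr[u]];
        rhs += (e[fr[u]] + c[f]) / v[fr[u]];
      }
      double cnew = rhs / prec + R::norm_rand() / std::sqrt(prec);
      for (size_t u = 0; u < fr.size(); ++u) e[fr[u]] += c[f] - cnew;
      c[f] = cnew;
    }

    // ---- dispersion: fixed effects, single-coordinate random walk ----
    for (int j = 0; j < ps; ++j) {
      double del = R::norm_rand() * scale_bs[j];
      double dll = 0.0;
      bool ok = true;
      const std::vector<int>& sup = bs_supp[j];
      for (size_t u = 0; u < sup.size(); ++u) {
        const int r = sup[u];
        double de = del * Xs(r, j);
        double etn = eta[r] + de;
        if (std::abs(etn) > ETA_MAX) { ok = false; break; }
        dll += -0.5 * de - 0.5 * e[r] * e[r] * (std::exp(-etn) - 1.0 / v[r]);
      }
      att_bs[j] += 1; batt_bs[j] += 1;
      if (ok && std::log(R::unif_rand()) < dll) {
        bs[j] += del;
        for (size_t u = 0; u < sup.size(); ++u) {
          const int r = sup[u];
          eta[r] += del * Xs(r, j);
          v[r] = std::exp(eta[r]);
        }
        acc_bs[j] += 1; bacc_bs[j] += 1;
      }
    }

    // ---- dispersion: breeding values ----
    double gams = g12 / g11;                      // E[as | a] slope
    double kaps = std::max(g22 - g12 * g12 / g11, 1e-12);
    for (int i = 0; i < N; ++i) {
      double diag = 0.0, dsum = 0.0;
      for (int kk = Ap[i]; kk < Ap[i + 1]; ++kk) {
        const int j = Ai[kk];
        if (j == i) { diag = Ax[kk]; continue; }
        dsum += Ax[kk] * (as_[j] - gams * a[j]);
      }
      double mu0 = gams * a[i] - dsum / diag;
      double prec0 = diag / kaps;
      const int r = rec_of[i];
      if (r < 0) {  // no record: exact conditional-normal draw
        as_[i] = mu0 + R::norm_rand() / std::sqrt(prec0);
        continue;
      }
      double del = R::norm_rand() * scale_as;
      double asn = as_[i] + del;
      double etn = eta[r] + del;
      ++att_as; ++batt_as;
      if (std::abs(etn) > ETA_MAX) continue;
      double dll = -0.5 * del - 0.5 * e[r] * e[r] * (std::exp(-etn) - 1.0 / v[r])
        - 0.5 * prec0 * ((asn - mu0) * (asn - mu0) - (as_[i] - mu0) * (as_[i] - mu0));
      if (std::log(R::unif_rand()) < dll) {
        as_[i] = asn;
        eta[r] = etn;
        v[r] = std::exp(etn);
        ++acc_as; ++bacc_as;
      }
    }

    // ---- dispersion: hapa effects ----
    for (int f = 0; f < q; ++f) {
      double del = R::norm_rand() * scale_cs;
      double csn = cs[f] + del;
      double dll = -0.5 * (csn * csn - cs[f] * cs[f]) / sigcs2;
      bool ok = true;
      const std::vector<int>& fr = fam_recs[f];
      for (size_t u = 0; u < fr.size(); ++u) {
        const int r = fr[u];
        double etn = eta[r] + del;
        if (std::abs(etn) > ETA_MAX) { ok = false; break; }
        dll += -0.5 * del - 0.5 * e[r] * e[r] * (std::exp(-etn) - 1.0 / v[r]);
      }
      ++att_cs; ++batt_cs;
      if (ok && std::log(R::unif_rand()) < dll) {
        cs[f] = csn;
        for (size_t u = 0; u < fr.size(); ++u) {
          eta[fr[u]] += del;
          v[fr[u]] = std::exp(eta[fr[u]]);
        }
        ++acc_cs; ++bacc_cs;
      }
    }

    // ---- reallocation moves: exact Gibbs along directions that leave all
    // residuals and log-variances unchanged, mixing the genetic-vs-hapa
    // split on each level: (c_f + d, a_family - d) and (cs_f + d*,
    // as_family - d*). Conditionals are Gaussian from the priors alone.
    if (q > 0) {
      const double det = G2(0, 0) * G2(1, 1) - G2(0, 1) * G2(0, 1);
      const double gi11 = G2(1, 1) / det, gi22 = G2(0, 0) / det,
                   gi12 = -G2(0, 1) / det;
      for (int f = 0; f < q; ++f) {
        const std::vector<int>& S = fam_anim[f];
        if (S.empty()) continue;
        double sa = 0.0, sas = 0.0;
        for (size_t u = 0; u < S.size(); ++u) {
          const int i = S[u];
          for (int kk = Ap[i]; kk < Ap[i + 1]; ++kk) {
            sa += Ax[kk] * a[Ai[kk]];
            sas += Ax[kk] * as_[Ai[kk]];
          }
        }
        // mean level
        {
          const double Aq = gi11 * fam_qss[f] + 1.0 / sigc2;
          const double Bl = c[f] / sigc2 - (gi11 * sa + gi12 * sas);
          const double d = -Bl / Aq + R::norm_rand() / std::sqrt(Aq);
          for (size_t u = 0; u < S.size(); ++u) a[S[u]] -= d;
          c[f] += d;
          sa -= d * fam_qss[f];  // keep 1_S' Ainv a current for the next move
        }
        // dispersion level
        {
          const double Aq = gi22 * fam_qss[f] + 1.0 / sigcs2;
          const double Bl = cs[f] / sigcs2 - (gi12 * sa + gi22 * sas);
          const double d = -Bl / Aq + R::norm_rand() / std::sqrt(Aq);
          for (size_t u = 0; u < S.size(); ++u) as_[S[u]] -= d;
          cs[f] += d;
        }
      }
    }

    // ---- covariances ----
    double q11 = 0, q12 = 0, q22 = 0;
    for (int j = 0; j < N; ++j) {
      for (int kk = Ap[j]; kk < Ap[j + 1]; ++kk) {
        const int r = Ai[kk];
        const double v = Ax[kk];
        q11 += v * a[r] * a[j];
        q12 += v * a[r] * as_[j];
        q22 += v * as_[r] * as_[j];
      }
    }
    arma::mat Q = {{q11, q12}, {q12, q22}};
    G2 = riwish2(nu_g + N, S_g + Q);

    // ---- interweaving: non-centered re-update of G2 ----
    // With whitened effects (at1, at2) = (L^-1 (x) I)(a, as) held fixed,
    // random-walk MH on theta = (log l11, l21, log l22) of L = chol(G2)
    // moves (G2, a, as) jointly and breaks the variance-effect funnel.
    {
      double l11 = std::sqrt(G2(0, 0));
      double l21 = G2(0, 1) / l11;
      double l22 = std::sqrt(std::max(G2(1, 1) - l21 * l21, 1e-12));
      for (int i = 0; i < N; ++i) {
        at1[i] = a[i] / l11;
        at2[i] = (as_[i] - l21 * at1[i]) / l22;
      }
      // log target in theta, up to a constant:
      //   loglik + log IW(G2(theta); nu_g, S_g) + 3 log l11 + 2 log l22
      // (Jacobian of G2 -> L plus the log transforms of the diagonals)
      auto logtarget = [&](double c11, double c21, double c22,
                           bool& finite) -> double {
        double detG = c11 * c11 * c22 * c22;
        // tr(S_g G^-1) via G^-1 = L^-T L^-1
        double i11 = 1.0 / c11, i21 = -c21 / (c11 * c22), i22 = 1.0 / c22;
        // G^-1 entries
        double g11i = i11 * i11 + i21 * i21, g12i = i21 * i22,
               g22i = i22 * i22;
        double tr = S_g(0, 0) * g11i + 2.0 * S_g(0, 1) * g12i +
                    S_g(1, 1) * g22i;
        double lp = -0.5 * (nu_g + 3.0) * std::log(detG) - 0.5 * tr +
                    3.0 * std::log(c11) + 2.0 * std::log(c22);
        finite = true;
        for (int r = 0; r < n; ++r) {
          const int i = zi[r];
          double ai = c11 * at1[i];
          double asi = c21 * at1[i] + c22 * at2[i];
          double er = e[r] + a[i] - ai;
          double etr = eta[r] + asi - as_[i];
          if (std::abs(etr) > ETA_MAX) { finite = false; return lp; }
          lp += -0.5 * etr - 0.5 * er * er * std::exp(-etr);
        }
        return lp;
      };
      bool fin0;
      double lp_cur = logtarget(l11, l21, l22, fin0);
      if (fin0) {
        double th[3] = {std::log(l11), l21, std::log(l22)};
        for (int j = 0; j < 3; ++j) {
          double thn0 = th[0], thn1 = th[1], thn2 = th[2];
          double del = R::norm_rand() * scale_iw[j];
          if (j == 0) thn0 += del; else if (j == 1) thn1 += del; else thn2 += del;
          double c11 = std::exp(thn0), c21 = thn1, c22 = std::exp(thn2);
          ++att_iw[j]; ++batt_iw[j];
          bool fin;
          double lp_new = logtarget(c11, c21, c22, fin);
          if (fin && std::log(R::unif_rand()) < lp_new - lp_cur) {
            th[0] = thn0; th[1] = thn1; th[2] = thn2;
            l11 = c11; l21 = c21; l22 = c22;
            lp_cur = lp_new;
            ++acc_iw[j]; ++bacc_iw[j];
          }
        }
        // reconstruct effects and caches from the accepted factorization
        for (int i = 0; i < N; ++i) {
          double ai = l11 * at1[i];
          double asi = l21 * at1[i] + l22 * at2[i];
          const int r = rec_of[i];
          if (r >= 0) {
            e[r] += a[i] - ai;
            eta[r] += asi - as_[i];
            v[r] = std::exp(eta[r]);
          }
          a[i] = ai;
          as_[i] = asi;
        }
        G2(0, 0) = l11 * l11;
        G2(0, 1) = G2(1, 0) = l11 * l21;
        G2(1, 1) = l21 * l21 + l22 * l22;
      }
    }

    if (q > 0) {
      sigc2 = (nu_s * s2_c + arma::dot(c, c)) / R::rchisq(nu_s + q);
      sigcs2 = (nu_s * s2_cs + arma::dot(cs, cs)) / R::rchisq(nu_s + q);

      // interweaving: non-centered rescale of (c, sigc2) and (cs, sigcs2)
      {
        const double th = std::log(sigc2);
        const double del = R::norm_rand() * scale_nc_c;
        const double ratio = std::exp(0.5 * del);
        double dll = 0.0;
        for (int r = 0; r < n; ++r) {
          const int f = wi[r];
          if (f < 0) continue;
          const double en = e[r] + (1.0 - ratio) * c[f];
          dll += -0.5 * (en * en - e[r] * e[r]) / v[r];
        }
        const double s2n = std::exp(th + del);
        dll += (-(0.5 * nu_s) * (th + del) - 0.5 * nu_s * s2_c / s2n)
             - (-(0.5 * nu_s) * th - 0.5 * nu_s * s2_c / sigc2);
        ++batt_nc_c;
        if (std::log(R::unif_rand()) < dll) {
          for (int r = 0; r < n; ++r)
            if (wi[r] >= 0) e[r] += (1.0 - ratio) * c[wi[r]];
          for (int f = 0; f < q; ++f) c[f] *= ratio;
          sigc2 = s2n;
          ++bacc_nc_c;
        }
      }
      {
        const double th = std::log(sigcs2);
        const double del = R::norm_rand() * scale_nc_cs;
        const double ratio = std::exp(0.5 * del);
        double dll = 0.0;
        bool ok = true;
        for (int r = 0; r < n; ++r) {
          const int f = wi[r];
          if (f < 0) continue;
          const double deta = (ratio - 1.0) * cs[f];
          const double etn = eta[r] + deta;
          if (std::abs(etn) > ETA_MAX) { ok = false; break; }
          dll += -0.5 * deta -
            0.5 * e[r] * e[r] * (std::exp(-etn) - 1.0 / v[r]);
        }
        const double s2n = std::exp(th + del);
        dll += (-(0.5 * nu_s) * (th + del) - 0.5 * nu_s * s2_cs / s2n)
             - (-(0.5 * nu_s) * th - 0.5 * nu_s * s2_cs / sigcs2);
        ++batt_nc_cs;
        if (ok && std::log(R::unif_rand()) < dll) {
          for (int r = 0; r < n; ++r) {
            if (wi[r] >= 0) {
              eta[r] += (ratio - 1.0) * cs[wi[r]];
              v[r] = std::exp(eta[r]);
            }
          }
          for (int f = 0; f < q; ++f) cs[f] *= ratio;
          sigcs2 = s2n;
          ++bacc_nc_cs;
        }
      }
    }

    // ---- adapt proposal scales during burn-in only ----
    if (adapt && it < burnin && (it + 1) % adapt_batch == 0) {
      auto tune = [](double& s, double acc, double att) {
        if (att > 0) {
          double rate = acc / att;
          s *= std::exp(0.6 * (rate - 0.3));
          s = std::min(std::max(s, 1e-4), 50.0);
        }
      };
      double r_as = (double)bacc_as, t_as = (double)batt_as;
      tune(scale_as, r_as, t_as);
      double r_cs = (double)bacc_cs, t_cs = (double)batt_cs;
      tune(scale_cs, r_cs, t_cs);
      for (int j = 0; j < ps; ++j) {
        double sj = scale_bs[j];
        tune(sj, bacc_bs[j], batt_bs[j]);
        scale_bs[j] = sj;
      }
      for (int j = 0; j < 3; ++j) {
        tune(scale_iw[j], (double)bacc_iw[j], (double)batt_iw[j]);
        bacc_iw[j] = batt_iw[j] = 0;
      }
      tune(scale_nc_c, (double)bacc_nc_c, (double)batt_nc_c);
      tune(scale_nc_cs, (double)bacc_nc_cs, (double)batt_nc_cs);
      bacc_nc_c = batt_nc_c = bacc_nc_cs = batt_nc_cs = 0;
      bacc_as = batt_as = bacc_cs = batt_cs = 0;
      bacc_bs.zeros(); batt_bs.zeros();
    }

    if ((it + 1) % 500 == 0) refresh();  // control floating-point drift

    // ---- store ----
    if (it >= burnin && (it - burnin) % thin == 0) {
      double sa2 = G2(0, 0), sas2 = G2(1, 1);
      double rho = G2(0, 1) / std::sqrt(sa2 * sas2);
      int col = 0;
      samples(kept, col++) = sa2;
      samples(kept, col++) = sas2;
      samples(kept, col++) = rho;
      samples(kept, col++) = sigc2;
      samples(kept, col++) = sigcs2;
      for (int j = 0; j < p; ++j) samples(kept, col++) = b[j];
      for (int j = 0; j < ps; ++j) samples(kept, col++) = bs[j];
      a_mean += a; as_mean += as_;
      ++kept;
    }
  }
  if (kept > 0) { a_mean /= kept; as_mean /= kept; }

  List state = List::create(_["b"] = b, _["a"] = a, _["c"] = c,
                            _["bs"] = bs, _["as"] = as_, _["cs"] = cs,
                            _["G2"] = G2, _["sigc2"] = sigc2,
                            _["sigcs2"] = sigcs2);
  List accept = List::create(
    _["as"] = att_as > 0 ? (double)acc_as / att_as : NA_REAL,
    _["cs"] = att_cs > 0 ? (double)acc_cs / att_cs : NA_REAL,
    _["bs"] = ps > 0 ? wrap(arma::vec(acc_bs / arma::clamp(att_bs, 1.0, 1e18)))
                     : wrap(NumericVector(0)),
    _["iw"] = NumericVector::create(
      att_iw[0] > 0 ? (double)acc_iw[0] / att_iw[0] : NA_REAL,
      att_iw[1] > 0 ? (double)acc_iw[1] / att_iw[1] : NA_REAL,
      att_iw[2] > 0 ? (double)acc_iw[2] / att_iw[2] : NA_REAL));
  return List::create(_["samples"] = samples.rows(0, std::max(kept - 1, 0)),
                      _["a_mean"] = a_mean, _["as_mean"] = as_mean,
                      _["accept"] = accept,
                      _["scales"] = List::create(_["as"] = scale_as,
                                                 _["cs"] = scale_cs,
                                                 _["bs"] = scale_bs),
                      _["state"] = return_state ? state : List::create(),
                      _["n_kept"] = kept);
}
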