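#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo (1992) algorithm.
// sire/dam are 0-based positions in a parent-first sorted pedigree; -1 = unknown.
// Unknown parents are treated as draws from a single non-inbred base population.
// [[Rcpp::export]]
NumericVector inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> L(n, 0.0);
  std::vector<int> touched;
  touched.reserve(256);

  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s < 0 && d < 0) { F[i] = 0.0; continue; }
    if (s < 0 || d < 0) { F[i] = 0.0; continue; }  // one unknown parent: F = 0
    if (i > 0 && s == sire[i - 1] && d == dam[i - 1] &&
        sire[i - 1] >= 0 && dam[i - 1] >= 0) {
      F[i] = F[i - 1];  // full sibs share F
      continue;
    }
    // a_ii = sum_j L_j^2 D_j over ancestors j of i (including i); F_i = a_ii - 1
    touched.clear();
    L[i] = 1.0;
    touched.push_back(i);
    double aii = 0.0;
    for (int j = i; j >= 0; --j) {
      if (L[j] == 0.0) continue;
      const double Lj = L[j];
      const int sj = sire[j], dj = dam[j];
      if (sj >= 0) { if (L[sj] == 0.0) touched.push_back(sj); L[sj] += 0.5 * Lj; }
      if (dj >= 0) { if (L[dj] == 0.0) touched.push_back(dj); L[dj] += 0.5 * Lj; }
      double Dj;
      if (sj >= 0 && dj >= 0)      Dj = 0.5  - 0.25 * (F[sj] + F[dj]);
      else if (sj >= 0)            Dj = 0.75 - 0.25 * F[sj];
      else if (dj >= 0)            Dj = 0.75 - 0.25 * F[dj];
      else                         Dj = 1.0;
      aii += Lj * Lj * Dj;
    }
    F[i] = aii - 1.0;
    for (size_t k = 0; k < touched.size(); ++k) L[touched[k]] = 0.0;
  }
  return F;
}

// Dense numerator relationship matrix by the tabular method.
// a_ij = 0.5 (a_i,sire(j) + a_i,dam(j)) for i < j; diagonal 1 + F.
// [[Rcpp::export]]
NumericMatrix amatrix_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int j = 0; j < n; ++j) {
    const int s = sire[j], d = dam[j];
    for (int i = 0; i < j; ++i) {
      double v = 0.0;
      if (s >= 0) v += 0.5 * A(i, s);
      if (d >= 0) v += 0.5 * A(i, d);
      A(i, j) = v;
      A(j, i) = v;
    }
    const double asd = (s >= 0 && d >= 0) ? A(s, d) : 0.0;
    A(j, j) = 1.0 + 0.5 * asd;
  }
  return A;
}
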