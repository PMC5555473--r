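#include <Rcpp.h>
#include <map>
#include <functional>
using namespace Rcpp;

// Inbreeding coefficients by ancestor traversal (Meuwissen & Luo style).
// `sire` and `dam` are 1-based positions in a topologically ordered pedigree
// (parents before offspring); 0 marks an unknown parent.
//
// For animal i with both parents known, the diagonal of the numerator
// relationship matrix is accumulated as a_ii = sum_j L_j^2 D_j over the
// ancestors j of i, where L_j is the partial relationship of i to j and
// D_j the Mendelian sampling variance of j; F_i = a_ii - 1.
// [[Rcpp::export]]
NumericVector inbreeding_ml(IntegerVector sire, IntegerVector dam) {
  int n = sire.size();
  NumericVector F(n);
  // F of an unknown parent enters the Mendelian sampling variance as -1,
  // which folds the unknown-parent cases into the one formula below.
  std::function<double(int)> fpar = [&](int p) { return p == 0 ? -1.0 : F[p - 1]; };
  for (int i = 0; i < n; ++i) {
    int s = sire[i], d = dam[i];
    if (s > i || d > i)
      stop("pedigree is not topologically ordered at position %d", i + 1);
    if (s == 0 || d == 0) { F[i] = 0.0; continue; }
    // traverse ancestors from youngest to oldest
    std::map<int, double, std::greater<int> > L;
    L[i + 1] = 1.0;
    double aii = 0.0;
    while (!L.empty()) {
      std::map<int, double, std::greater<int> >::iterator it = L.begin();
      int j = it->first;
      double r = it->second;
      L.erase(it);
      int js = sire[j - 1], jd = dam[j - 1];
      double Dj = 0.5 - 0.25 * (fpar(js) + fpar(jd));
      aii += r * r * Dj;
      if (js > 0) L[js] += 0.5 * r;
      if (jd > 0) L[jd] += 0.5 * r;
    }
    F[i] = aii - 1.0;
  }
  return F;
}
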