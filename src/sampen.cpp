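#include <Rcpp.h>
using namespace Rcpp;

// Template-match counts for sample entropy (Richman & Moorman).
// Templates of length m are taken at i = 1..N-m so that every m-template
// has an (m+1)-length extension; pairs are unordered and self-matches are
// excluded. Distance is Chebyshev (max-norm); matches use "<= r".
// [[Rcpp::export]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool ok = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return NumericVector::create(_["A"] = A, _["B"] = B);
}
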