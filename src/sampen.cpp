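#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Template-match counts for sample entropy. Templates of length m are taken
// at positions i = 0..N-m-1 (so the (m+1)-length extension always exists);
// B counts unordered pairs i<j whose length-m templates agree within
// Chebyshev tolerance r, A the subset whose length-(m+1) extensions also
// agree. Self-matches are excluded by construction.
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates with an extension
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
      }
      if (!match) continue;
      B += 1.0;
      if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
    }
  }
  return List::create(_["A"] = A, _["B"] = B);
}
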