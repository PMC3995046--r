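#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Direct-form II transposed IIR/FIR filter with initial state zi.
// b, a: coefficient vectors (a[0] need not be 1); zi: length max(nb,na)-1.
// [[Rcpp::export]]
NumericVector df2t_filter(NumericVector b, NumericVector a, NumericVector x,
                          NumericVector zi) {
  int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0), z(std::max(nf - 1, 1), 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  double a0 = aa[0];
  if (a0 == 0.0) stop("a[1] must be nonzero");
  for (int i = 0; i < nf; ++i) { bb[i] /= a0; aa[i] /= a0; }
  for (int i = 0; i < zi.size() && i < nf - 1; ++i) z[i] = zi[i];

  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nf > 1 ? z[0] : 0.0);
    for (int j = 1; j < nf - 1; ++j)
      z[j - 1] = bb[j] * xi + z[j] - aa[j] * yi;
    if (nf > 1)
      z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}
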