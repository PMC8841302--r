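#include <Rcpp.h>
using namespace Rcpp;

// Direct-form II transposed IIR filter with initial state zi (length
// max(length(a), length(b)) - 1). a[0] must be 1 (caller normalizes).
// [[Rcpp::export(name = ".iirFilter")]]
NumericVector iirFilter(NumericVector b, NumericVector a, NumericVector x,
                        NumericVector zi) {
  int nb = b.size(), na = a.size();
  int nord = std::max(nb, na) - 1;
  int n = x.size();
  std::vector<double> bb(nord + 1, 0.0), aa(nord + 1, 0.0);
  for (int i = 0; i < nb; ++i) bb[i] = b[i];
  for (int i = 0; i < na; ++i) aa[i] = a[i];
  std::vector<double> z(nord, 0.0);
  for (int i = 0; i < nord && i < zi.size(); ++i) z[i] = zi[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nord > 0 ? z[0] : 0.0);
    for (int j = 0; j < nord - 1; ++j)
      z[j] = bb[j + 1] * xi + z[j + 1] - aa[j + 1] * yi;
    if (nord > 0) z[nord - 1] = bb[nord] * xi - aa[nord] * yi;
    y[i] = yi;
  }
  return y;
}
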