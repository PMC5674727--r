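#include <Rcpp.h>
using namespace Rcpp;

// For each row of d, the column indices (1-based) of the k smallest values
// in ascending order. Ties resolve to the lower column index. Scans in
// column-major order to stay cache-friendly.
// [[Rcpp::export]]
IntegerMatrix row_min_k_cpp(NumericMatrix d, int k) {
  int n = d.nrow(), m = d.ncol();
  if (k > m) k = m;
  std::vector<double> val((size_t)n * k, R_PosInf);
  std::vector<int> idx((size_t)n * k, 0);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      double v = d(i, j);
      double *vr = &val[(size_t)i * k];
      if (v >= vr[k - 1]) continue;
      int *ir = &idx[(size_t)i * k];
      int pos = k - 1;
      while (pos > 0 && vr[pos - 1] > v) {
        vr[pos] = vr[pos - 1];
        ir[pos] = ir[pos - 1];
        --pos;
      }
      vr[pos] = v;
      ir[pos] = j + 1;
    }
  }
  IntegerMatrix out(n, k);
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < k; ++t) out(i, t) = idx[(size_t)i * k + t];
  return out;
}
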