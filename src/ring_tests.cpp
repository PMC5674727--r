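#include <Rcpp.h>
using namespace Rcpp;

// Ring offsets, clockwise from 12 o'clock, y increasing downwards.
// Must stay in lock-step with inner_ring_offsets() / outer_ring_offsets().
static const int IN_DX[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int IN_DY[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int OUT_DX[16] = {0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1};
static const int OUT_DY[16] = {-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3};

// median of 4: mean of the two middle order statistics
static double median4(double a, double b, double c, double d) {
  double lo = std::min(std::min(a, b), std::min(c, d));
  double hi = std::max(std::max(a, b), std::max(c, d));
  return (a + b + c + d - lo - hi) / 2.0;
}

static double median8(const double *v) {
  double s[8];
  std::copy(v, v + 8, s);
  std::sort(s, s + 8);
  return (s[3] + s[4]) / 2.0;
}

// inner: 8 ring values; returns true and sets beta when a saddle shape passes
static bool inner_test(const double *inn, double &beta) {
  double top = inn[0], right = inn[2], bottom = inn[4], left = inn[6];
  double ur = inn[1], dr = inn[3], dl = inn[5], ul = inn[7];
  bool plus = (std::min(top, bottom) > std::max(left, right)) ||
              (std::max(top, bottom) < std::min(left, right));
  bool cross = (std::min(ur, dl) > std::max(dr, ul)) ||
               (std::max(ur, dl) < std::min(dr, ul));
  if (!plus && !cross) return false;
  if (plus && cross) {
    beta = median8(inn);
  } else if (plus) {
    beta = median4(top, bottom, left, right);
  } else {
    beta = median4(ur, dl, dr, ul);
  }
  return true;
}

// labels: -1 = d, 0 = s, 1 = l. Cyclic saddle pattern test:
// s-runs <= 2; arcs (maximal d/l runs) length in [2, 8]; after dropping s,
// consecutive arcs alternate labels cyclically; >= 2 arcs of each label.
static bool outer_test(const int *lab, int n) {
  int start = -1;
  for (int i = 0; i < n; ++i) {
    if (lab[i] != lab[(i + n - 1) % n]) { start = i; break; }
  }
  if (start < 0) return false;  // all one label (incl. all s)
  // collect cyclic runs starting at a run boundary
  std::vector<int> run_lab(n), run_len(n);
  int nrun = 0;
  int i = 0;
  while (i < n) {
    int l = lab[(start + i) % n];
    int len = 1;
    while (i + len < n && lab[(start + i + len) % n] == l) ++len;
    run_lab[nrun] = l; run_len[nrun] = len; ++nrun;
    i += len;
  }
  int n_d = 0, n_l = 0;
  for (int r = 0; r < nrun; ++r) {
    if (run_lab[r] == 0) {
      if (run_len[r] > 2) return false;
    } else {
      if (run_len[r] < 2 || run_len[r] > 8) return false;
      if (run_lab[r] == -1) ++n_d; else ++n_l;
    }
  }
  if (n_d < 2 || n_l < 2) return false;
  // alternation of the arc labels after dropping s runs
  int prev = 99;
  int first = 99, last = 99;
  for (int r = 0; r < nrun; ++r) {
    if (run_lab[r] == 0) continue;
    if (prev != 99 && run_lab[r] == prev) return false;
    if (first == 99) first = run_lab[r];
    prev = run_lab[r];
    last = run_lab[r];
  }
  if (first == last) return false;  // cyclic neighbors share a label
  return true;
}

// [[Rcpp::export]]
List ring_test_bulk_cpp(NumericMatrix dog, double epsilon) {
  int N = dog.nrow(), M = dog.ncol();
  std::vector<int> xs, ys;
  std::vector<double> resp, betas;
  long n_cand = 0, n_inner = 0;
  double inn[8], out[16];
  int lab[16];
  if (M >= 7 && N >= 7) {
    for (int y = 4; y <= N - 3; ++y) {        // 1-based bounds
      for (int x = 4; x <= M - 3; ++x) {
        ++n_cand;
        int r = y - 1, c = x - 1;             // 0-based array access
        for (int j = 0; j < 8; ++j)
          inn[j] = dog(r + IN_DY[j], c + IN_DX[j]);
        double beta;
        if (!inner_test(inn, beta)) continue;
        ++n_inner;
        double lo = beta - epsilon, hi = beta + epsilon;
        double sum_d = 0, sum_l = 0;
        int cnt_d = 0, cnt_l = 0;
        for (int j = 0; j < 16; ++j) {
          double v = dog(r + OUT_DY[j], c + OUT_DX[j]);
          out[j] = v;
          if (v < lo) { lab[j] = -1; sum_d += v; ++cnt_d; }
          else if (v > hi) { lab[j] = 1; sum_l += v; ++cnt_l; }
          else lab[j] = 0;
        }
        if (!outer_test(lab, 16)) continue;
        double response = 0.0;
        if (cnt_d > 0 && cnt_l > 0)
          response = (beta - sum_d / cnt_d) + (sum_l / cnt_l - beta);
        xs.push_back(x); ys.push_back(y);
        resp.push_back(response); betas.push_back(beta);
      }
    }
  }
  return List::create(_["x"] = xs, _["y"] = ys, _["response"] = resp,
                      _["beta"] = betas,
                      _["n_candidates"] = (double)n_cand,
                      _["n_inner_pass"] = (double)n_inner);
}

// [[Rcpp::export]]
LogicalVector outer_test_bulk_cpp(IntegerMatrix labels) {
  // labels: rows = cases, columns = cyclic positions; values in {-1, 0, 1}
  int n = labels.nrow(), m = labels.ncol();
  LogicalVector out(n);
  std::vector<int> lab(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) lab[j] = labels(i, j);
    out[i] = outer_test(lab.data(), m);
  }
  return out;
}
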