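#include <Rcpp.h>
using namespace Rcpp;

// CUSUM scan statistics for iterative change-point detection.
//
// For a series x of length n with prefix sums of deviations
// S_k = sum_{i<=k} (x_i - xbar), two statistics are provided:
//
//  - "pair" (default): the standardized epidemic CUSUM
//        T = max_{i<j} |S_j - S_i| / sqrt(w (1 - w/n)),  w = j - i,
//    which has power for short states embedded in long ones (the window
//    (i, j] is tested against its complement); window and flank lengths
//    respect min_len.
//  - "range": max S - min S, the classic CUSUM range.
//
// Significance is assessed against random permutations of the segment
// (scale-invariant, so no variance estimate is needed). The permutation
// loop curtails early: a permutation stops as soon as it exceeds the
// observed statistic, and the whole loop stops once the exceedance count
// makes the p-value decision certain at level alpha.

// centred boxcar smoothing with shrinking windows at the ends; applied
// identically to the observed series and to every permutation, so the
// permutation test remains exact under exchangeability of the raw samples.
static void smooth_box(const std::vector<double>& x, std::vector<double>& y,
                       int w) {
  const int n = (int)x.size();
  if (w <= 1) { y = x; return; }
  const int h = w / 2;
  for (int i = 0; i < n; ++i) {
    int a = std::max(0, i - h), b = std::min(n - 1, i + h);
    double acc = 0.0;
    for (int k = a; k <= b; ++k) acc += x[k];
    y[i] = acc / (b - a + 1);
  }
}

static void prefix_dev(const std::vector<double>& x, std::vector<double>& S) {
  const int n = (int)x.size();
  double mean = 0.0;
  for (int i = 0; i < n; ++i) mean += x[i];
  mean /= n;
  double acc = 0.0;
  for (int i = 0; i < n; ++i) { acc += x[i] - mean; S[i] = acc; }
}

// max pair statistic; returns best value, fills bi/bj (0-based boundary
// indices: window is (bi, bj] in 1-based sample terms). early_stop > 0
// aborts the scan once the running max exceeds it (used in permutations).
static double pair_scan(const std::vector<double>& S, int n, int min_len,
                        int* bi, int* bj, double early_stop) {
  double best = -1.0;
  for (int w = min_len; w <= n - min_len; ++w) {
    const double denom = std::sqrt((double)w * (1.0 - (double)w / n));
    for (int i = 0; i + w <= n; ++i) {
      if (i != 0 && i < min_len) continue;          // left flank too short
      const int j = i + w;
      if (j != n && n - j < min_len) continue;      // right flank too short
      const double si = (i == 0) ? 0.0 : S[i - 1];
      double t = std::fabs(S[j - 1] - si) / denom;
      if (t > best) {
        best = t;
        if (bi) { *bi = i; *bj = j; }
        if (early_stop > 0 && best >= early_stop) return best;
      }
    }
  }
  return best;
}

static double range_scan(const std::vector<double>& S, int n) {
  double lo = 0.0, hi = 0.0;
  for (int i = 0; i < n; ++i) {
    if (S[i] < lo) lo = S[i];
    if (S[i] > hi) hi = S[i];
  }
  return hi - lo;
}

// Fisher-Yates shuffle driven by R's RNG (respects set.seed).
static void shuffle_r(std::vector<double>& x) {
  const int n = (int)x.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(x[i], x[j]);
  }
}

// [[Rcpp::export(name = ".cusum_scan")]]
List cusum_scan(NumericVector x, int min_len, std::string stat, int smooth_w) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> sm(n), S(n);
  smooth_box(xv, sm, smooth_w);
  prefix_dev(sm, S);
  if (stat == "pair") {
    int bi = -1, bj = -1;
    double obs = pair_scan(S, n, min_len, &bi, &bj, -1.0);
    return List::create(_["stat"] = obs, _["i"] = bi, _["j"] = bj);
  }
  double obs = range_scan(S, n);
  // argmax |S_k| with both parts >= min_len, for the split position
  int bk = -1; double bv = -1.0;
  for (int k = min_len; k <= n - min_len; ++k) {
    double v = std::fabs(S[k - 1]);
    if (v > bv) { bv = v; bk = k; }
  }
  return List::create(_["stat"] = obs, _["i"] = 0, _["j"] = bk);
}

// Curtailed permutation test: returns the exceedance count and the number
// of permutations actually run. Decision rule in R:
//   significant  iff  performed == B  and  (1 + exceed) / (B + 1) <= alpha.
// The loop stops once exceed reaches max_exceed = floor(alpha * (B + 1)),
// at which point significance is impossible.
// [[Rcpp::export(name = ".cusum_perm")]]
List cusum_perm(NumericVector x, int min_len, std::string stat,
                int B, double observed, int max_exceed, int smooth_w) {
  const int n = x.size();
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> sm(n), S(n);
  RNGScope scope;
  int exceed = 0, b = 0;
  for (b = 0; b < B; ++b) {
    shuffle_r(xv);
    smooth_box(xv, sm, smooth_w);
    prefix_dev(sm, S);
    double v;
    if (stat == "pair")
      v = pair_scan(S, n, min_len, nullptr, nullptr, observed);
    else
      v = range_scan(S, n);
    if (v >= observed) {
      if (++exceed >= max_exceed) { ++b; break; }
    }
  }
  return List::create(_["exceed"] = exceed, _["performed"] = b);
}
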