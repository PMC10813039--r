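#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// median of an already-sorted vector
static inline double sorted_median(const std::vector<double>& v) {
  size_t n = v.size();
  if (n == 0) return NA_REAL;
  if (n % 2 == 1) return v[n / 2];
  return 0.5 * (v[n / 2 - 1] + v[n / 2]);
}

static inline double median3(double a, double b, double c) {
  return std::max(std::min(a, b), std::min(std::max(a, b), c));
}

// Per-A-scan ILM detection on raw intensity profiles.
//
// prof: matrix with one row per A-scan, columns = depth (index 1 = vitreous
// side). Each row is median-3 smoothed along depth, a robust noise scale is
// taken as 1.4826 * MAD of the leading vitreous segment, and the detected
// depth is the first index whose smoothed value exceeds the expanding-median
// running baseline of all shallower samples by more than k * scale (with an
// absolute floor to break ties in noiseless data). Returns 1-based depth
// indices, -1 where no qualifying rise exists.
// [[Rcpp::export]]
IntegerVector ilm_detect_cpp(NumericMatrix prof, double k, double abs_floor) {
  int n = prof.nrow(), d = prof.ncol();
  IntegerVector out(n);
  std::vector<double> s(d), sorted;
  sorted.reserve(d);
  int q = std::max(4, d / 8);  // leading segment assumed vitreous
  if (q > d) q = d;
  for (int i = 0; i < n; ++i) {
    // median-3 smoothing with replicated ends
    for (int j = 0; j < d; ++j) {
      double a = prof(i, j > 0 ? j - 1 : 0);
      double b = prof(i, j);
      double c = prof(i, j < d - 1 ? j + 1 : d - 1);
      s[j] = median3(a, b, c);
    }
    // robust scale from leading segment: 1.4826 * MAD
    sorted.assign(s.begin(), s.begin() + q);
    std::sort(sorted.begin(), sorted.end());
    double med0 = sorted_median(sorted);
    for (int j = 0; j < q; ++j) sorted[j] = std::fabs(s[j] - med0);
    std::sort(sorted.begin(), sorted.end());
    double scale = 1.4826 * sorted_median(sorted);
    double thr_add = k * scale + abs_floor;

    // expanding-median baseline over s[0..j-1], first crossing wins
    int hit = -1;
    sorted.clear();
    sorted.push_back(s[0]);
    for (int j = 1; j < d; ++j) {
      double base = sorted_median(sorted);
      if (s[j] > base + thr_add) { hit = j; break; }
      sorted.insert(std::upper_bound(sorted.begin(), sorted.end(), s[j]), s[j]);
    }
    out[i] = hit < 0 ? -1 : hit + 1;  // 1-based for R
  }
  return out;
}

// NA-aware 2-D median filter on an integer surface (rows = B-scans,
// cols = A-scans). NA entries (failed A-scans) are ignored as neighbours and
// stay NA in the output. half = (window - 1) / 2.
// [[Rcpp::export]]
IntegerMatrix median_filter2d_cpp(IntegerMatrix x, int half) {
  int nr = x.nrow(), nc = x.ncol();
  IntegerMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((2 * half + 1) * (2 * half + 1));
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (x(r, c) == NA_INTEGER) { out(r, c) = NA_INTEGER; continue; }
      buf.clear();
      for (int dr = -half; dr <= half; ++dr) {
        int rr = r + dr;
        if (rr < 0 || rr >= nr) continue;
        for (int dc = -half; dc <= half; ++dc) {
          int cc = c + dc;
          if (cc < 0 || cc >= nc) continue;
          if (x(rr, cc) == NA_INTEGER) continue;
          buf.push_back((double)x(rr, cc));
        }
      }
      std::sort(buf.begin(), buf.end());
      out(r, c) = (int)std::lround(sorted_median(buf));
    }
  }
  return out;
}
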