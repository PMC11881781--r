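#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// median of a sorted window; even lengths average the two central order
// statistics, as R's median() and Matlab's median() do
static inline double sorted_median(const std::vector<double>& s) {
  const size_t len = s.size();
  const size_t mid = len / 2;
  if (len % 2 == 1) return s[mid];
  return (s[mid - 1] + s[mid]) / 2.0;
}

// median of the absolute deviations |s[j] - med| for a sorted window s.
// Going outward from the median the deviations form two sorted streams
// (left: med - s[l] increasing, right: s[r] - med increasing), so the k-th
// smallest deviation comes from a two-pointer merge — identical values to
// sorting the deviation multiset, at O(len/2) cost.
static double sorted_mad(const std::vector<double>& s, double med) {
  const int len = (int)s.size();
  int l = (len - 1) / 2;          // last element <= med by construction
  int r = l + 1;
  const int want1 = (len - 1) / 2;  // 0-based ranks of the central
  const int want2 = len / 2;        // deviation order statistics
  double d1 = 0.0, d2 = 0.0;
  for (int cnt = 0; cnt <= want2; ++cnt) {
    const double dl = (l >= 0) ? med - s[l] : R_PosInf;
    const double dr = (r < len) ? s[r] - med : R_PosInf;
    double d;
    if (dl <= dr) { d = dl; --l; } else { d = dr; ++r; }
    if (cnt == want1) d1 = d;
    if (cnt == want2) d2 = d;
  }
  return (want1 == want2) ? d1 : (d1 + d2) / 2.0;
}

static inline void sorted_insert(std::vector<double>& s, double v) {
  s.insert(std::upper_bound(s.begin(), s.end(), v), v);
}

static inline void sorted_erase(std::vector<double>& s, double v) {
  s.erase(std::lower_bound(s.begin(), s.end(), v));
}

// Windowed median/MAD outlier flags. The window for element i covers
// [i - before, i + after], truncated at the sequence edges (the centred
// convention of Matlab's isoutlier with a movmedian window: an even window
// of length k uses k/2 elements before and k/2 - 1 after). A sample is
// flagged when |x[i] - median| > k_thresh * scale * MAD; the strict
// inequality means constant stretches (MAD = 0, deviation 0) are never
// flagged while an isolated spike inside one is.
// [[Rcpp::export]]
LogicalVector mad_outlier_flags_cpp(NumericVector x, int before, int after,
                                    double k_thresh, double scale) {
  const int n = x.size();
  LogicalVector out(n);
  std::vector<double> win;
  win.reserve(before + after + 2);
  int lo = 0, hi = -1;  // current window bounds (inclusive)
  for (int i = 0; i < n; ++i) {
    const int new_lo = std::max(0, i - before);
    const int new_hi = std::min(n - 1, i + after);
    while (hi < new_hi) sorted_insert(win, x[++hi]);
    while (lo < new_lo) sorted_erase(win, x[lo++]);
    const double med = sorted_median(win);
    const double mad = sorted_mad(win, med);
    out[i] = std::abs(x[i] - med) > k_thresh * scale * mad;
  }
  return out;
}
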