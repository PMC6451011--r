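#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Centered rolling median with shrinking windows at the edges.
//
// For window width w the full window at position i (0-based) covers
// [i - w/2, i + w - 1 - w/2]; for even w the window is one element
// heavier on the left.  At the series edges the window is clamped to
// the available range.  An even number of in-window values yields the
// mean of the two middle order statistics (interpolated median).
// [[Rcpp::export(name = ".rolling_median_cpp")]]
NumericVector rolling_median_cpp(NumericVector x, int w) {
  const int n = x.size();
  if (w < 1) stop("window must be >= 1");
  if (w > n) stop("window longer than series");
  const int left = w / 2;
  const int right = w - 1 - left;
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(w);
  for (int i = 0; i < n; ++i) {
    int lo = i - left;
    int hi = i + right;
    if (lo < 0) lo = 0;
    if (hi > n - 1) hi = n - 1;
    const int m = hi - lo + 1;
    buf.assign(x.begin() + lo, x.begin() + hi + 1);
    const int mid = m / 2;
    std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
    double med = buf[mid];
    if (m % 2 == 0) {
      double lo_med = *std::max_element(buf.begin(), buf.begin() + mid);
      med = (med + lo_med) / 2.0;
    }
    out[i] = med;
  }
  return out;
}
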