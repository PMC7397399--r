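#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Centered rolling extremum with edge-value padding (monotonic deque, O(n)).
// The signal is conceptually extended by half a window on each side with its
// first/last value before the window is slid, so a monotone input maps to
// itself under erosion+dilation (opening) including at the boundaries.
static NumericVector roll_extreme(const NumericVector& x, int window,
                                  bool is_min) {
  int n = x.size();
  if (n < 1) stop("empty signal");
  if (window < 1) stop("window must be >= 1");
  if (window % 2 == 0) stop("window must be odd");
  int h = window / 2;
  int m = n + 2 * h;
  std::vector<double> p(m);
  for (int i = 0; i < m; ++i) {
    int j = i - h;
    if (j < 0) j = 0;
    if (j > n - 1) j = n - 1;
    p[i] = x[j];
  }
  NumericVector out(n);
  std::deque<int> dq;
  for (int i = 0; i < m; ++i) {
    while (!dq.empty() &&
           (is_min ? p[dq.back()] >= p[i] : p[dq.back()] <= p[i]))
      dq.pop_back();
    dq.push_back(i);
    int lo = i - window + 1;
    while (dq.front() < lo) dq.pop_front();
    if (i >= window - 1) out[i - window + 1] = p[dq.front()];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector roll_min_pad(NumericVector x, int window) {
  return roll_extreme(x, window, true);
}

// [[Rcpp::export]]
NumericVector roll_max_pad(NumericVector x, int window) {
  return roll_extreme(x, window, false);
}
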