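#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Topographic prominence of candidate local maxima.
// For each peak, walk left and right until a strictly higher sample (or the
// signal edge) is met, tracking the minimum on each side; prominence is the
// peak height minus the higher of the two side minima.
// [[Rcpp::export]]
NumericVector peak_prominence_cpp(NumericVector x, IntegerVector idx) {
  int n = x.size(), m = idx.size();
  NumericVector prom(m);
  for (int j = 0; j < m; ++j) {
    int p = idx[j] - 1; // 1-based from R
    double h = x[p];
    double lmin = h, rmin = h;
    for (int i = p - 1; i >= 0; --i) {
      if (x[i] > h) break;
      if (x[i] < lmin) lmin = x[i];
    }
    for (int i = p + 1; i < n; ++i) {
      if (x[i] > h) break;
      if (x[i] < rmin) rmin = x[i];
    }
    prom[j] = h - std::max(lmin, rmin);
  }
  return prom;
}

// Centered moving maximum over [i-h, i+h] (shrunken at the edges),
// monotonic-deque algorithm, O(n).
// [[Rcpp::export]]
NumericVector moving_max_cpp(NumericVector x, int h) {
  int n = x.size();
  NumericVector out(n);
  std::deque<int> dq;
  int r = -1; // last index pushed
  for (int i = 0; i < n; ++i) {
    int hi = std::min(n - 1, i + h);
    while (r < hi) {
      ++r;
      while (!dq.empty() && x[dq.back()] <= x[r]) dq.pop_back();
      dq.push_back(r);
    }
    while (!dq.empty() && dq.front() < i - h) dq.pop_front();
    out[i] = x[dq.front()];
  }
  return out;
}
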