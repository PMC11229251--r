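#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Running median over a masked signal. Invalid samples are excluded from
// every window and are passed through unchanged; windows truncate at the
// signal edges. Even-sized windows average the two middle order statistics.
// [[Rcpp::export]]
NumericVector median_filter_masked(NumericVector x, LogicalVector valid,
                                   int left, int right) {
  int n = x.size();
  NumericVector out(n);
  std::vector<double> buf;
  buf.reserve(left + right + 1);
  for (int i = 0; i < n; ++i) {
    out[i] = x[i];
    if (!valid[i]) continue;
    buf.clear();
    int a = i - left < 0 ? 0 : i - left;
    int b = i + right > n - 1 ? n - 1 : i + right;
    for (int j = a; j <= b; ++j)
      if (valid[j]) buf.push_back(x[j]);
    if (buf.empty()) continue;
    std::size_t m = buf.size();
    std::nth_element(buf.begin(), buf.begin() + m / 2, buf.end());
    double hi = buf[m / 2];
    if (m % 2 == 1) {
      out[i] = hi;
    } else {
      double lo = *std::max_element(buf.begin(), buf.begin() + m / 2);
      out[i] = (lo + hi) / 2.0;
    }
  }
  return out;
}
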