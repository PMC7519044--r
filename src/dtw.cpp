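#include <Rcpp.h>
using namespace Rcpp;

// Classic dynamic time warping accumulated cost.
//
// Local cost |a_i - b_j| (or squared difference), unit step pattern
// {(1,0),(0,1),(1,1)}, boundary-aligned at both ends, no warping window.
// Two-row dynamic program, O(n*m) time, O(m) memory.
//
// [[Rcpp::export(name = ".dtw_cost_cpp")]]
double dtw_cost_cpp(NumericVector a, NumericVector b, bool squared = false) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    stop("dtw: both sequences must be non-empty");
  std::vector<double> prev(m), cur(m);
  for (int j = 0; j < m; ++j) {
    double d = a[0] - b[j];
    double c = squared ? d * d : std::fabs(d);
    prev[j] = c + (j > 0 ? prev[j - 1] : 0.0);
  }
  for (int i = 1; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = a[i] - b[j];
      double c = squared ? d * d : std::fabs(d);
      double best;
      if (j == 0) {
        best = prev[0];
      } else {
        best = std::min(std::min(prev[j], prev[j - 1]), cur[j - 1]);
      }
      cur[j] = c + best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}
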