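#include <Rcpp.h>
using namespace Rcpp;

// Fisher-Jenks optimal 1-D classification: dynamic program minimizing the
// total within-class sum of squared deviations over contiguous classes of the
// sorted input. Ties between optimal partitions are broken toward smaller
// early-class sizes (the earliest feasible split is kept).
//
// x must be sorted ascending. Returns 1-based start index of each class.
// [[Rcpp::export(name = ".jenks_dp")]]
IntegerVector jenks_dp(NumericVector x, int k) {
  const int n = x.size();
  if (k < 1 || k > n) stop("k must be between 1 and n");

  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  // ssd of x[i..j] inclusive, 0-based
  auto ssd = [&](int i, int j) {
    double s = cs[j + 1] - cs[i], s2 = cs2[j + 1] - cs2[i];
    int m = j - i + 1;
    double v = s2 - s * s / m;
    return v > 0 ? v : 0.0;
  };

  // cost[m][j]: best total ssd of splitting x[0..j] into m+1 classes
  std::vector<std::vector<double> > cost(k, std::vector<double>(n));
  std::vector<std::vector<int> > from(k, std::vector<int>(n, 0));
  for (int j = 0; j < n; ++j) cost[0][j] = ssd(0, j);
  for (int m = 1; m < k; ++m) {
    for (int j = m; j < n; ++j) {
      double best = R_PosInf;
      int arg = m;
      // last class starts at i (0-based); earlier classes fill x[0..i-1].
      // Scanning i ascending and keeping strict improvements leaves the
      // smallest feasible i on ties => larger last class, smaller early ones.
      for (int i = m; i <= j; ++i) {
        double c = cost[m - 1][i - 1] + ssd(i, j);
        if (c < best) { best = c; arg = i; }
      }
      cost[m][j] = best;
      from[m][j] = arg;
    }
  }

  IntegerVector starts(k);
  int j = n - 1;
  for (int m = k - 1; m >= 1; --m) {
    starts[m] = from[m][j] + 1;   // 1-based
    j = from[m][j] - 1;
  }
  starts[0] = 1;
  starts.attr("ssd") = cost[k - 1][n - 1];
  return starts;
}
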