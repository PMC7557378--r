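#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Minimum-cost rectangular linear assignment by successive shortest
// augmenting paths with dual-variable (reduced cost) updates.
// Requires nrow <= ncol; every row is matched to a distinct column.
// Complexity O(nr^2 * nc), exact for finite costs.

// [[Rcpp::export(name = ".lsap_cpp")]]
IntegerVector lsap_cpp(NumericMatrix cost) {
  const int nr = cost.nrow(), nc = cost.ncol();
  if (nr > nc) stop("cost matrix must have nrow <= ncol");
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (NumericVector::is_na(cost(i, j)))
        stop("cost matrix contains NA");

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(nr, 0.0), v(nc, 0.0), shortest(nc);
  std::vector<int> col4row(nr, -1), row4col(nc, -1), pred(nc);
  std::vector<char> SR(nr), SC(nc);

  for (int curRow = 0; curRow < nr; ++curRow) {
    std::fill(shortest.begin(), shortest.end(), INF);
    std::fill(SR.begin(), SR.end(), 0);
    std::fill(SC.begin(), SC.end(), 0);
    std::fill(pred.begin(), pred.end(), -1);

    double minVal = 0.0;
    int i = curRow, sink = -1;
    while (sink == -1) {
      SR[i] = 1;
      int jMin = -1;
      double lowest = INF;
      for (int j = 0; j < nc; ++j) {
        if (SC[j]) continue;
        double r = minVal + cost(i, j) - u[i] - v[j];
        if (r < shortest[j]) { shortest[j] = r; pred[j] = i; }
        if (shortest[j] < lowest) { lowest = shortest[j]; jMin = j; }
      }
      if (jMin == -1 || !R_finite(lowest)) stop("assignment problem infeasible");
      minVal = lowest;
      SC[jMin] = 1;
      if (row4col[jMin] == -1) sink = jMin; else i = row4col[jMin];
    }

    u[curRow] += minVal;
    for (int k = 0; k < nr; ++k)
      if (SR[k] && k != curRow) u[k] += minVal - shortest[col4row[k]];
    for (int j = 0; j < nc; ++j)
      if (SC[j]) v[j] -= minVal - shortest[j];

    int j = sink;
    while (true) {
      int ii = pred[j];
      row4col[j] = ii;
      int tmp = col4row[ii];
      col4row[ii] = j;
      if (ii == curRow) break;
      j = tmp;
    }
  }

  IntegerVector out(nr);
  for (int k = 0; k < nr; ++k) out[k] = col4row[k] + 1;  // 1-based columns
  return out;
}
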