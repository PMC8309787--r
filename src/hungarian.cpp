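#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Linear sum assignment by shortest augmenting paths with potentials
// (O(n^3)). Expects a rectangular cost matrix with m <= n; forbidden
// pairs must already be replaced by a large-but-finite penalty so that
// the solver maximizes the number of affordable pairs first.
static std::vector<int> lsap_rows_leq_cols(const NumericMatrix& cost) {
  const int m = cost.nrow(), n = cost.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> u(m + 1, 0.0), v(n + 1, 0.0);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= m; ++i) {
    p[0] = i;
    int j0 = 0;
    std::vector<double> minv(n + 1, INF);
    std::vector<bool> used(n + 1, false);
    do {
      used[j0] = true;
      int i0 = p[j0], j1 = -1;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost(i0 - 1, j - 1) - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  std::vector<int> row_to_col(m, -1);
  for (int j = 1; j <= n; ++j)
    if (p[j] != 0) row_to_col[p[j] - 1] = j - 1;
  return row_to_col;
}

// [[Rcpp::export(name = ".lsap_solve")]]
IntegerVector lsap_solve(NumericMatrix cost) {
  const int m = cost.nrow(), n = cost.ncol();
  if (m == 0 || n == 0) return IntegerVector(m, NA_INTEGER);
  std::vector<int> r2c;
  if (m <= n) {
    r2c = lsap_rows_leq_cols(cost);
  } else {
    NumericMatrix t(n, m);
    for (int i = 0; i < m; ++i)
      for (int j = 0; j < n; ++j) t(j, i) = cost(i, j);
    std::vector<int> c2r = lsap_rows_leq_cols(t);
    r2c.assign(m, -1);
    for (int j = 0; j < n; ++j)
      if (c2r[j] >= 0) r2c[c2r[j]] = j;
  }
  IntegerVector out(m);
  for (int i = 0; i < m; ++i)
    out[i] = (r2c[i] >= 0) ? r2c[i] + 1 : NA_INTEGER;  // 1-based for R
  return out;
}
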