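#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with the standard three-predecessor recursion:
//   D(i,j) = d(i,j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1)),  D(1,1) = d(1,1)
// Local cost d is |x_i - y_j| (or its square when squared_cost).
// The optimal warping path is recovered by backtracking from (n,m);
// ties prefer the diagonal predecessor, then the vertical one (i-1, j).
// [[Rcpp::export]]
List dtw_align_cpp(NumericVector x, NumericVector y, bool squared_cost) {
  const int n = x.size(), m = y.size();
  NumericMatrix D(n, m);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double d = std::fabs(x[i] - y[j]);
      if (squared_cost) d *= d;
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else if (i == 0) best = D(0, j - 1);
      else if (j == 0) best = D(i - 1, 0);
      else best = std::min(D(i - 1, j - 1), std::min(D(i - 1, j), D(i, j - 1)));
      D(i, j) = d + best;
    }
  }

  // backtrack; path length is at most n + m - 1
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      double diag = D(i - 1, j - 1), vert = D(i - 1, j), horiz = D(i, j - 1);
      if (diag <= vert && diag <= horiz) { --i; --j; }
      else if (vert <= horiz) { --i; }
      else { --j; }
    }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());

  return List::create(_["distance"] = D(n - 1, m - 1),
                      _["index_x"] = wrap(pi),
                      _["index_y"] = wrap(pj));
}

// Row-wise medians ignoring NA (NaN when a row is all-NA); the hot path of
// the bootstrap, which rebuilds group curves thousands of times.
// [[Rcpp::export]]
NumericVector row_medians_cpp(NumericMatrix x) {
  const int n = x.nrow();
  NumericVector out(n);
  std::vector<double> row;
  for (int i = 0; i < n; ++i) {
    row.clear();
    for (int j = 0; j < x.ncol(); ++j) {
      double v = x(i, j);
      if (!NumericVector::is_na(v)) row.push_back(v);
    }
    const int k = row.size();
    if (k == 0) { out[i] = R_NaN; continue; }
    std::sort(row.begin(), row.end());
    out[i] = (k % 2 == 1) ? row[k / 2] : 0.5 * (row[k / 2 - 1] + row[k / 2]);
  }
  return out;
}
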