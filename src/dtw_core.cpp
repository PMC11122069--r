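#include <Rcpp.h>
using namespace Rcpp;

// Cumulative-distance recursion and warp-path backtracking for DTW.
// r(i,j) = d(i,j) + min(r(i-1,j), r(i-1,j-1), r(i,j-1)), out-of-grid
// neighbours +Inf, r(1,1) = d(1,1); distance = r(n,m). Backtracking ties
// prefer diagonal, then vertical (i-1,j), then horizontal (i,j-1).

// [[Rcpp::export]]
List dtw_core(NumericMatrix d) {
  const int n = d.nrow(), m = d.ncol();
  if (n < 1 || m < 1) stop("dtw_core: empty distance matrix");
  NumericMatrix r(n, m);
  const double inf = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double up   = (i > 0) ? r(i - 1, j) : inf;
      double diag = (i > 0 && j > 0) ? r(i - 1, j - 1) : inf;
      double left = (j > 0) ? r(i, j - 1) : inf;
      double best = diag;
      if (up < best) best = up;
      if (left < best) best = left;
      if (i == 0 && j == 0) best = 0.0;
      r(i, j) = d(i, j) + best;
    }
  }
  // backtrack from (n-1, m-1) to (0, 0)
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    double up   = (i > 0) ? r(i - 1, j) : inf;
    double diag = (i > 0 && j > 0) ? r(i - 1, j - 1) : inf;
    double left = (j > 0) ? r(i, j - 1) : inf;
    if (diag <= up && diag <= left) { --i; --j; }
    else if (up <= left)            { --i; }
    else                            { --j; }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["cumulative"] = r,
                      _["distance"]   = r(n - 1, m - 1),
                      _["path_i"]     = IntegerVector(pi.begin(), pi.end()),
                      _["path_j"]     = IntegerVector(pj.begin(), pj.end()));
}
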