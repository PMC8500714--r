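#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping alignment of two 2D paths with Euclidean local
// cost and the symmetric step pattern (insert / delete / match), no
// window constraint.  Returns the optimal coupling as 1-based index
// pairs, ordered from the start of both paths.
// [[Rcpp::export]]
List dtw_path_cpp(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  NumericMatrix D(n, m);
  IntegerMatrix from(n, m); // 0 diag, 1 up (i-1), 2 left (j-1)
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1);
      double c = std::sqrt(dx * dx + dy * dy);
      if (i == 0 && j == 0) { D(i, j) = c; from(i, j) = -1; }
      else if (i == 0) { D(i, j) = D(i, j - 1) + c; from(i, j) = 2; }
      else if (j == 0) { D(i, j) = D(i - 1, j) + c; from(i, j) = 1; }
      else {
        double d0 = D(i - 1, j - 1), d1 = D(i - 1, j), d2 = D(i, j - 1);
        if (d0 <= d1 && d0 <= d2) { D(i, j) = d0 + c; from(i, j) = 0; }
        else if (d1 <= d2)        { D(i, j) = d1 + c; from(i, j) = 1; }
        else                      { D(i, j) = d2 + c; from(i, j) = 2; }
      }
    }
  }
  std::vector<int> ii, jj;
  int i = n - 1, j = m - 1;
  while (i >= 0 && j >= 0) {
    ii.push_back(i + 1); jj.push_back(j + 1);
    int f = from(i, j);
    if (f == -1) break;
    if (f == 0) { --i; --j; } else if (f == 1) { --i; } else { --j; }
  }
  std::reverse(ii.begin(), ii.end());
  std::reverse(jj.begin(), jj.end());
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["distance"] = D(n - 1, m - 1));
}

// Discrete Frechet distance between two 2D paths (classic dynamic
// program over couplings).
// [[Rcpp::export]]
double frechet_dist_cpp(NumericMatrix A, NumericMatrix B) {
  int n = A.nrow(), m = B.nrow();
  NumericMatrix C(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      if (i == 0 && j == 0) C(i, j) = d;
      else if (i == 0) C(i, j) = std::max(C(i, j - 1), d);
      else if (j == 0) C(i, j) = std::max(C(i - 1, j), d);
      else {
        double prev = std::min(C(i - 1, j - 1), std::min(C(i - 1, j), C(i, j - 1)));
        C(i, j) = std::max(prev, d);
      }
    }
  }
  return C(n - 1, m - 1);
}
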