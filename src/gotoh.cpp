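#include <Rcpp.h>
using namespace Rcpp;

// Gotoh dynamic programming over a positive similarity matrix with affine
// gaps (opening penalty, zero extension) and free end gaps.  Returns the
// 1-based (i, j) index pairs of the best-scoring monotone correspondence.
// [[Rcpp::export]]
IntegerMatrix gotoh_align(NumericMatrix S, double gap_open) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix TM(n + 1, m + 1), TX(n + 1, m + 1), TY(n + 1, m + 1);

  for (int j = 0; j <= m; ++j) { M(0, j) = 0.0; X(0, j) = NEG; Y(0, j) = 0.0; }
  for (int i = 0; i <= n; ++i) { M(i, 0) = 0.0; X(i, 0) = 0.0; Y(i, 0) = NEG; }
  M(0, 0) = 0.0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: i aligned to j
      double best = M(i - 1, j - 1); int tb = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); tb = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); tb = 2; }
      M(i, j) = best + S(i - 1, j - 1); TM(i, j) = tb;
      // X: gap in the column sequence (skip row i)
      double xo = M(i - 1, j) - gap_open, xe = X(i - 1, j);
      if (xo >= xe) { X(i, j) = xo; TX(i, j) = 0; }
      else          { X(i, j) = xe; TX(i, j) = 1; }
      // Y: gap in the row sequence (skip column j)
      double yo = M(i, j - 1) - gap_open, ye = Y(i, j - 1);
      if (yo >= ye) { Y(i, j) = yo; TY(i, j) = 0; }
      else          { Y(i, j) = ye; TY(i, j) = 2; }
    }
  }

  // free end gaps: best cell on the last row or column, any state
  double best = NEG; int bi = n, bj = m, bs = 0;
  for (int i = 0; i <= n; ++i)
    for (int s = 0; s < 3; ++s) {
      double v = (s == 0) ? M(i, m) : (s == 1 ? X(i, m) : Y(i, m));
      if (v > best) { best = v; bi = i; bj = m; bs = s; }
    }
  for (int j = 0; j <= m; ++j)
    for (int s = 0; s < 3; ++s) {
      double v = (s == 0) ? M(n, j) : (s == 1 ? X(n, j) : Y(n, j));
      if (v > best) { best = v; bi = n; bj = j; bs = s; }
    }

  std::vector<int> qi, rj;
  int i = bi, j = bj, s = bs;
  while (i > 0 && j > 0) {
    if (s == 0) {
      int prev = TM(i, j);
      qi.push_back(i); rj.push_back(j);
      --i; --j; s = prev;
    } else if (s == 1) {
      int prev = TX(i, j); --i; s = prev;
    } else {
      int prev = TY(i, j); --j; s = prev;
    }
  }
  const int np = qi.size();
  IntegerMatrix out(np, 2);
  for (int k = 0; k < np; ++k) {
    out(k, 0) = qi[np - 1 - k];
    out(k, 1) = rj[np - 1 - k];
  }
  return out;
}
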