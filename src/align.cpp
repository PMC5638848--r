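#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment over a precomputed column-score matrix.
// S[i,j] is the score of aligning unit i of `a` against unit j of `b`
// (residues for pairwise alignment, profile columns for profile-profile
// alignment). Affine gap cost: a gap of length L costs open + ext*(L-1).
// Terminal gaps are penalised (true global alignment). Traceback prefers
// diagonal, then gap-in-b (up), then gap-in-a (left), which makes the
// alignment deterministic.
//
// Returns a list with integer vectors ai, bi (1-based indices into a and
// b per alignment column; 0 marks a gap) and the optimal score.
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // DP matrices: M match/mismatch, X gap in b (consume a), Y gap in a.
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // 0 = diag, 1 = up(X), 2 = left(Y); per matrix a traceback code.
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -gap_open - gap_ext * (i - 1);
    tbX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -gap_open - gap_ext * (j - 1);
    tbY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: come from any matrix diagonally.
      double s = S(i - 1, j - 1);
      double bm = M(i - 1, j - 1), bx = X(i - 1, j - 1), by = Y(i - 1, j - 1);
      int code = 0; double best = bm;
      if (bx > best) { best = bx; code = 1; }
      if (by > best) { best = by; code = 2; }
      M(i, j) = best + s; tbM(i, j) = code;
      // X: gap in b, consume a[i].
      double xo = M(i - 1, j) - gap_open, xe = X(i - 1, j) - gap_ext,
             xy = Y(i - 1, j) - gap_open;
      code = 0; best = xo;
      if (xe > best) { best = xe; code = 1; }
      if (xy > best) { best = xy; code = 2; }
      X(i, j) = best; tbX(i, j) = code;
      // Y: gap in a, consume b[j].
      double yo = M(i, j - 1) - gap_open, yx = X(i, j - 1) - gap_open,
             ye = Y(i, j - 1) - gap_ext;
      code = 0; best = yo;
      if (yx > best) { best = yx; code = 1; }
      if (ye > best) { best = ye; code = 2; }
      Y(i, j) = best; tbY(i, j) = code;
    }
  }

  // Choose end matrix: prefer M, then X, then Y on ties.
  int mat = 0; double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); mat = 1; }
  if (Y(n, m) > best) { best = Y(n, m); mat = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (mat == 0) {
      int prev = tbM(i, j);
      ai.push_back(i); bi.push_back(j); --i; --j; mat = prev;
    } else if (mat == 1) {
      int prev = tbX(i, j);
      ai.push_back(i); bi.push_back(0); --i; mat = prev;
    } else {
      int prev = tbY(i, j);
      ai.push_back(0); bi.push_back(j); --j; mat = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["ai"] = wrap(ai), _["bi"] = wrap(bi),
                      _["score"] = best);
}
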