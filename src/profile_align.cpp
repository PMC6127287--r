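#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment of two alignment profiles.
//
// A profile is a 5 x L numeric matrix of per-column base frequencies
// (rows A, C, G, T, gap; columns sum to 1). The column-column score is the
// expected pairwise score sum_{a,b in ACGT} fx_a * fy_b * s(a,b) with
// s(a,a) = match, s(a,b) = mismatch; gap frequency mass scores 0.
// Gap runs of length L cost gap_open + L * gap_extend (the Biostrings
// pairwiseAlignment convention), so single-sequence profiles reproduce
// ordinary Needleman-Wunsch with affine gaps exactly.
//
// Returns the optimal score and a traceback path over the merged columns:
// 1 = consume a column of both profiles, 2 = X column against gap,
// 3 = Y column against gap. Ties break deterministically (diagonal, then
// X-gap, then Y-gap), so the alignment is reproducible.

static inline double col_score(const NumericMatrix& px, const NumericMatrix& py,
                               int i, int j, double match, double mismatch) {
  double s = 0.0;
  for (int a = 0; a < 4; ++a) {
    double fa = px(a, i);
    if (fa == 0.0) continue;
    for (int b = 0; b < 4; ++b) {
      double fb = py(b, j);
      if (fb == 0.0) continue;
      s += fa * fb * (a == b ? match : mismatch);
    }
  }
  return s;
}

// [[Rcpp::export(name = ".cpp_align_profiles")]]
List cpp_align_profiles(NumericMatrix px, NumericMatrix py,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  const int n = px.ncol(), m = py.ncol();
  const double NEG = -1e30;
  const double g1 = gap_open + gap_extend;  // cost of opening (first gap col)

  // DP matrices: M (diagonal), IX (gap in Y, consume X), IY (gap in X)
  NumericMatrix M(n + 1, m + 1), IX(n + 1, m + 1), IY(n + 1, m + 1);
  // traceback state choices: which of {M,IX,IY} fed each cell
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0; IX(0, 0) = NEG; IY(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; IY(i, 0) = NEG;
    IX(i, 0) = gap_open + i * gap_extend;
    tbX(i, 0) = 2;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; IX(0, j) = NEG;
    IY(0, j) = gap_open + j * gap_extend;
    tbY(0, j) = 3;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sc = col_score(px, py, i - 1, j - 1, match, mismatch);
      // M: predecessor preference M > IX > IY on ties
      double best = M(i - 1, j - 1); int from = 1;
      if (IX(i - 1, j - 1) > best) { best = IX(i - 1, j - 1); from = 2; }
      if (IY(i - 1, j - 1) > best) { best = IY(i - 1, j - 1); from = 3; }
      M(i, j) = best + sc; tbM(i, j) = from;

      double oM = M(i - 1, j) + g1, oX = IX(i - 1, j) + gap_extend,
             oY = IY(i - 1, j) + g1;
      best = oM; from = 1;
      if (oX > best) { best = oX; from = 2; }
      if (oY > best) { best = oY; from = 3; }
      IX(i, j) = best; tbX(i, j) = from;

      oM = M(i, j - 1) + g1; oX = IX(i, j - 1) + g1;
      oY = IY(i, j - 1) + gap_extend;
      best = oM; from = 1;
      if (oX > best) { best = oX; from = 2; }
      if (oY > best) { best = oY; from = 3; }
      IY(i, j) = best; tbY(i, j) = from;
    }
  }

  double score = M(n, m); int state = 1;
  if (IX(n, m) > score) { score = IX(n, m); state = 2; }
  if (IY(n, m) > score) { score = IY(n, m); state = 3; }

  std::vector<int> path;
  path.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 1) {
      path.push_back(1);
      int from = tbM(i, j); --i; --j; state = from;
    } else if (state == 2) {
      path.push_back(2);
      int from = tbX(i, j); --i; state = from;
    } else {
      path.push_back(3);
      int from = tbY(i, j); --j; state = from;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
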