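#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment of two sequence profiles (Gotoh three-state DP).
//
// profA, profB: (n_symbols x n_cols) column frequency matrices. Gap mass is
// simply omitted, so a column's frequencies may sum to < 1; the column score
// is the frequency-weighted sum-of-pairs substitution score.
//
// Gap cost convention: a gap of length L costs gap_open + L * gap_ext (the
// first gapped position pays both terms). With semi_global = true, terminal
// gaps in either profile are free.
//
// Tie-break: on equal scores prefer the diagonal (match) state, then the
// gap-in-B state (consume A), then gap-in-A. Deterministic by construction.
//
// Returns list(score, ops) where ops is an integer vector read 5'->3':
// 0 = column from both profiles, 1 = column from A only (gap in B),
// 2 = column from B only (gap in A).

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List align_profiles_cpp(NumericMatrix profA, NumericMatrix profB,
                        NumericMatrix submat, double gap_open, double gap_ext,
                        bool semi_global) {
  const int la = profA.ncol(), lb = profB.ncol(), ns = submat.nrow();

  // column-pair scores: colsc(i,j) = profA[,i]' %*% submat %*% profB[,j]
  std::vector<double> SB((size_t)ns * lb, 0.0);
  for (int j = 0; j < lb; ++j)
    for (int a = 0; a < ns; ++a) {
      double s = 0.0;
      for (int b = 0; b < ns; ++b) s += submat(a, b) * profB(b, j);
      SB[(size_t)a + (size_t)j * ns] = s;
    }
  std::vector<double> colsc((size_t)la * lb, 0.0);
  for (int i = 0; i < la; ++i)
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int a = 0; a < ns; ++a) s += profA(a, i) * SB[(size_t)a + (size_t)j * ns];
      colsc[(size_t)i + (size_t)j * la] = s;
    }

  const int R = la + 1, C = lb + 1;
  std::vector<double> M((size_t)R * C, NEG_INF), X((size_t)R * C, NEG_INF),
      Y((size_t)R * C, NEG_INF);
  // predecessor state per cell per state: 0 = M, 1 = X, 2 = Y
  std::vector<signed char> pM((size_t)R * C, -1), pX((size_t)R * C, -1),
      pY((size_t)R * C, -1);
#define IDX(i, j) ((size_t)(i) + (size_t)(j) * R)

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i < R; ++i) {
    X[IDX(i, 0)] = semi_global ? 0.0 : -(gap_open + i * gap_ext);
    pX[IDX(i, 0)] = 1;
  }
  if (la > 0) pX[IDX(1, 0)] = 0;
  for (int j = 1; j < C; ++j) {
    Y[IDX(0, j)] = semi_global ? 0.0 : -(gap_open + j * gap_ext);
    pY[IDX(0, j)] = 2;
  }
  if (lb > 0) pY[IDX(0, 1)] = 0;

  for (int i = 1; i < R; ++i) {
    for (int j = 1; j < C; ++j) {
      // M: consume one column of each
      {
        double m = M[IDX(i - 1, j - 1)], x = X[IDX(i - 1, j - 1)],
               y = Y[IDX(i - 1, j - 1)];
        double best = m; signed char p = 0;
        if (x > best) { best = x; p = 1; }
        if (y > best) { best = y; p = 2; }
        M[IDX(i, j)] = best + colsc[(size_t)(i - 1) + (size_t)(j - 1) * la];
        pM[IDX(i, j)] = p;
      }
      // X: consume A column, gap in B
      {
        double m = M[IDX(i - 1, j)] - (gap_open + gap_ext);
        double x = X[IDX(i - 1, j)] - gap_ext;
        double y = Y[IDX(i - 1, j)] - (gap_open + gap_ext);
        double best = m; signed char p = 0;
        if (x > best) { best = x; p = 1; }
        if (y > best) { best = y; p = 2; }
        X[IDX(i, j)] = best;
        pX[IDX(i, j)] = p;
      }
      // Y: consume B column, gap in A
      {
        double m = M[IDX(i, j - 1)] - (gap_open + gap_ext);
        double x = X[IDX(i, j - 1)] - (gap_open + gap_ext);
        double y = Y[IDX(i, j - 1)] - gap_ext;
        double best = m; signed char p = 0;
        if (x > best) { best = x; p = 1; }
        if (y > best) { best = y; p = 2; }
        Y[IDX(i, j)] = best;
        pY[IDX(i, j)] = p;
      }
    }
  }

  // end point: bottom-right for global; best cell on last row/col for
  // semi-global (remaining terminal gaps appended free)
  int ei = la, ej = lb;
  if (semi_global) {
    double best = NEG_INF;
    for (int i = 0; i < R; ++i) {
      double v = std::max(M[IDX(i, lb)], std::max(X[IDX(i, lb)], Y[IDX(i, lb)]));
      if (v > best) { best = v; ei = i; ej = lb; }
    }
    for (int j = 0; j < C; ++j) {
      double v = std::max(M[IDX(la, j)], std::max(X[IDX(la, j)], Y[IDX(la, j)]));
      if (v > best) { best = v; ei = la; ej = j; }
    }
  }

  double sM = M[IDX(ei, ej)], sX = X[IDX(ei, ej)], sY = Y[IDX(ei, ej)];
  int state = 0; double score = sM;
  if (sX > score) { score = sX; state = 1; }
  if (sY > score) { score = sY; state = 2; }

  std::vector<int> ops;
  ops.reserve(la + lb);
  // free terminal gaps past the semi-global end point
  for (int i = la; i > ei; --i) ops.push_back(1);
  for (int j = lb; j > ej; --j) ops.push_back(2);

  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char p = pM[IDX(i, j)];
      ops.push_back(0); --i; --j; state = p;
    } else if (state == 1) {
      signed char p = pX[IDX(i, j)];
      ops.push_back(1); --i; state = p;
    } else {
      signed char p = pY[IDX(i, j)];
      ops.push_back(2); --j; state = p;
    }
  }
  std::reverse(ops.begin(), ops.end());
#undef IDX
  return List::create(_["score"] = score, _["ops"] = wrap(ops));
}
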