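#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Symbol codes: A=0 C=1 G=2 T=3 gap=4 N=5
static inline int sym_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  case '-': return 4;
  case 'N': case 'n': return 5;
  default: return -1;
  }
}

static inline double base_score(int a, int b, double match, double mismatch) {
  if (a == 5 || b == 5) return 0.0;           // N scores 0 against everything
  if (a == 4 && b == 4) return 0.0;           // gap-gap
  if (a == 4 || b == 4) return mismatch;      // base against existing gap
  return (a == b) ? match : mismatch;
}

// Affine-gap (Gotoh) global DP over a generic column-score callback.
// States: 0 = M (both), 1 = X (gap in b, consume a), 2 = Y (gap in a).
// Ties resolved deterministically: diagonal > up > left.
template <typename ScoreFun>
static std::vector<int> gotoh_path(int n, int m, ScoreFun colScore,
                                   double gapOpen, double gapExt) {
  const double NEG = -1e18;
  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  std::vector<signed char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);
  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -gapOpen - gapExt * i;
    tX[i * W] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -gapOpen - gapExt * j;
    tY[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    const size_t r = i * W, p = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      double s = colScore(i - 1, j - 1);
      double best = M[p + j - 1]; signed char tb = 0;
      if (X[p + j - 1] > best) { best = X[p + j - 1]; tb = 1; }
      if (Y[p + j - 1] > best) { best = Y[p + j - 1]; tb = 2; }
      M[r + j] = best + s; tM[r + j] = tb;
      best = M[p + j] - gapOpen - gapExt; tb = 0;
      if (X[p + j] - gapExt >= best) { best = X[p + j] - gapExt; tb = 1; }
      X[r + j] = best; tX[r + j] = tb;
      best = M[r + j - 1] - gapOpen - gapExt; tb = 0;
      if (Y[r + j - 1] - gapExt >= best) { best = Y[r + j - 1] - gapExt; tb = 2; }
      Y[r + j] = best; tY[r + j] = tb;
    }
  }
  int state = 0;
  double sc = M[n * W + m];
  if (X[n * W + m] > sc) { sc = X[n * W + m]; state = 1; }
  if (Y[n * W + m] > sc) { sc = Y[n * W + m]; state = 2; }
  std::vector<int> moves;
  moves.reserve(n + m + 2);
  moves.push_back(state);   // final state sentinel, consumed by callers
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) { moves.push_back(1); state = tM[i * W + j]; --i; --j; }
    else if (state == 1) { moves.push_back(2); state = tX[i * W + j]; --i; }
    else { moves.push_back(3); state = tY[i * W + j]; --j; }
  }
  return moves; // moves[0] = sentinel, rest reversed path
}

// Global pairwise alignment; returns gapped strings and the score.
// [[Rcpp::export(name = ".nwAlignPair")]]
List nwAlignPair(std::string a, std::string b,
                 double match = 1.0, double mismatch = -1.0,
                 double gapOpen = 2.0, double gapExt = 1.0) {
  int n = a.size(), m = b.size();
  std::vector<int> ca(n), cb(m);
  for (int i = 0; i < n; ++i) {
    ca[i] = sym_code(a[i]);
    if (ca[i] < 0) stop("invalid character in sequence");
  }
  for (int j = 0; j < m; ++j) {
    cb[j] = sym_code(b[j]);
    if (cb[j] < 0) stop("invalid character in sequence");
  }
  std::vector<int> moves = gotoh_path(
      n, m,
      [&](int i, int j) { return base_score(ca[i], cb[j], match, mismatch); },
      gapOpen, gapExt);
  std::string ra, rb;
  ra.reserve(moves.size()); rb.reserve(moves.size());
  int i = n, j = m;
  double score = 0.0;
  for (size_t k = 1; k < moves.size(); ++k) {
    if (moves[k] == 1) { ra.push_back(a[--i]); rb.push_back(b[--j]); }
    else if (moves[k] == 2) { ra.push_back(a[--i]); rb.push_back('-'); }
    else { ra.push_back('-'); rb.push_back(b[--j]); }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  // recompute the score from the emitted alignment (affine)
  int run = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    if (ra[k] == '-' || rb[k] == '-') {
      score -= gapExt;
      if (run == 0) score -= gapOpen;
      ++run;
    } else {
      run = 0;
      score += base_score(sym_code(ra[k]), sym_code(rb[k]), match, mismatch);
    }
  }
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = score);
}

// Profile-profile global alignment; profiles are 6 x L frequency matrices
// (rows A, C, G, T, gap, N). Returns the move vector: 1 = column from both,
// 2 = column from A only (gap in B), 3 = from B only.
// [[Rcpp::export(name = ".profileAlignPath")]]
IntegerVector profileAlignPath(NumericMatrix A, NumericMatrix B,
                               double match = 1.0, double mismatch = -1.0,
                               double gapOpen = 2.0, double gapExt = 1.0) {
  if (A.nrow() != 6 || B.nrow() != 6) stop("profiles must have 6 rows");
  int n = A.ncol(), m = B.ncol();
  // 6x6 symbol score table
  double S[6][6];
  for (int x = 0; x < 6; ++x)
    for (int y = 0; y < 6; ++y) S[x][y] = base_score(x, y, match, mismatch);
  std::vector<double> pa(6 * n), pb(6 * m);
  for (int i = 0; i < n; ++i)
    for (int x = 0; x < 6; ++x) pa[i * 6 + x] = A(x, i);
  for (int j = 0; j < m; ++j)
    for (int x = 0; x < 6; ++x) pb[j * 6 + x] = B(x, j);
  std::vector<int> moves = gotoh_path(
      n, m,
      [&](int i, int j) {
        double s = 0.0;
        const double* fi = &pa[i * 6];
        const double* fj = &pb[j * 6];
        for (int x = 0; x < 6; ++x) {
          if (fi[x] == 0.0) continue;
          for (int y = 0; y < 6; ++y) {
            if (fj[y] == 0.0) continue;
            s += fi[x] * fj[y] * S[x][y];
          }
        }
        return s;
      },
      gapOpen, gapExt);
  std::vector<int> out(moves.size() - 1);
  for (size_t k = 1; k < moves.size(); ++k)
    out[moves.size() - 1 - k] = moves[k];
  return wrap(out);
}
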