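#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment of two profiles given the
// precomputed column-pair substitution score matrix S (nA x nB columns).
// Affine gaps: a run of k gap columns costs open + (k-1) * extend
// (open and extend are negative scores). Terminal gaps are penalized.
//
// Deterministic traceback tie-break, constant everywhere:
//   diagonal (match state) > up (gap in B) > left (gap in A),
// applied both when choosing the final state and when choosing each
// state's predecessor.
//
// Returns list(score, path): path is an integer vector over alignment
// columns with 0 = aligned pair, 1 = consume A only (gap in B),
// 2 = consume B only (gap in A), in left-to-right order.

// [[Rcpp::export]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int nA = S.nrow(), nB = S.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  const int W = nB + 1;
  std::vector<double> M((nA + 1) * W, NEG), X((nA + 1) * W, NEG),
      Y((nA + 1) * W, NEG);
  // traceback: predecessor state per cell (0=M,1=X,2=Y), 255 = none
  std::vector<unsigned char> tM((nA + 1) * W, 255), tX((nA + 1) * W, 255),
      tY((nA + 1) * W, 255);

  M[0] = 0.0;
  for (int i = 1; i <= nA; ++i) {
    X[i * W] = gap_open + (i - 1) * gap_extend;
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= nB; ++j) {
    Y[j] = gap_open + (j - 1) * gap_extend;
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= nA; ++i) {
    for (int j = 1; j <= nB; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      // M: diagonal move; predecessor preference M > X > Y
      double best = M[d];
      unsigned char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      M[c] = best + S(i - 1, j - 1);
      tM[c] = arg;
      // X: gap in B (move up); opening from M or Y, extending from X
      best = M[u] + gap_open; arg = 0;
      if (X[u] + gap_extend > best) { best = X[u] + gap_extend; arg = 1; }
      if (Y[u] + gap_open > best) { best = Y[u] + gap_open; arg = 2; }
      X[c] = best; tX[c] = arg;
      // Y: gap in A (move left)
      best = M[l] + gap_open; arg = 0;
      if (X[l] + gap_open > best) { best = X[l] + gap_open; arg = 1; }
      if (Y[l] + gap_extend > best) { best = Y[l] + gap_extend; arg = 2; }
      Y[c] = best; tY[c] = arg;
    }
  }

  const int end = nA * W + nB;
  double score = M[end];
  unsigned char state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::vector<int> path;
  path.reserve(nA + nB);
  int i = nA, j = nB;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      path.push_back(0);
      state = tM[c];
      --i; --j;
    } else if (state == 1) {
      path.push_back(1);
      state = tX[c];
      --i;
    } else {
      path.push_back(2);
      state = tY[c];
      --j;
    }
  }
  std::reverse(path.begin(), path.end());
  return List::create(_["score"] = score,
                      _["path"] = IntegerVector(path.begin(), path.end()));
}
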