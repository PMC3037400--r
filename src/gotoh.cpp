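#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh three-state recursion) over a
// precomputed column-score matrix S (n1 x n2).  A gap run of length k costs
// gap_open + (k - 1) * gap_extend; terminal gaps are penalized like internal
// ones.  Tie-breaking is fixed: diagonal (match) > up (gap in the second
// input) > left (gap in the first input), applied both when recording
// predecessors and when choosing the final state, so the traceback is
// bit-reproducible.
//
// Returns the optimal score and the alignment path as two integer vectors of
// equal length: 1-based source positions per alignment column, 0 for a gap.
// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -std::numeric_limits<double>::infinity();
  // state codes: 0 = M (diagonal), 1 = X (consume row seq, gap in cols),
  // 2 = Y (consume col seq, gap in rows)
  std::vector<double> M((n1 + 1) * (n2 + 1), NEG);
  std::vector<double> X((n1 + 1) * (n2 + 1), NEG);
  std::vector<double> Y((n1 + 1) * (n2 + 1), NEG);
  std::vector<unsigned char> pM((n1 + 1) * (n2 + 1), 0);
  std::vector<unsigned char> pX((n1 + 1) * (n2 + 1), 0);
  std::vector<unsigned char> pY((n1 + 1) * (n2 + 1), 0);
  const int W = n2 + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n1; ++i) {
    X[IDX(i, 0)] = gap_open + (i - 1) * gap_extend;
    pX[IDX(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n2; ++j) {
    Y[IDX(0, j)] = gap_open + (j - 1) * gap_extend;
    pY[IDX(0, j)] = (j == 1) ? 0 : 2;
  }

  // preference order M > X > Y on strict comparison (">" keeps first best)
  auto best3 = [](double m, double x, double y, unsigned char &who) {
    double b = m; who = 0;
    if (x > b) { b = x; who = 1; }
    if (y > b) { b = y; who = 2; }
    return b;
  };

  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      unsigned char who;
      double b = best3(M[IDX(i - 1, j - 1)], X[IDX(i - 1, j - 1)],
                       Y[IDX(i - 1, j - 1)], who);
      M[IDX(i, j)] = b + S(i - 1, j - 1);
      pM[IDX(i, j)] = who;

      b = best3(M[IDX(i - 1, j)] + gap_open,
                X[IDX(i - 1, j)] + gap_extend,
                Y[IDX(i - 1, j)] + gap_open, who);
      X[IDX(i, j)] = b;
      pX[IDX(i, j)] = who;

      b = best3(M[IDX(i, j - 1)] + gap_open,
                X[IDX(i, j - 1)] + gap_open,
                Y[IDX(i, j - 1)] + gap_extend, who);
      Y[IDX(i, j)] = b;
      pY[IDX(i, j)] = who;
    }
  }

  unsigned char state;
  double score = best3(M[IDX(n1, n2)], X[IDX(n1, n2)], Y[IDX(n1, n2)], state);

  std::vector<int> ai, bi;
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      unsigned char prev = pM[IDX(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      unsigned char prev = pX[IDX(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i;
      state = prev;
    } else {
      unsigned char prev = pY[IDX(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
#undef IDX
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bi.begin(), bi.end()));
}
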