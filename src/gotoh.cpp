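#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment with affine gaps over a
// precomputed column-score matrix S (rows: columns of profile A, cols:
// columns of profile B). The first residue of a gap costs open + extend.
// Returns the optimal score and one optimal path; ties are broken
// deterministically (match > gap-in-B > gap-in-A).
// [[Rcpp::export]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  // state 0 = M (match), 1 = X (consume A, gap in B), 2 = Y (gap in A)
  std::vector<double> M((n + 1) * (m + 1), NEG), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = gap_open + i * gap_extend;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = gap_open + j * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double d = std::max(M[at(i - 1, j - 1)],
                          std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      M[at(i, j)] = S(i - 1, j - 1) + d;
      X[at(i, j)] = std::max(
          std::max(M[at(i - 1, j)], Y[at(i - 1, j)]) + gap_open + gap_extend,
          X[at(i - 1, j)] + gap_extend);
      Y[at(i, j)] = std::max(
          std::max(M[at(i, j - 1)], X[at(i, j - 1)]) + gap_open + gap_extend,
          Y[at(i, j - 1)] + gap_extend);
    }
  }
  double sM = M[at(n, m)], sX = X[at(n, m)], sY = Y[at(n, m)];
  double score = std::max(sM, std::max(sX, sY));
  int state = (score == sM) ? 0 : (score == sX ? 1 : 2);

  std::vector<int> pi, pj;
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      pi.push_back(i);
      pj.push_back(j);
      double tgt = M[at(i, j)] - S(i - 1, j - 1);
      if (std::abs(M[at(i - 1, j - 1)] - tgt) < eps) state = 0;
      else if (std::abs(X[at(i - 1, j - 1)] - tgt) < eps) state = 1;
      else state = 2;
      --i; --j;
    } else if (state == 1) {
      pi.push_back(i);
      pj.push_back(0);
      double tgt = X[at(i, j)];
      if (std::abs(M[at(i - 1, j)] + gap_open + gap_extend - tgt) < eps)
        state = 0;
      else if (std::abs(X[at(i - 1, j)] + gap_extend - tgt) < eps) state = 1;
      else state = 2;
      --i;
    } else {
      pi.push_back(0);
      pj.push_back(j);
      double tgt = Y[at(i, j)];
      if (std::abs(M[at(i, j - 1)] + gap_open + gap_extend - tgt) < eps)
        state = 0;
      else if (std::abs(Y[at(i, j - 1)] + gap_extend - tgt) < eps) state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["score"] = score,
                      _["path_i"] = IntegerVector(pi.begin(), pi.end()),
                      _["path_j"] = IntegerVector(pj.begin(), pj.end()));
}
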