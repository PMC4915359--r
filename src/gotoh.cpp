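#include <Rcpp.h>
using namespace Rcpp;

// Three-state (M/X/Y) Gotoh affine-gap alignment against a generic pairing
// score matrix S (n x m): S(i-1, j-1) scores pairing row item i with column
// item j.  Rows are the first ("a") sequence or the profile match columns;
// columns are the second ("b") sequence.  A gap run of length L costs
// gap_open + L * gap_extend (the first gapped position pays both).
//
// State X consumes a row item against a gap (gap in b); state Y consumes a
// column item against a gap (gap in a).  Ties are broken deterministically:
// M is preferred over X over Y, both when choosing a predecessor and when
// choosing the final state, so traceback prefers diagonal, then gap-in-b,
// then gap-in-a.  In local mode the alignment may start and end anywhere
// (fresh starts are taken only when strictly better than continuing) and the
// empty alignment with score 0 is allowed.
//
// Returns: score; pairs (L x 2 integer matrix, 1-based indices, 0 = gap);
// in local mode the pairs cover only the aligned region.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix S, double gap_open, double gap_extend,
                     bool local) {
  const int n = S.nrow(), m = S.ncol();
  if (n < 1 || m < 1) stop("both sequences must be nonempty");
  const double go = gap_open + gap_extend;  // cost of the first gap position

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // predecessor state: 0 = M, 1 = X, 2 = Y, 3 = local fresh start
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((n + 1) * (m + 1), -1);
  std::vector<signed char> tbY((n + 1) * (m + 1), -1);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  if (!local) {
    M[at(0, 0)] = 0.0;
    for (int i = 1; i <= n; ++i) {
      X[at(i, 0)] = -(gap_open + i * gap_extend);
      tbX[at(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= m; ++j) {
      Y[at(0, j)] = -(gap_open + j * gap_extend);
      tbY[at(0, j)] = (j == 1) ? 0 : 2;
    }
  }

  double best_local = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: consume row i and column j
      double b = M[at(i - 1, j - 1)];
      signed char s = 0;
      if (X[at(i - 1, j - 1)] > b) { b = X[at(i - 1, j - 1)]; s = 1; }
      if (Y[at(i - 1, j - 1)] > b) { b = Y[at(i - 1, j - 1)]; s = 2; }
      if (local && 0.0 > b) { b = 0.0; s = 3; }
      M[at(i, j)] = S(i - 1, j - 1) + b;
      tbM[at(i, j)] = s;

      // X: consume row i against a gap
      b = M[at(i - 1, j)] - go; s = 0;
      if (X[at(i - 1, j)] - gap_extend > b) { b = X[at(i - 1, j)] - gap_extend; s = 1; }
      if (Y[at(i - 1, j)] - go > b) { b = Y[at(i - 1, j)] - go; s = 2; }
      X[at(i, j)] = b;
      tbX[at(i, j)] = s;

      // Y: consume column j against a gap
      b = M[at(i, j - 1)] - go; s = 0;
      if (X[at(i, j - 1)] - go > b) { b = X[at(i, j - 1)] - go; s = 1; }
      if (Y[at(i, j - 1)] - gap_extend > b) { b = Y[at(i, j - 1)] - gap_extend; s = 2; }
      Y[at(i, j)] = b;
      tbY[at(i, j)] = s;

      if (local && M[at(i, j)] > best_local) {
        best_local = M[at(i, j)];
        best_i = i; best_j = j;
      }
    }
  }

  double score;
  int ci, cj, cs;
  if (local) {
    score = best_local;
    if (best_i == 0) {  // empty alignment
      return List::create(_["score"] = 0.0,
                          _["pairs"] = IntegerMatrix(0, 2));
    }
    ci = best_i; cj = best_j; cs = 0;
  } else {
    score = M[at(n, m)]; cs = 0;
    if (X[at(n, m)] > score) { score = X[at(n, m)]; cs = 1; }
    if (Y[at(n, m)] > score) { score = Y[at(n, m)]; cs = 2; }
    ci = n; cj = m;
  }

  std::vector<int> pa, pb;
  while (true) {
    if (!local && ci == 0 && cj == 0) break;
    signed char prev;
    if (cs == 0) {
      prev = tbM[at(ci, cj)];
      pa.push_back(ci); pb.push_back(cj);
      --ci; --cj;
      if (local && prev == 3) break;
    } else if (cs == 1) {
      prev = tbX[at(ci, cj)];
      pa.push_back(ci); pb.push_back(0);
      --ci;
    } else {
      prev = tbY[at(ci, cj)];
      pa.push_back(0); pb.push_back(cj);
      --cj;
    }
    cs = prev;
  }

  const int L = (int)pa.size();
  IntegerMatrix pairs(L, 2);
  for (int k = 0; k < L; ++k) {
    pairs(k, 0) = pa[L - 1 - k];
    pairs(k, 1) = pb[L - 1 - k];
  }
  return List::create(_["score"] = score, _["pairs"] = pairs);
}
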