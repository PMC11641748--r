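#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh three-state DP).
// Gap of length L costs gap_open + gap_ext * (L - 1), i.e. gap_open
// already includes the first gapped base.
//
// States: M = read[i-1] aligned to ref[j-1]; X = gap in ref (insertion in
// the read); Y = gap in read (deletion from the ref). All transitions
// between states are allowed so the optimum over the full alignment space
// is found; scores are integer-valued doubles, so equality comparisons in
// the traceback are exact.

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string read, std::string ref,
                  double match, double mismatch,
                  double gap_open, double gap_ext) {
  const int n = (int) read.size();
  const int m = (int) ref.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  const double NEG = -1e18;
  const int W = m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG);
  std::vector<double> X((size_t)(n + 1) * W, NEG);
  std::vector<double> Y((size_t)(n + 1) * W, NEG);
  auto idx = [W](int i, int j) { return (size_t) i * W + j; };

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[idx(i, 0)] = -(gap_open + gap_ext * (i - 1));
  for (int j = 1; j <= m; ++j) Y[idx(0, j)] = -(gap_open + gap_ext * (j - 1));

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      double diag = std::max(M[idx(i - 1, j - 1)],
                    std::max(X[idx(i - 1, j - 1)], Y[idx(i - 1, j - 1)]));
      M[idx(i, j)] = diag + s;
      X[idx(i, j)] = std::max(M[idx(i - 1, j)] - gap_open,
                     std::max(X[idx(i - 1, j)] - gap_ext,
                              Y[idx(i - 1, j)] - gap_open));
      Y[idx(i, j)] = std::max(M[idx(i, j - 1)] - gap_open,
                     std::max(X[idx(i, j - 1)] - gap_open,
                              Y[idx(i, j - 1)] - gap_ext));
    }
  }

  double score = std::max(M[idx(n, m)], std::max(X[idx(n, m)], Y[idx(n, m)]));

  // Traceback. Preference order on ties: M, then Y (deletion), then X;
  // placement ambiguity is resolved later by event-level left-normalization.
  std::string ar, af;
  ar.reserve(n + m);
  af.reserve(n + m);
  int i = n, j = m;
  char state;
  if (score == M[idx(n, m)]) state = 'M';
  else if (score == Y[idx(n, m)]) state = 'Y';
  else state = 'X';

  while (i > 0 || j > 0) {
    if (state == 'M') {
      ar.push_back(read[i - 1]);
      af.push_back(ref[j - 1]);
      double target = M[idx(i, j)] -
        ((read[i - 1] == ref[j - 1]) ? match : mismatch);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (target == M[idx(i, j)]) state = 'M';
      else if (target == Y[idx(i, j)]) state = 'Y';
      else state = 'X';
    } else if (state == 'X') {
      ar.push_back(read[i - 1]);
      af.push_back('-');
      double here = X[idx(i, j)];
      --i;
      if (here == M[idx(i, j)] - gap_open) state = 'M';
      else if (here == X[idx(i, j)] - gap_ext) state = 'X';
      else state = 'Y';
    } else { // Y
      ar.push_back('-');
      af.push_back(ref[j - 1]);
      double here = Y[idx(i, j)];
      --j;
      if (here == M[idx(i, j)] - gap_open) state = 'M';
      else if (here == Y[idx(i, j)] - gap_ext) state = 'Y';
      else state = 'X';
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(af.begin(), af.end());

  return List::create(_["score"] = score,
                      _["aligned_read"] = ar,
                      _["aligned_ref"] = af);
}
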