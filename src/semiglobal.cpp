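#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap semi-global (free end gaps on both sequences) alignment.
// A gap of length L costs gap_open + L * gap_extend, except terminal gaps
// on either sequence which are free. Traceback is deterministic with
// tie-break order diagonal > up > left; among equal end scores the cell
// nearest the (n, m) corner wins (corner first, then last column bottom-up,
// then last row right-to-left).
//
// ai, bi are 0-based indices of the residues of a and b into the rows /
// columns of the integer substitution matrix `sub`.

static const int NEG = -100000000;

// [[Rcpp::export]]
List semiglobal_align_cpp(std::string a, std::string b,
                          IntegerVector ai, IntegerVector bi,
                          IntegerMatrix sub,
                          int gap_open, int gap_extend) {
  const int n = a.size(), m = b.size();
  const int go = gap_open, ge = gap_extend;
  // H: best ending in match/mismatch or boundary; E: gap in b (vertical,
  // consumes a); F: gap in a (horizontal, consumes b).
  std::vector<int> H((n + 1) * (m + 1)), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  for (int j = 0; j <= m; ++j) H[at(0, j)] = 0;  // free leading gap in a
  for (int i = 0; i <= n; ++i) H[at(i, 0)] = 0;  // free leading gap in b

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int e = H[at(i - 1, j)] - go - ge;
      if (E[at(i - 1, j)] != NEG && E[at(i - 1, j)] - ge > e)
        e = E[at(i - 1, j)] - ge;
      E[at(i, j)] = e;
      int f = H[at(i, j - 1)] - go - ge;
      if (F[at(i, j - 1)] != NEG && F[at(i, j - 1)] - ge > f)
        f = F[at(i, j - 1)] - ge;
      F[at(i, j)] = f;
      int h = H[at(i - 1, j - 1)] + sub(ai[i - 1], bi[j - 1]);
      if (e > h) h = e;
      if (f > h) h = f;
      H[at(i, j)] = h;
    }
  }

  // End cell: max of H over last row and last column, deterministic choice.
  int bi_ = n, bj_ = m, best = H[at(n, m)];
  for (int i = n - 1; i >= 0; --i)
    if (H[at(i, m)] > best) { best = H[at(i, m)]; bi_ = i; bj_ = m; }
  for (int j = m - 1; j >= 0; --j)
    if (H[at(n, j)] > best) { best = H[at(n, j)]; bi_ = n; bj_ = j; }

  std::string ra, rb;  // built reversed
  // Free trailing gaps.
  for (int j = m; j > bj_; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  for (int i = n; i > bi_; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }

  int i = bi_, j = bj_;
  char state = 'H';
  while (i > 0 && j > 0) {
    if (state == 'H') {
      int h = H[at(i, j)];
      if (h == H[at(i - 1, j - 1)] + sub(ai[i - 1], bi[j - 1])) {
        ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
      } else if (h == E[at(i, j)]) {
        state = 'E';
      } else if (h == F[at(i, j)]) {
        state = 'F';
      } else {
        stop("traceback failure in H");  // should be unreachable
      }
    } else if (state == 'E') {
      ra.push_back(a[i - 1]); rb.push_back('-');
      if (E[at(i, j)] == H[at(i - 1, j)] - go - ge) state = 'H';
      else state = 'E';  // extend
      --i;
    } else {  // 'F'
      ra.push_back('-'); rb.push_back(b[j - 1]);
      if (F[at(i, j)] == H[at(i, j - 1)] - go - ge) state = 'H';
      else state = 'F';
      --j;
    }
  }
  // Free leading gaps (H[i][0] = H[0][j] = 0; E/F cannot reach the border
  // with a better score than the free-gap boundary, traceback re-enters H
  // only via an exact -go-ge step, so any residual prefix is terminal).
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }

  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  // Alignment statistics over the aligned region (first..last column where
  // both sequences place a residue).
  int first = -1, last = -1, matches = 0;
  for (int c = 0; c < (int)ra.size(); ++c) {
    if (ra[c] != '-' && rb[c] != '-') {
      if (first < 0) first = c;
      last = c;
    }
  }
  int region = (first < 0) ? 0 : last - first + 1;
  if (first >= 0)
    for (int c = first; c <= last; ++c)
      if (ra[c] != '-' && rb[c] != '-' && ra[c] == rb[c]) ++matches;

  return List::create(_["score"] = best, _["aligned_a"] = ra,
                      _["aligned_b"] = rb, _["aligned_region_length"] = region,
                      _["n_exact_matches"] = matches);
}
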