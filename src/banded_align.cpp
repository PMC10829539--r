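#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Banded global (Needleman-Wunsch) alignment with linear gap penalty.
//
// The band constrains j - i (position in b minus position in a) to
// [-band, band]; reaching cell (m, n) requires band >= |n - m|.
// Tie-breaking is deterministic: diagonal, then gap-in-b (deletion of an
// 'a' character from 'b'), then gap-in-a (insertion in 'b').
//
// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string a, std::string b, int band,
                      double match, double mismatch, double gap) {
  const int m = (int) a.size();
  const int n = (int) b.size();
  if (band < std::abs(n - m))
    stop("band (%d) too small for length difference (%d); widen the band",
         band, std::abs(n - m));
  const int W = 2 * band + 1;
  const double NEG = -std::numeric_limits<double>::infinity();

  // score[i][k], k = j - i + band
  std::vector<double> prev(W, NEG), cur(W, NEG);
  // moves: 1 = diagonal, 2 = gap in b (consume a), 3 = gap in a (consume b)
  std::vector<signed char> ptr((size_t)(m + 1) * W, 0);

  for (int k = 0; k < W; ++k) {
    int j = k - band; // i = 0
    if (j >= 0 && j <= n) {
      prev[k] = gap * j;
      if (j > 0) ptr[k] = 3;
    }
  }
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(n, i + band);
    std::fill(cur.begin(), cur.end(), NEG);
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i + band;
      double best = NEG;
      signed char mv = 0;
      if (j >= 1) { // diagonal: prev row, same k
        double s = prev[k];
        if (s > NEG) {
          double sc = s + (a[i - 1] == b[j - 1] ? match : mismatch);
          if (sc > best) { best = sc; mv = 1; }
        }
      }
      if (k + 1 < W) { // gap in b: prev row, k + 1
        double s = prev[k + 1];
        if (s > NEG) {
          double sc = s + gap;
          if (sc > best) { best = sc; mv = 2; }
        }
      }
      if (k - 1 >= 0 && j >= 1) { // gap in a: same row, k - 1
        double s = cur[k - 1];
        if (s > NEG) {
          double sc = s + gap;
          if (sc > best) { best = sc; mv = 3; }
        }
      }
      if (i == 0 && j == 0) { best = 0.0; mv = 0; }
      cur[k] = best;
      ptr[(size_t)i * W + k] = mv;
    }
    std::swap(prev, cur);
  }

  int kend = n - m + band;
  double score = prev[kend];
  if (!R_finite(score))
    stop("no alignment path inside the band; widen the band");

  std::string ra, rb;
  ra.reserve(m + band); rb.reserve(n + band);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    signed char mv = ptr[(size_t)i * W + (j - i + band)];
    if (mv == 1) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (mv == 2) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else if (mv == 3) {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    } else {
      stop("corrupt traceback");
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
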