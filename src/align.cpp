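#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap global alignment.
// States: M (diagonal), X (gap in b, consumes a), Y (gap in a, consumes b).
// A gap of length k costs gap_open + k * gap_extend.
// Traceback is deterministic: on ties prefer M > X > Y everywhere, which
// realises the documented "diagonal > gap-in-b > gap-in-a" rule.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// pick argmax among (m, x, y) with priority M > X > Y on ties
static inline int argmax3(double m, double x, double y, double &best) {
  best = m;
  int who = 0;
  if (x > best) { best = x; who = 1; }
  if (y > best) { best = y; who = 2; }
  return who;
}

// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b,
                  NumericMatrix sub, std::string alphabet,
                  double gap_open, double gap_extend,
                  bool free_end_gaps) {
  const int n = a.size(), m = b.size();
  int idx[256];
  for (int i = 0; i < 256; ++i) idx[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    idx[(unsigned char)alphabet[i]] = (int)i;

  auto score_at = [&](int i, int j) {
    return sub(idx[(unsigned char)a[i - 1]], idx[(unsigned char)b[j - 1]]);
  };

  const double open_cost = gap_open + gap_extend;
  const size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<double> M(sz, NEG_INF), X(sz, NEG_INF), Y(sz, NEG_INF);
  // predecessor state of each cell/state: 0=M 1=X 2=Y, -1 = none
  std::vector<signed char> pM(sz, -1), pX(sz, -1), pY(sz, -1);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = free_end_gaps ? 0.0 : -(gap_open + i * gap_extend);
    pX[at(i, 0)] = 1;
  }
  if (n >= 1) pX[at(1, 0)] = 0;
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = free_end_gaps ? 0.0 : -(gap_open + j * gap_extend);
    pY[at(0, j)] = 2;
  }
  if (m >= 1) pY[at(0, 1)] = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = at(i, j), di = at(i - 1, j - 1),
                   up = at(i - 1, j), lf = at(i, j - 1);
      double best;
      int who = argmax3(M[di], X[di], Y[di], best);
      if (best > NEG_INF) {
        M[c] = best + score_at(i, j);
        pM[c] = (signed char)who;
      }
      who = argmax3(M[up] - open_cost, X[up] - gap_extend,
                    Y[up] - open_cost, best);
      X[c] = best;
      pX[c] = (signed char)who;
      who = argmax3(M[lf] - open_cost, X[lf] - open_cost,
                    Y[lf] - gap_extend, best);
      Y[c] = best;
      pY[c] = (signed char)who;
    }
  }

  // terminal cell and state; with free end gaps, trailing gaps are free so
  // the end may sit on the last row/column with the remainder gapped at
  // zero cost. Tie-break: corner first, then last column (largest i), then
  // last row (largest j); states M > X > Y.
  int ei = n, ej = m;
  double score;
  int state = argmax3(M[at(n, m)], X[at(n, m)], Y[at(n, m)], score);
  if (free_end_gaps) {
    for (int i = n; i >= 0; --i) {
      double s;
      int w = argmax3(M[at(i, m)], X[at(i, m)], Y[at(i, m)], s);
      if (s > score) { score = s; state = w; ei = i; ej = m; }
    }
    for (int j = m; j >= 0; --j) {
      double s;
      int w = argmax3(M[at(n, j)], X[at(n, j)], Y[at(n, j)], s);
      if (s > score) { score = s; state = w; ei = n; ej = j; }
    }
  }

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  // free trailing gaps
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }

  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    const size_t c = at(i, j);
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = pM[c]; --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = pX[c]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = pY[c]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score);
}
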