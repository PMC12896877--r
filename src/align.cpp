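#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Global alignment (Needleman-Wunsch / Gotoh) of two short RNA strings.
//
// Gap of length L costs gap_open + (L-1) * gap_extend; gap_open == gap_extend
// gives the linear model. The two-state recurrence over H = max(M, X, Y) is
// exact only when opening is at least as costly as extending
// (gap_open <= gap_extend); the R wrapper enforces that.
//
// Tie preferences, for determinism:
//   * cell state: diagonal (M) > gap-in-subject (X, "up") > gap-in-query (Y, "left")
//   * within a gap state: extend an existing gap rather than re-open.

static const double NEG = -1e18;

// [[Rcpp::export(name = ".nw_align")]]
List nw_align(const std::string& a, const std::string& b,
              double match, double mismatch,
              double gap_open, double gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  const int W = m + 1;
  std::vector<double> H((n + 1) * W, NEG), M(H), X(H), Y(H);
  #define AT(i, j) ((i) * W + (j))

  H[AT(0, 0)] = 0.0; M[AT(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[AT(i, 0)] = gap_open + (i - 1) * gap_extend;
    H[AT(i, 0)] = X[AT(i, 0)];
  }
  for (int j = 1; j <= m; ++j) {
    Y[AT(0, j)] = gap_open + (j - 1) * gap_extend;
    H[AT(0, j)] = Y[AT(0, j)];
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      M[AT(i, j)] = H[AT(i - 1, j - 1)] + s;
      X[AT(i, j)] = std::max(H[AT(i - 1, j)] + gap_open,
                             X[AT(i - 1, j)] + gap_extend);
      Y[AT(i, j)] = std::max(H[AT(i, j - 1)] + gap_open,
                             Y[AT(i, j - 1)] + gap_extend);
      double h = M[AT(i, j)];
      if (X[AT(i, j)] > h) h = X[AT(i, j)];
      if (Y[AT(i, j)] > h) h = Y[AT(i, j)];
      H[AT(i, j)] = h;
    }
  }

  // traceback; state: 0 = M, 1 = X (up), 2 = Y (left)
  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  int state;
  auto pick_state = [&](int i, int j) -> int {
    if (i == 0) return 2;
    if (j == 0) return 1;
    double h = H[AT(i, j)];
    if (M[AT(i, j)] == h) return 0;
    if (X[AT(i, j)] == h) return 1;
    return 2;
  };
  state = pick_state(i, j);
  while (i > 0 || j > 0) {
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j;
      if (i > 0 || j > 0) state = pick_state(i, j);
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      bool extended = (i > 1 || j == 0) &&
        (X[AT(i, j)] == X[AT(i - 1, j)] + gap_extend);
      --i;
      if (i > 0 || j > 0) state = extended ? 1 : pick_state(i, j);
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      bool extended = (j > 1 || i == 0) &&
        (Y[AT(i, j)] == Y[AT(i, j - 1)] + gap_extend);
      --j;
      if (i > 0 || j > 0) state = extended ? 2 : pick_state(i, j);
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = H[AT(n, m)]);
}

// Score-only variant for catalogue screens (no traceback allocation).
// [[Rcpp::export(name = ".nw_score")]]
double nw_score(const std::string& a, const std::string& b,
                double match, double mismatch,
                double gap_open, double gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<double> Hp(m + 1), H(m + 1), Xp(m + 1), X(m + 1), Y(m + 1);
  Hp[0] = 0.0; Xp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Hp[j] = gap_open + (j - 1) * gap_extend;
    Xp[j] = NEG;
  }
  for (int i = 1; i <= n; ++i) {
    H[0] = gap_open + (i - 1) * gap_extend;
    X[0] = H[0];
    double y = NEG;
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double mm = Hp[j - 1] + s;
      X[j] = std::max(Hp[j] + gap_open, Xp[j] + gap_extend);
      y = std::max(H[j - 1] + gap_open, y + gap_extend);
      Y[j] = y;
      H[j] = std::max(mm, std::max(X[j], y));
    }
    std::swap(Hp, H); std::swap(Xp, X);
  }
  return Hp[m];
}
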