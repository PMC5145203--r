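#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap (Gotoh) global alignment kernels shared by the pairwise and
// profile aligners. Scores are maximised; a gap of length k costs
// open + (k-1) * extend, and adjacent gaps in opposite sequences each pay
// the opening penalty. State codes in the returned ops vector:
//   0 = consume one position of both inputs (match/mismatch column)
//   1 = consume a only (gap in b)
//   2 = consume b only (gap in a)

static const double NEG_INF = -1e30;

// Traceback preference when scores tie: match/mismatch, then gap in a
// (consume b), then gap in b (consume a).
static inline int pick3(double m, double ga, double gb) {
  if (m >= ga && m >= gb) return 0;
  if (ga >= gb) return 2;
  return 1;
}

// a, b: 1-based indices into S (square scoring matrix).
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double open, double ext) {
  const int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // X: gap in b (consumes a); Y: gap in a (consumes b).
  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = open + (i - 1) * ext;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = open + (j - 1) * ext;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S(a[i - 1] - 1, b[j - 1] - 1);
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      M(i, j) = s + std::max(dm, std::max(dx, dy));
      X(i, j) = std::max(M(i - 1, j) + open,
                std::max(X(i - 1, j) + ext, Y(i - 1, j) + open));
      Y(i, j) = std::max(M(i, j - 1) + open,
                std::max(X(i, j - 1) + open, Y(i, j - 1) + ext));
    }
  }
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  // state: 0 = M, 1 = X, 2 = Y
  int state = pick3(M(n, m), Y(n, m), X(n, m)) == 0 ? 0 :
              (pick3(M(n, m), Y(n, m), X(n, m)) == 2 ? 2 : 1);
  std::vector<int> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(2); --j; continue; }
    if (j == 0) { ops.push_back(1); --i; continue; }
    if (state == 0) {
      double s = S(a[i - 1] - 1, b[j - 1] - 1);
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      ops.push_back(0);
      // preference among predecessors: M, then Y (gap in a), then X
      if (dm + s >= M(i, j) - 1e-9 && dm >= dx && dm >= dy) state = 0;
      else if (dy >= dx) state = 2;
      else state = 1;
      --i; --j;
    } else if (state == 1) { // in X: gap in b, consumed a
      double fm = M(i - 1, j) + open, fx = X(i - 1, j) + ext,
             fy = Y(i - 1, j) + open;
      ops.push_back(1);
      if (fm >= fx && fm >= fy) state = 0;
      else if (fy >= fx) state = 2;
      else state = 1;
      --i;
    } else { // in Y: gap in a, consumed b
      double fm = M(i, j - 1) + open, fx = X(i, j - 1) + open,
             fy = Y(i, j - 1) + ext;
      ops.push_back(2);
      if (fm >= fy && fm >= fx) state = 0;
      else if (fy >= fx) state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = wrap(ops), _["score"] = best);
}

// Profile-profile alignment. A (La x K) and B (Lb x K) are residue frequency
// profiles (gap mass dropped, so rows sum to <= 1); the column score is
// fa' S fb. Same affine machinery and tie-breaks as nw_align_cpp.
// [[Rcpp::export(name = ".profile_align_cpp")]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B, NumericMatrix S,
                       double open, double ext) {
  const int n = A.nrow(), m = B.nrow(), K = S.nrow();
  // T = B %*% S so that score(i, j) = A[i, ] . T[j, ]
  NumericMatrix T(m, K);
  for (int j = 0; j < m; ++j)
    for (int x = 0; x < K; ++x) {
      double acc = 0.0;
      for (int y = 0; y < K; ++y) acc += B(j, y) * S(y, x);
      T(j, x) = acc;
    }
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = open + (i - 1) * ext;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = open + (j - 1) * ext;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = 0.0;
      for (int x = 0; x < K; ++x) s += A(i - 1, x) * T(j - 1, x);
      M(i, j) = s + std::max(M(i - 1, j - 1),
                 std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      X(i, j) = std::max(M(i - 1, j) + open,
                std::max(X(i - 1, j) + ext, Y(i - 1, j) + open));
      Y(i, j) = std::max(M(i, j - 1) + open,
                std::max(X(i, j - 1) + open, Y(i, j - 1) + ext));
    }
  }
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  int state;
  if (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) state = 0;
  else if (Y(n, m) >= X(n, m)) state = 2;
  else state = 1;
  std::vector<int> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(2); --j; continue; }
    if (j == 0) { ops.push_back(1); --i; continue; }
    if (state == 0) {
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      ops.push_back(0);
      if (dm >= dx && dm >= dy) state = 0;
      else if (dy >= dx) state = 2;
      else state = 1;
      --i; --j;
    } else if (state == 1) {
      double fm = M(i - 1, j) + open, fx = X(i - 1, j) + ext,
             fy = Y(i - 1, j) + open;
      ops.push_back(1);
      if (fm >= fx && fm >= fy) state = 0;
      else if (fy >= fx) state = 2;
      else state = 1;
      --i;
    } else {
      double fm = M(i, j - 1) + open, fx = X(i, j - 1) + open,
             fy = Y(i, j - 1) + ext;
      ops.push_back(2);
      if (fm >= fy && fm >= fx) state = 0;
      else if (fy >= fx) state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = wrap(ops), _["score"] = best);
}

// Pairwise difference / comparable-site counts over an integer alignment
// matrix (rows = sequences, 0 = gap). Pairwise deletion: a column counts for
// a pair iff both entries are non-zero.
// [[Rcpp::export(name = ".pdist_counts_cpp")]]
List pdist_counts_cpp(IntegerMatrix Mx) {
  const int n = Mx.nrow(), L = Mx.ncol();
  IntegerMatrix ndiff(n, n), ncomp(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int d = 0, c = 0;
      for (int k = 0; k < L; ++k) {
        int xi = Mx(i, k), xj = Mx(j, k);
        if (xi != 0 && xj != 0) { ++c; if (xi != xj) ++d; }
      }
      ndiff(i, j) = ndiff(j, i) = d;
      ncomp(i, j) = ncomp(j, i) = c;
    }
  }
  return List::create(_["ndiff"] = ndiff, _["ncomp"] = ncomp);
}
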