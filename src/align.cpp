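#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global (Needleman-Wunsch/Gotoh) alignment.
// Convention: a gap run of length L costs open + L*ext; end gaps are
// penalized (true global). Tie-breaks are fixed so tracebacks are
// deterministic: diagonal (match state) > up (gap in b) > left (gap in a),
// and predecessor states are preferred in the order M > X > Y.
//
// Sequences arrive as 0-based integer codes into the substitution matrix.

static const double NEG_INF = -1e30;

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(IntegerVector a, IntegerVector b, NumericMatrix sub,
               double open, double ext) {
  const int n = a.size(), m = b.size();
  // state matrices: M diagonal, X gap in b (consumes a), Y gap in a
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: predecessor state per cell/state (0=M,1=X,2=Y,-1=none)
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = -(open + i * ext);
    tX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -(open + j * ext);
    tY(0, j) = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = sub(a[i - 1], b[j - 1]);
      // M: prefer M > X > Y on ties
      double best = M(i - 1, j - 1); int who = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); who = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); who = 2; }
      M(i, j) = best + s; tM(i, j) = who;
      // X: gap in b, consume a[i]
      double cand = M(i - 1, j) - (open + ext); who = 0;
      if (X(i - 1, j) - ext > cand) { cand = X(i - 1, j) - ext; who = 1; }
      if (Y(i - 1, j) - (open + ext) > cand) {
        cand = Y(i - 1, j) - (open + ext); who = 2;
      }
      X(i, j) = cand; tX(i, j) = who;
      // Y: gap in a, consume b[j]
      cand = M(i, j - 1) - (open + ext); who = 0;
      if (X(i, j - 1) - (open + ext) > cand) {
        cand = X(i, j - 1) - (open + ext); who = 1;
      }
      if (Y(i, j - 1) - ext > cand) { cand = Y(i, j - 1) - ext; who = 2; }
      Y(i, j) = cand; tY(i, j) = who;
    }
  }

  double score = M(n, m); int state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 0) {
      prev = tM(i, j);
      ra.push_back('A' + a[i - 1]);  // placeholder, remapped in R? no:
      rb.push_back('A' + b[j - 1]);
      --i; --j;
    } else if (state == 1) {
      prev = tX(i, j);
      ra.push_back('A' + a[i - 1]);
      rb.push_back('-');
      --i;
    } else {
      prev = tY(i, j);
      ra.push_back('-');
      rb.push_back('A' + b[j - 1]);
      --j;
    }
    state = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  // aligned rows are returned as integer code strings offset from 'A';
  // gap columns carry '-'. The R wrapper maps codes back to residues.
  return List::create(_["score"] = score, _["row_a"] = ra, _["row_b"] = rb);
}
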