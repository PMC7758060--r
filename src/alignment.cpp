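#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise DP (Gotoh three-state) over a precomputed pair-score
// matrix S (n x m): S(i,j) = score of aligning position i of `a` with
// position j of `b`. A gap of length L costs gap_open + L * gap_extend.
//
// States: M (aligned pair), X (gap in b: consume a, "up"), Y (gap in a:
// consume b, "left"). Tie-breaks are fixed so tracebacks are reproducible:
// among states M > X > Y, and the best local cell is the first maximum in
// row-major scan order.

static const double NEG_INF = -1e300;

struct DPResult {
  double score;
  int end_i, end_j, end_state; // 1-based DP coordinates
};

// [[Rcpp::export]]
double cpp_align_score(NumericMatrix S, double gap_open, double gap_extend,
                       bool local) {
  const int n = S.nrow(), m = S.ncol();
  const double open_cost = gap_open + gap_extend;
  std::vector<double> Mprev(m + 1), Mcur(m + 1), Xprev(m + 1), Xcur(m + 1),
      Yprev(m + 1), Ycur(m + 1);
  double best = local ? 0.0 : NEG_INF;
  Mprev[0] = 0.0;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = local ? NEG_INF : NEG_INF;
    Xprev[j] = NEG_INF;
    Yprev[j] = local ? NEG_INF : -(gap_open + j * gap_extend);
  }
  Xprev[0] = NEG_INF;
  Yprev[0] = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG_INF;
    Xcur[0] = local ? NEG_INF : -(gap_open + i * gap_extend);
    Ycur[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(Mprev[j - 1], std::max(Xprev[j - 1], Yprev[j - 1]));
      if (local) diag = std::max(diag, 0.0);
      // local: i==1 or j==1 cells can always start fresh
      if (!local && i == 1 && j == 1) diag = 0.0;
      double mv = (diag <= NEG_INF / 2) ? NEG_INF : diag + S(i - 1, j - 1);
      Mcur[j] = mv;
      double xo = std::max(Mprev[j], Yprev[j]) ;
      Xcur[j] = std::max(xo <= NEG_INF / 2 ? NEG_INF : xo - open_cost,
                         Xprev[j] <= NEG_INF / 2 ? NEG_INF : Xprev[j] - gap_extend);
      double yo = std::max(Mcur[j - 1], Xcur[j - 1]);
      Ycur[j] = std::max(yo <= NEG_INF / 2 ? NEG_INF : yo - open_cost,
                         Ycur[j - 1] <= NEG_INF / 2 ? NEG_INF : Ycur[j - 1] - gap_extend);
      if (local && Mcur[j] > best) best = Mcur[j];
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }
  if (!local) {
    best = std::max(Mprev[m], std::max(Xprev[m], Yprev[m]));
    if (n == 0 || m == 0) {
      int L = std::max(n, m);
      best = (L == 0) ? 0.0 : -(gap_open + L * gap_extend);
    }
  }
  return best;
}

// Full DP with traceback pointers.
// [[Rcpp::export]]
List cpp_align(NumericMatrix S, double gap_open, double gap_extend, bool local) {
  const int n = S.nrow(), m = S.ncol();
  const double open_cost = gap_open + gap_extend;
  if (n == 0 || m == 0) {
    double sc = 0.0;
    if (!local) {
      int L = std::max(n, m);
      sc = (L == 0) ? 0.0 : -(gap_open + L * gap_extend);
    }
    IntegerVector ai, bi;
    if (!local && n == 0 && m > 0) { ai = IntegerVector(m, NA_INTEGER); bi = seq(0, m - 1); }
    if (!local && m == 0 && n > 0) { ai = seq(0, n - 1); bi = IntegerVector(n, NA_INTEGER); }
    return List::create(_["score"] = sc, _["a_idx"] = ai, _["b_idx"] = bi);
  }
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // pointer codes: for M: 0 diag-from-M, 1 diag-from-X, 2 diag-from-Y, 3 fresh start
  // for X: 0 open-from-M, 1 extend-X, 2 open-from-Y; for Y likewise with X<->Y roles
  IntegerMatrix PM(n + 1, m + 1), PX(n + 1, m + 1), PY(n + 1, m + 1);
  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = local ? NEG_INF : -(gap_open + j * gap_extend);
    PY(0, j) = (j == 1) ? 0 : 1;
  }
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = local ? NEG_INF : -(gap_open + i * gap_extend);
    PX(i, 0) = (i == 1) ? 0 : 1;
  }
  double best = 0.0; int bi_ = 0, bj_ = 0, bstate = -1; // local best (M only)
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M
      double dM = M(i - 1, j - 1), dX = X(i - 1, j - 1), dY = Y(i - 1, j - 1);
      double dbest = dM; int dptr = 0;
      if (dX > dbest) { dbest = dX; dptr = 1; }
      if (dY > dbest) { dbest = dY; dptr = 2; }
      if (local && 0.0 > dbest) { dbest = 0.0; dptr = 3; }
      M(i, j) = (dbest <= NEG_INF / 2) ? NEG_INF : dbest + S(i - 1, j - 1);
      PM(i, j) = dptr;
      // X (consume a, gap in b)
      double xM = M(i - 1, j) - open_cost, xX = X(i - 1, j) - gap_extend,
             xY = Y(i - 1, j) - open_cost;
      double xb = xM; int xp = 0;
      if (xX > xb) { xb = xX; xp = 1; }
      if (xY > xb) { xb = xY; xp = 2; }
      X(i, j) = xb; PX(i, j) = xp;
      // Y (consume b, gap in a)
      double yM = M(i, j - 1) - open_cost, yY = Y(i, j - 1) - gap_extend,
             yX = X(i, j - 1) - open_cost;
      double yb = yM; int yp = 0;
      if (yY > yb) { yb = yY; yp = 1; }
      if (yX > yb) { yb = yX; yp = 2; }
      Y(i, j) = yb; PY(i, j) = yp;
      if (local && M(i, j) > best) { best = M(i, j); bi_ = i; bj_ = j; bstate = 0; }
    }
  }
  std::vector<int> ai, bj;
  double score;
  int i, j, state;
  if (local) {
    score = best;
    if (bstate < 0) // empty alignment
      return List::create(_["score"] = 0.0, _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0));
    i = bi_; j = bj_; state = 0;
  } else {
    double gM = M(n, m), gX = X(n, m), gY = Y(n, m);
    score = gM; state = 0;
    if (gX > score) { score = gX; state = 1; }
    if (gY > score) { score = gY; state = 2; }
    i = n; j = m;
  }
  while (i > 0 || j > 0) {
    if (state == 0) { // M
      if (i == 0 || j == 0) break;
      int p = PM(i, j);
      ai.push_back(i - 1); bj.push_back(j - 1);
      --i; --j;
      if (p == 3) break;           // local fresh start
      state = p;                    // 0=M,1=X,2=Y
      if (local && i == 0 && j == 0) break;
    } else if (state == 1) { // X: consumed a[i-1] against gap
      int p = PX(i, j);
      ai.push_back(i - 1); bj.push_back(NA_INTEGER);
      --i;
      state = (p == 0) ? 0 : (p == 1 ? 1 : 2);
      if (local && p == 0 && false) break;
    } else { // Y
      int p = PY(i, j);
      ai.push_back(NA_INTEGER); bj.push_back(j - 1);
      --j;
      state = (p == 0) ? 0 : (p == 1 ? 2 : 1);
    }
    if (local && state == 0 && (i == 0 || j == 0)) break;
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
  return List::create(_["score"] = score,
                      _["a_idx"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_idx"] = IntegerVector(bj.begin(), bj.end()));
}

// Pair-score matrix for integer-coded sequences under a substitution matrix.
// [[Rcpp::export]]
NumericMatrix cpp_pair_scores(IntegerVector a, IntegerVector b, NumericMatrix sub) {
  NumericMatrix S(a.size(), b.size());
  for (int i = 0; i < a.size(); ++i)
    for (int j = 0; j < b.size(); ++j)
      S(i, j) = sub(a[i], b[j]);
  return S;
}

// Best local profile-vs-sequence scores for a list of integer-coded targets.
// prof is width x alphabet_size.
// [[Rcpp::export]]
NumericVector cpp_profile_best_scores(NumericMatrix prof, List targets,
                                      double gap_open, double gap_extend) {
  const int nt = targets.size();
  NumericVector out(nt);
  const int n = prof.nrow();
  for (int t = 0; t < nt; ++t) {
    IntegerVector b = targets[t];
    NumericMatrix S(n, b.size());
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < b.size(); ++j)
        S(i, j) = prof(i, b[j]);
    out[t] = cpp_align_score(S, gap_open, gap_extend, true);
  }
  return out;
}

// Best scores of one integer-coded query against many targets under a
// substitution matrix; local or global mode. Used for shuffle/multinomial nulls.
// [[Rcpp::export]]
NumericVector cpp_seq_best_scores(IntegerVector a, List targets, NumericMatrix sub,
                                  double gap_open, double gap_extend, bool local) {
  const int nt = targets.size();
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerVector b = targets[t];
    NumericMatrix S(a.size(), b.size());
    for (int i = 0; i < a.size(); ++i)
      for (int j = 0; j < b.size(); ++j)
        S(i, j) = sub(a[i], b[j]);
    out[t] = cpp_align_score(S, gap_open, gap_extend, local);
  }
  return out;
}
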