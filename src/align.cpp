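#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state recursion).
// Sequences arrive as 0-based integer codes indexing `sub`.
// A gap of length k costs gap_open + k * gap_extend.

static const double NEG_INF = -1e30;

static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// [[Rcpp::export]]
List affine_global_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                       double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double go = gap_open + gap_extend; // cost of opening a length-1 gap
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  // X: a-residue against gap (vertical); Y: b-residue against gap (horizontal)
  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= m; ++i) X(i, 0) = -(gap_open + i * gap_extend);
  for (int j = 1; j <= n; ++j) Y(0, j) = -(gap_open + j * gap_extend);
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      M(i, j) = s + max3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1));
      X(i, j) = max3(M(i - 1, j) - go, X(i - 1, j) - gap_extend, Y(i - 1, j) - go);
      Y(i, j) = max3(M(i, j - 1) - go, Y(i, j - 1) - gap_extend, X(i, j - 1) - go);
    }
  }
  double score = max3(M(m, n), X(m, n), Y(m, n));

  // traceback: state 0 = M, 1 = X, 2 = Y
  std::vector<int> ai, bi; // 1-based positions, 0 = gap
  int i = m, j = n;
  int state = (score == M(m, n)) ? 0 : (score == X(m, n)) ? 1 : 2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double prev = M(i, j) - sub(a[i - 1], b[j - 1]);
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      state = (std::abs(prev - M(i, j)) < 1e-9) ? 0
            : (std::abs(prev - X(i, j)) < 1e-9) ? 1 : 2;
    } else if (state == 1) {
      double cur = X(i, j);
      ai.push_back(i); bi.push_back(0);
      int pi = i - 1;
      if (pi >= 0 && std::abs(cur - (X(pi, j) - gap_extend)) < 1e-9) state = 1;
      else if (std::abs(cur - (M(pi, j) - go)) < 1e-9) state = 0;
      else state = 2;
      i = pi;
    } else {
      double cur = Y(i, j);
      ai.push_back(0); bi.push_back(j);
      int pj = j - 1;
      if (pj >= 0 && std::abs(cur - (Y(i, pj) - gap_extend)) < 1e-9) state = 2;
      else if (std::abs(cur - (M(i, pj) - go)) < 1e-9) state = 0;
      else state = 1;
      j = pj;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = score,
                      _["a_pos"] = wrap(ai), _["b_pos"] = wrap(bi));
}

// [[Rcpp::export]]
List affine_local_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                      double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double go = gap_open + gap_extend;
  NumericMatrix M(m + 1, n + 1), X(m + 1, n + 1), Y(m + 1, n + 1);
  for (int i = 0; i <= m; ++i)
    for (int j = 0; j <= n; ++j) { M(i, j) = X(i, j) = Y(i, j) = NEG_INF; }
  double best = 0.0; int bi_ = 0, bj_ = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double s = sub(a[i - 1], b[j - 1]);
      double diag = max3(M(i - 1, j - 1), X(i - 1, j - 1), Y(i - 1, j - 1));
      M(i, j) = s + std::max(0.0, diag);
      X(i, j) = max3(M(i - 1, j) - go, X(i - 1, j) - gap_extend, Y(i - 1, j) - go);
      Y(i, j) = max3(M(i, j - 1) - go, Y(i, j - 1) - gap_extend, X(i, j - 1) - go);
      if (M(i, j) > best) { best = M(i, j); bi_ = i; bj_ = j; }
    }
  }
  std::vector<int> ai, bj;
  if (best > 0) {
    int i = bi_, j = bj_, state = 0;
    while (i > 0 || j > 0) {
      if (state == 0) {
        double prev = M(i, j) - sub(a[i - 1], b[j - 1]);
        ai.push_back(i); bj.push_back(j);
        --i; --j;
        if (prev <= 1e-9 && std::abs(prev) < 1e-9) break; // local start
        if (std::abs(prev - M(i, j)) < 1e-9) state = 0;
        else if (std::abs(prev - X(i, j)) < 1e-9) state = 1;
        else state = 2;
      } else if (state == 1) {
        double cur = X(i, j);
        ai.push_back(i); bj.push_back(0);
        int pi = i - 1;
        if (std::abs(cur - (X(pi, j) - gap_extend)) < 1e-9) state = 1;
        else if (std::abs(cur - (M(pi, j) - go)) < 1e-9) state = 0;
        else state = 2;
        i = pi;
      } else {
        double cur = Y(i, j);
        ai.push_back(0); bj.push_back(j);
        int pj = j - 1;
        if (std::abs(cur - (Y(i, pj) - gap_extend)) < 1e-9) state = 2;
        else if (std::abs(cur - (M(i, pj) - go)) < 1e-9) state = 0;
        else state = 1;
        j = pj;
      }
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj.begin(), bj.end());
  return List::create(_["score"] = best,
                      _["a_pos"] = wrap(ai), _["b_pos"] = wrap(bj));
}

// Score-only Smith-Waterman against a list of targets (rolling rows).
// [[Rcpp::export]]
NumericVector affine_local_scores_cpp(IntegerVector a, List targets,
                                      NumericMatrix sub, double gap_open,
                                      double gap_extend) {
  const int m = a.size();
  const double go = gap_open + gap_extend;
  const int nt = targets.size();
  NumericVector out(nt);
  for (int t = 0; t < nt; ++t) {
    IntegerVector b = targets[t];
    const int n = b.size();
    std::vector<double> Mp(n + 1, NEG_INF), Xp(n + 1, NEG_INF), Yp(n + 1, NEG_INF);
    std::vector<double> Mc(n + 1), Xc(n + 1), Yc(n + 1);
    double best = 0.0;
    for (int i = 1; i <= m; ++i) {
      Mc[0] = NEG_INF; Xc[0] = NEG_INF; Yc[0] = NEG_INF;
      for (int j = 1; j <= n; ++j) {
        double s = sub(a[i - 1], b[j - 1]);
        double diag = max3(Mp[j - 1], Xp[j - 1], Yp[j - 1]);
        Mc[j] = s + std::max(0.0, diag);
        Xc[j] = max3(Mp[j] - go, Xp[j] - gap_extend, Yp[j] - go);
        Yc[j] = max3(Mc[j - 1] - go, Yc[j - 1] - gap_extend, Xc[j - 1] - go);
        if (Mc[j] > best) best = Mc[j];
      }
      std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    }
    out[t] = best;
  }
  return out;
}
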