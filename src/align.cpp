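#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment over sound-class index sequences with a
// linear gap penalty. Sequences are 1-based indices into the similarity
// matrix; 0 is never a valid index.

static inline double nw_fill(const IntegerVector& a, const IntegerVector& b,
                             const NumericMatrix& sim, double gap,
                             std::vector<double>& F) {
  const int n = a.size(), m = b.size();
  F.assign((n + 1) * (m + 1), 0.0);
  const int W = m + 1;
  for (int i = 1; i <= n; ++i) F[i * W] = i * gap;
  for (int j = 1; j <= m; ++j) F[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      const int bj = b[j - 1] - 1;
      double diag = F[(i - 1) * W + (j - 1)] + sim(ai, bj);
      double up   = F[(i - 1) * W + j] + gap;      // a[i] vs gap
      double left = F[i * W + (j - 1)] + gap;      // gap vs b[j]
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      F[i * W + j] = best;
    }
  }
  return F[n * W + m];
}

// [[Rcpp::export(name = ".nw_score")]]
double nw_score(IntegerVector a, IntegerVector b, NumericMatrix sim, double gap) {
  std::vector<double> F;
  return nw_fill(a, b, sim, gap, F);
}

// Traceback with deterministic tie-breaking: prefer diagonal (match/mismatch),
// then consuming a (gap in b), then consuming b (gap in a).
// Returns a 2-column matrix of 1-based positions, NA for gaps.
// [[Rcpp::export(name = ".nw_align")]]
List nw_align(IntegerVector a, IntegerVector b, NumericMatrix sim, double gap) {
  const int n = a.size(), m = b.size();
  std::vector<double> F;
  double score = nw_fill(a, b, sim, gap, F);
  const int W = m + 1;
  std::vector<int> pa, pb;
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        std::abs(F[i * W + j] - (F[(i - 1) * W + (j - 1)] + sim(a[i - 1] - 1, b[j - 1] - 1))) < eps) {
      pa.push_back(i); pb.push_back(j); --i; --j;
    } else if (i > 0 && std::abs(F[i * W + j] - (F[(i - 1) * W + j] + gap)) < eps) {
      pa.push_back(i); pb.push_back(NA_INTEGER); --i;
    } else {
      pa.push_back(NA_INTEGER); pb.push_back(j); --j;
    }
  }
  const int L = pa.size();
  IntegerMatrix pairs(L, 2);
  for (int k = 0; k < L; ++k) {
    pairs(k, 0) = pa[L - 1 - k];
    pairs(k, 1) = pb[L - 1 - k];
  }
  return List::create(_["score"] = score, _["pairs"] = pairs);
}

// Full matrix of normalized distances d = 1 - 2 S(a,b) / (S(a,a) + S(b,b)),
// clipped to [0, 1]. seqs is a list of 1-based integer vectors.
// [[Rcpp::export(name = ".nw_dist_matrix")]]
NumericMatrix nw_dist_matrix(List seqs, NumericMatrix sim, double gap) {
  const int N = seqs.size();
  NumericMatrix D(N, N);
  std::vector<IntegerVector> s(N);
  std::vector<double> self(N);
  std::vector<double> F;
  for (int i = 0; i < N; ++i) {
    s[i] = as<IntegerVector>(seqs[i]);
    double ss = 0.0;
    for (int k = 0; k < s[i].size(); ++k) ss += sim(s[i][k] - 1, s[i][k] - 1);
    self[i] = ss;
    if (ss <= 0.0) stop("degenerate self-score (<= 0) for sequence %d", i + 1);
  }
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      bool same = s[i].size() == s[j].size();
      if (same) {
        for (int k = 0; k < s[i].size(); ++k)
          if (s[i][k] != s[j][k]) { same = false; break; }
      }
      double d;
      if (same) {
        d = 0.0;  // identical class strings are at distance 0 exactly
      } else {
        double sc = nw_fill(s[i], s[j], sim, gap, F);
        d = 1.0 - 2.0 * sc / (self[i] + self[j]);
        if (d < 0.0) d = 0.0;
        if (d > 1.0) d = 1.0;
      }
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}
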