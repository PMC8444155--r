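#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Equilibrium base-pair probabilities under a uniform-weight ensemble of
// pseudoknot-free secondary structures: every structure S has weight
// pair_weight^{|S|}; P(i,j) is the weighted fraction of structures pairing
// i with j. Computed by an inside-outside pass over the unambiguous
// decomposition Z(i,j) = Z(i,j-1) + sum_k Z(i,k-1) * w * Z(k+1,j-1),
// with per-nucleotide rescaling so partition sums stay inside double range
// for multi-kilobase sequences.

static inline bool can_pair(int a, int b) {
  // codes: A=0, C=1, G=2, U/T=3, other=-1
  if (a < 0 || b < 0) return false;
  int lo = a < b ? a : b, hi = a < b ? b : a;
  return (lo == 0 && hi == 3) ||  // A:U
         (lo == 1 && hi == 2) ||  // C:G
         (lo == 2 && hi == 3);    // G:U
}

static std::vector<int> encode(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': case 'a': v[i] = 0; break;
      case 'C': case 'c': v[i] = 1; break;
      case 'G': case 'g': v[i] = 2; break;
      case 'U': case 'u': case 'T': case 't': v[i] = 3; break;
      default: v[i] = -1;
    }
  }
  return v;
}

// [[Rcpp::export(name = ".pair_prob_cpp")]]
NumericMatrix pair_prob_cpp(std::string seq, int min_loop, double pair_weight) {
  const int n = seq.size();
  NumericMatrix P(n, n);
  if (n == 0) return P;
  std::vector<int> code = encode(seq);

  // Q, O, Ob indexed [i][j] for 0 <= i <= j < n; empty spans handled inline.
  auto idx = [n](int i, int j) { return i * n + j; };
  std::vector<double> Q((size_t)n * n), O((size_t)n * n), Ob((size_t)n * n);

  double s = 1.0;           // per-nucleotide rescale factor
  double s_lo = 0.0, s_hi = R_PosInf;  // bracket for adaptive search
  const int max_tries = 200;
  bool ok = false;

  for (int attempt = 0; attempt < max_tries && !ok; ++attempt) {
    std::fill(Q.begin(), Q.end(), 0.0);
    const double u = 1.0 / s;        // weight of one unpaired base (scaled)
    const double pw = pair_weight / (s * s);  // one pair covers two bases
    bool overflow = false;

    for (int span = 1; span <= n && !overflow; ++span) {
      for (int i = 0; i + span - 1 < n; ++i) {
        int j = i + span - 1;
        double z = (span == 1 ? u : Q[idx(i, j - 1)] * u);
        for (int k = i; k <= j - min_loop - 1; ++k) {
          if (!can_pair(code[k], code[j])) continue;
          double left = (k == i) ? 1.0 : Q[idx(i, k - 1)];
          double inner = (k + 1 > j - 1) ? 1.0 : Q[idx(k + 1, j - 1)];
          z += left * pw * inner;
        }
        if (!std::isfinite(z)) { overflow = true; break; }
        Q[idx(i, j)] = z;
      }
    }

    double ztot = overflow ? R_PosInf : Q[idx(0, n - 1)];
    if (overflow || ztot > 1e280) {
      s_lo = s;  // scale too small
      s = std::isfinite(s_hi) ? std::sqrt(s_lo * s_hi) : s * 2.0;
      continue;
    }
    if (ztot <= 0.0 || ztot < 1e-280) {
      s_hi = s;  // scale too large
      s = (s_lo > 0.0) ? std::sqrt(s_lo * s_hi) : s / 2.0;
      continue;
    }
    ok = true;
  }
  if (!ok) stop("partition function scaling failed to converge");

  const double u = 1.0 / s;
  const double pw = pair_weight / (s * s);
  const double ztot = Q[idx(0, n - 1)];

  std::fill(O.begin(), O.end(), 0.0);
  std::fill(Ob.begin(), Ob.end(), 0.0);
  O[idx(0, n - 1)] = 1.0;
  for (int span = n; span >= 1; --span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      double o = O[idx(i, j)];
      if (o != 0.0) {
        // rule: Z(i,j) <- Z(i,j-1) * u  (j unpaired)
        if (span > 1) O[idx(i, j - 1)] += o * u;
        // rule: Z(i,j) <- Z(i,k-1) * Zb(k,j)
        for (int k = i; k <= j - min_loop - 1; ++k) {
          if (!can_pair(code[k], code[j])) continue;
          double left = (k == i) ? 1.0 : Q[idx(i, k - 1)];
          double inner = (k + 1 > j - 1) ? 1.0 : Q[idx(k + 1, j - 1)];
          double zb = pw * inner;
          if (k > i) O[idx(i, k - 1)] += o * zb;
          Ob[idx(k, j)] += o * left;
        }
      }
      // rule: Zb(i,j) = pw * Z(i+1,j-1) -> outside mass flows into interior
      double ob = Ob[idx(i, j)];
      if (ob != 0.0 && i + 1 <= j - 1) O[idx(i + 1, j - 1)] += ob * pw;
    }
  }

  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      if (!can_pair(code[i], code[j])) continue;
      double inner = (i + 1 > j - 1) ? 1.0 : Q[idx(i + 1, j - 1)];
      double p = Ob[idx(i, j)] * pw * inner / ztot;
      if (p < 0) p = 0;
      if (p > 1) p = 1;
      P(i, j) = p;
      P(j, i) = p;
    }
  }
  return P;
}
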