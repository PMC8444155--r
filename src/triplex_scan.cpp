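#include <Rcpp.h>
using namespace Rcpp;

// Diagonal scanner for triplex matches between a TFO sequence (RNA, already
// oriented 5'->3' along the purine strand; callers reverse it for
// antiparallel motifs) and the purine strand of a DNA duplex window.
// A hit is a gap-free aligned interval satisfying minimum length, error
// rate, maximum consecutive errors, and minimum guanine rate (fraction of G
// on the purine strand), reduced to maximal intervals per diagonal: a valid
// interval strictly contained in another valid interval on the same
// alignment diagonal is dropped. 'N' (or any non-ACGT character) on either
// side always counts as an error position.

static inline bool triplet_match(int motif, char r, char d) {
  // motif: 0 = Y (T.A, C.G), 1 = R (G.G, A.A), 2 = GT (G.G, T.A)
  switch (motif) {
    case 0: return (r == 'T' && d == 'A') || (r == 'C' && d == 'G');
    case 1: return (r == 'G' && d == 'G') || (r == 'A' && d == 'A');
    case 2: return (r == 'G' && d == 'G') || (r == 'T' && d == 'A');
  }
  return false;
}

// [[Rcpp::export(name = ".triplex_scan_cpp")]]
IntegerMatrix triplex_scan_cpp(std::string tfo, std::string pur, int motif,
                               int min_len, double max_err_rate,
                               double min_g_rate, int max_consec) {
  const int nr = tfo.size(), nd = pur.size();
  std::vector<int> out;  // rows: tfo_start, pur_start, len, n_err, n_g

  if (nr >= min_len && nd >= min_len) {
    std::vector<int> E, G;  // prefix sums along one diagonal
    std::vector<int> keepA, keepB;
    for (int off = -(nd - 1); off <= nr - 1; ++off) {
      // diagonal: tfo index i = d + off for d in [d0, d1)
      int d0 = std::max(0, -off);
      int d1 = std::min(nd, nr - off);
      int L = d1 - d0;
      if (L < min_len) continue;
      E.assign(L + 1, 0);
      G.assign(L + 1, 0);
      for (int t = 0; t < L; ++t) {
        char dc = pur[d0 + t];
        char rc = tfo[d0 + t + off];
        E[t + 1] = E[t] + (triplet_match(motif, rc, dc) ? 0 : 1);
        G[t + 1] = G[t] + (dc == 'G' ? 1 : 0);
      }
      // minimal allowed start per end, from runs of > max_consec errors
      std::vector<int> cand_a, cand_b;
      int run = 0, minA = 0;
      for (int b = 0; b < L; ++b) {
        run = (E[b + 1] > E[b]) ? run + 1 : 0;
        if (run >= max_consec + 1) minA = b - max_consec + 1;
        if (b + 1 < min_len) continue;
        int amax = b - min_len + 1;
        for (int a = minA; a <= amax; ++a) {
          int len = b - a + 1;
          int ne = E[b + 1] - E[a];
          if ((double)ne > max_err_rate * len + 1e-9) continue;
          int ng = G[b + 1] - G[a];
          if ((double)ng < min_g_rate * len - 1e-9) continue;
          cand_a.push_back(a);
          cand_b.push_back(b);
        }
      }
      if (cand_a.empty()) continue;
      // maximality: sort by start asc, end desc; keep ends exceeding the max
      std::vector<int> ord(cand_a.size());
      for (size_t t = 0; t < ord.size(); ++t) ord[t] = t;
      std::sort(ord.begin(), ord.end(), [&](int x, int y) {
        if (cand_a[x] != cand_a[y]) return cand_a[x] < cand_a[y];
        return cand_b[x] > cand_b[y];
      });
      int maxB = -1;
      for (int t : ord) {
        if (cand_b[t] > maxB) {
          maxB = cand_b[t];
          int a = cand_a[t], b = cand_b[t], len = b - a + 1;
          out.push_back(d0 + a + off);          // tfo_start
          out.push_back(d0 + a);                // pur_start
          out.push_back(len);
          out.push_back(E[b + 1] - E[a]);
          out.push_back(G[b + 1] - G[a]);
        }
      }
    }
  }

  int nhit = out.size() / 5;
  IntegerMatrix res(nhit, 5);
  for (int h = 0; h < nhit; ++h)
    for (int c = 0; c < 5; ++c) res(h, c) = out[5 * h + c];
  colnames(res) = CharacterVector::create("tfo_start", "pur_start", "len",
                                          "n_err", "n_g");
  return res;
}
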