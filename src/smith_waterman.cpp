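#include <Rcpp.h>
using namespace Rcpp;

// Gotoh local alignment with affine gaps. A gap of length k costs
// gap_open + k * gap_extend (BLAST convention: the first gapped residue
// costs gap_open + gap_extend).
//
// Traceback is deterministic: when scores tie, prefer diagonal, then a gap
// in the target (vertical), then a gap in the query (horizontal). This
// favours matched columns and therefore higher identity / shorter
// alignments among equal-scoring paths.
//
// qidx/tidx are 0-based indices into the substitution matrix.
// [[Rcpp::export]]
List sw_align_cpp(IntegerVector qidx, IntegerVector tidx,
                  IntegerMatrix submat, int gap_open, int gap_extend) {
  const int m = qidx.size(), n = tidx.size();
  const int NEG = -1000000000;
  const int gi = gap_open + gap_extend; // cost of opening (first residue)

  // full DP matrices; sequences here are protein-sized so this is cheap
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);
  std::vector<int> F((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[at(i, j - 1)] - gi, E[at(i, j - 1)] - gap_extend);
      int f = std::max(H[at(i - 1, j)] - gi, F[at(i - 1, j)] - gap_extend);
      int d = H[at(i - 1, j - 1)] + submat(qidx[i - 1], tidx[j - 1]);
      int h = std::max(0, std::max(d, std::max(e, f)));
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  int align_len = 0, n_ident = 0;
  int q_end = bi, t_end = bj, q_start = bi + 1, t_start = bj + 1;
  if (best > 0) {
    int i = bi, j = bj;
    int state = 0; // 0 = H, 1 = E (horizontal), 2 = F (vertical)
    while (true) {
      if (state == 0) {
        if (H[at(i, j)] == 0) break;
        int d = H[at(i - 1, j - 1)] + submat(qidx[i - 1], tidx[j - 1]);
        if (H[at(i, j)] == d) {
          if (qidx[i - 1] == tidx[j - 1]) ++n_ident;
          ++align_len; --i; --j;
        } else if (H[at(i, j)] == F[at(i, j)]) {
          state = 2;
        } else {
          state = 1;
        }
      } else if (state == 1) { // gap in query, consume target
        ++align_len;
        if (E[at(i, j)] == H[at(i, j - 1)] - gi) { --j; state = 0; }
        else { --j; } // stay in E
      } else { // gap in target, consume query
        ++align_len;
        if (F[at(i, j)] == H[at(i - 1, j)] - gi) { --i; state = 0; }
        else { --i; }
      }
      if (i == 0 || j == 0) break;
    }
    q_start = i + 1;
    t_start = j + 1;
  } else {
    // empty-alignment convention for all-negative scoring
    q_start = 0; q_end = 0; t_start = 0; t_end = 0;
  }

  return List::create(_["score"] = best,
                      _["alignment_length"] = align_len,
                      _["n_identical"] = n_ident,
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["t_start"] = t_start, _["t_end"] = t_end);
}
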