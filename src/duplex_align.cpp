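// Local complementarity alignment of a lncRNA against a reversed target
// sequence: full Smith-Waterman with affine gap costs (a gap of length k
// costs gap_open + k * gap_extend, both passed as positive costs) and
// Waterman-Eggert style enumeration of suboptimal alignments by masking
// the matched cells of each reported path and recomputing.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <climits>

using namespace Rcpp;

static const int NEG = INT_MIN / 4;

static inline int base_index(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    case 'N': case 'n': return 4;
    default: return -1;
  }
}

// [[Rcpp::export]]
List duplex_align_core(std::string query, std::string target_rev,
                       IntegerMatrix submat, int gap_open, int gap_extend,
                       int min_score, int max_hits) {
  const int n = (int) query.size();
  const int m = (int) target_rev.size();
  List hits;
  if (n == 0 || m == 0) return hits;
  if (min_score < 1) min_score = 1;  // guarantees termination of masking

  std::vector<int> q(n), t(m);
  for (int i = 0; i < n; ++i) {
    q[i] = base_index(query[i]);
    if (q[i] < 0) stop("non-nucleotide symbol '%c' in query", query[i]);
  }
  for (int j = 0; j < m; ++j) {
    t[j] = base_index(target_rev[j]);
    if (t[j] < 0) stop("non-nucleotide symbol '%c' in target", target_rev[j]);
  }

  const int go = gap_open, ge = gap_extend;
  std::vector<char> blocked((size_t) n * m, 0);
  // DP matrices, (n+1) x (m+1), row-major
  std::vector<int> H((size_t) (n + 1) * (m + 1));
  std::vector<int> E((size_t) (n + 1) * (m + 1));
  std::vector<int> F((size_t) (n + 1) * (m + 1));
  const size_t W = (size_t) m + 1;

  while ((int) hits.size() < max_hits) {
    // ---- fill ----
    for (size_t j = 0; j <= (size_t) m; ++j) { H[j] = 0; E[j] = NEG; F[j] = NEG; }
    int best = 0, bi = 0, bj = 0;
    for (int i = 1; i <= n; ++i) {
      H[i * W] = 0; E[i * W] = NEG; F[i * W] = NEG;
      for (int j = 1; j <= m; ++j) {
        const size_t c = i * W + j;
        int e = std::max(H[c - 1] - go - ge, E[c - 1] - ge);
        int f = std::max(H[c - W] - go - ge, F[c - W] - ge);
        int d = NEG;
        if (!blocked[(size_t) (i - 1) * m + (j - 1)])
          d = H[c - W - 1] + submat(q[i - 1], t[j - 1]);
        int h = std::max(std::max(0, d), std::max(e, f));
        E[c] = e; F[c] = f; H[c] = h;
        if (h > best) { best = h; bi = i; bj = j; }
      }
    }
    if (best < min_score) break;

    // ---- traceback (priority: diagonal > gap-in-target > gap-in-lnc) ----
    int i = bi, j = bj;
    char state = 'H';
    std::string pairing, q_aln, t_aln;
    std::vector<std::pair<int, int> > diag_cells;
    while (true) {
      const size_t c = (size_t) i * W + j;
      if (state == 'H') {
        const int h = H[c];
        if (h == 0) break;
        int d = NEG;
        if (i >= 1 && j >= 1 && !blocked[(size_t) (i - 1) * m + (j - 1)])
          d = H[c - W - 1] + submat(q[i - 1], t[j - 1]);
        if (d == h) {
          int a = q[i - 1], b = t[j - 1];
          char col = '.';
          bool wc = (a == 2 && b == 1) || (a == 1 && b == 2) ||
                    (a == 0 && b == 3) || (a == 3 && b == 0);
          bool wobble = (a == 2 && b == 3) || (a == 3 && b == 2);
          if (wc) col = '|'; else if (wobble) col = ':';
          pairing.push_back(col);
          q_aln.push_back(query[i - 1]);
          t_aln.push_back(target_rev[j - 1]);
          diag_cells.push_back(std::make_pair(i - 1, j - 1));
          --i; --j;
        } else if (F[c] == h) {
          state = 'F';
        } else if (E[c] == h) {
          state = 'E';
        } else {
          stop("internal error: traceback failed");  // should not happen
        }
      } else if (state == 'F') {  // gap in target, consumes query base i
        pairing.push_back('-');
        q_aln.push_back(query[i - 1]);
        t_aln.push_back('-');
        const int f = F[c];
        if (H[c - W] - go - ge == f) { state = 'H'; }
        else { state = 'F'; }
        --i;
      } else {  // state == 'E': gap in lnc, consumes target base j
        pairing.push_back('-');
        q_aln.push_back('-');
        t_aln.push_back(target_rev[j - 1]);
        const int e = E[c];
        if (H[c - 1] - go - ge == e) { state = 'H'; }
        else { state = 'E'; }
        --j;
      }
    }
    std::reverse(pairing.begin(), pairing.end());
    std::reverse(q_aln.begin(), q_aln.end());
    std::reverse(t_aln.begin(), t_aln.end());

    hits.push_back(List::create(
      _["score"] = best,
      _["q_start"] = i, _["q_end"] = bi,      // 0-based half-open on query
      _["r_start"] = j, _["r_end"] = bj,      // 0-based half-open on reversed target
      _["pairing"] = pairing,
      _["q_aln"] = q_aln, _["t_aln"] = t_aln
    ));

    if (diag_cells.empty()) break;  // safety: nothing left to mask
    for (size_t k = 0; k < diag_cells.size(); ++k) {
      blocked[(size_t) diag_cells[k].first * m + diag_cells[k].second] = 1;
    }
  }
  return hits;
}
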