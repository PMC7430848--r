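#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <climits>
using namespace Rcpp;

// Low-column banded global-in-read alignment.
//
// Rows u = 0..n index read prefixes, band columns v = 0..2b; the cell (u, v)
// corresponds to genome column c = v + sci(u), i.e. the score of aligning the
// first u read bases to the first c genome bases. sci(u) = max(floor(slope*u
// - b), 0) is the starting column index of row u, so storage is (n+1) x
// (2b+1) regardless of genome length. Row 0 is gap-penalized (the alignment
// is pinned to the anchor at (0,0)); the final score is the maximum over the
// deepest reachable row's valid cells (genome suffix beyond the traceback
// end is free). If the band runs off the genome end before row n (boundary-
// clipped segment), the remaining read bases are reported in `read_clipped`.
//
// Tie-breaking: diagonal, then up (read-consuming I), then left (D); the
// final cell tie prefers the smallest genome column.

static const int NEG = INT_MIN / 4;

static inline int sci_of(int u, int b, double slope) {
  double l = slope * static_cast<double>(u) - static_cast<double>(b);
  int f = static_cast<int>(std::floor(l));
  return f > 0 ? f : 0;
}

// [[Rcpp::export(name = ".cpp_banded_align")]]
List cpp_banded_align(std::string r, std::string g, int b, double slope,
                      int match, int mismatch, int gap,
                      bool return_matrix = false) {
  const int n = static_cast<int>(r.size());
  const int m = static_cast<int>(g.size());
  if (b < 1) stop("bandwidth b must be >= 1");
  const int W = 2 * b + 1;

  if (n == 0 || m == 0) {
    return List::create(
      _["score"] = 0, _["op_lengths"] = IntegerVector(0),
      _["op_chars"] = CharacterVector(0), _["genome_consumed"] = 0,
      _["read_clipped"] = n, _["edge_touch"] = false);
  }

  // deepest row whose band still intersects the genome
  int last_u = n;
  while (last_u > 0 && sci_of(last_u, b, slope) > m) --last_u;

  std::vector<int> F(static_cast<size_t>(last_u + 1) * W, NEG);
  std::vector<signed char> TB(static_cast<size_t>(last_u + 1) * W, 0);
  // TB codes: 0 invalid, 1 diag, 2 up, 3 left, 4 origin
  std::vector<int> sci(last_u + 1);
  for (int u = 0; u <= last_u; ++u) sci[u] = sci_of(u, b, slope);

  for (int v = 0; v < W && v <= m; ++v) {       // row 0: sci(0) == 0
    F[v] = -gap * v;
    TB[v] = (v == 0) ? 4 : 3;
  }

  for (int u = 1; u <= last_u; ++u) {
    const int s = sci[u], sp = sci[u - 1], shift = s - sp;
    int *Fc = &F[static_cast<size_t>(u) * W];
    const int *Fp = &F[static_cast<size_t>(u - 1) * W];
    signed char *Tc = &TB[static_cast<size_t>(u) * W];
    const char rb = r[u - 1];
    for (int v = 0; v < W; ++v) {
      const int c = v + s;
      if (c > m) break;
      int best = NEG;
      signed char mv = 0;
      const int vd = v + shift - 1;             // (u-1, c-1)
      if (c >= 1 && vd >= 0 && vd < W && Fp[vd] > NEG) {
        const char gb = g[c - 1];
        const int sc = (rb == gb && rb != 'N') ? match : mismatch;
        best = Fp[vd] + sc;
        mv = 1;
      }
      const int vu = v + shift;                 // (u-1, c)
      if (vu >= 0 && vu < W && Fp[vu] > NEG) {
        const int cand = Fp[vu] - gap;
        if (cand > best) { best = cand; mv = 2; }
      }
      if (v >= 1 && Fc[v - 1] > NEG) {          // (u, c-1)
        const int cand = Fc[v - 1] - gap;
        if (cand > best) { best = cand; mv = 3; }
      }
      if (mv != 0) { Fc[v] = best; Tc[v] = mv; }
    }
  }

  // best cell in the deepest reachable row, smallest genome column on ties
  const int s_last = sci[last_u];
  int best_v = -1, best_score = NEG;
  for (int v = 0; v < W; ++v) {
    if (v + s_last > m) break;
    const int sc = F[static_cast<size_t>(last_u) * W + v];
    if (sc > best_score) { best_score = sc; best_v = v; }
  }
  if (best_v < 0) {
    // no reachable cell at all (degenerate band); clip everything
    return List::create(
      _["score"] = 0, _["op_lengths"] = IntegerVector(0),
      _["op_chars"] = CharacterVector(0), _["genome_consumed"] = 0,
      _["read_clipped"] = n, _["edge_touch"] = false);
  }

  // traceback
  std::vector<char> path;
  path.reserve(n + m);
  bool edge_touch = false;
  int u = last_u, v = best_v;
  while (true) {
    const signed char mv = TB[static_cast<size_t>(u) * W + v];
    if (mv == 4) break;
    if ((v == 0 && sci[u] > 0) || v == W - 1) edge_touch = true;
    if (mv == 1) {
      path.push_back('M');
      const int shift = sci[u] - sci[u - 1];
      v = v + shift - 1; --u;
    } else if (mv == 2) {
      path.push_back('I');
      const int shift = sci[u] - sci[u - 1];
      v = v + shift; --u;
    } else if (mv == 3) {
      path.push_back('D');
      v = v - 1;
    } else {
      stop("internal: traceback reached an invalid cell");
    }
  }

  // run-length encode the reversed path
  std::vector<int> lens;
  std::vector<char> ops;
  for (int i = static_cast<int>(path.size()) - 1; i >= 0; --i) {
    const char op = path[i];
    if (!ops.empty() && ops.back() == op) ++lens.back();
    else { ops.push_back(op); lens.push_back(1); }
  }
  CharacterVector op_chars(ops.size());
  for (size_t i = 0; i < ops.size(); ++i) op_chars[i] = std::string(1, ops[i]);

  List out = List::create(
    _["score"] = best_score,
    _["op_lengths"] = IntegerVector(lens.begin(), lens.end()),
    _["op_chars"] = op_chars,
    _["genome_consumed"] = best_v + s_last,
    _["read_clipped"] = n - last_u,
    _["edge_touch"] = edge_touch);

  if (return_matrix) {
    IntegerMatrix FM(last_u + 1, W);
    for (int uu = 0; uu <= last_u; ++uu)
      for (int vv = 0; vv < W; ++vv) {
        const int val = F[static_cast<size_t>(uu) * W + vv];
        FM(uu, vv) = (val <= NEG) ? NA_INTEGER : val;
      }
    out["matrix"] = FM;
    out["sci"] = IntegerVector(sci.begin(), sci.end());
  }
  return out;
}
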