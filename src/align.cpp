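#include <Rcpp.h>
#include <climits>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment core.
//
// All scores are kept in doubled integer units so that a half-integer gap
// extension (0.5 in user units) stays exact: callers pass open2 = 2*gap_open,
// ext2 = 2*gap_extend and a substitution matrix already multiplied by 2.
// A gap of length L costs open2 + (L-1)*ext2.
//
// Alignment types: 0 = global with penalized end gaps, 1 = global with free
// end gaps (needle-style semi-global), 2 = local (Smith-Waterman).
//
// Traceback tie-breaking is fixed (diagonal over up over left, and "close the
// gap" before "extend" before "switch gap") so output is deterministic.

static const int NEG = INT_MIN / 4;

static inline int max3i(int a, int b, int c) {
  return std::max(a, std::max(b, c));
}

struct AlnResult {
  int score2;
  std::vector<int> ops;  // 0 = diagonal, 1 = up (consume a), 2 = left (consume b)
  int a_begin, a_end, b_begin, b_end;  // 1-based inclusive; 0 when empty
};

// ---------------------------------------------------------------------------
// global / semi-global
static AlnResult align_global(const std::vector<int>& a, const std::vector<int>& b,
                              const std::vector<int>& S, int na, bool free_end,
                              int open2, int ext2, bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  const int w = m + 1;
  std::vector<int> M((n + 1) * w, NEG), GA((n + 1) * w, NEG), GB((n + 1) * w, NEG);
  M[0] = 0;
  for (int i = 1; i <= n; ++i)
    GA[i * w] = free_end ? 0 : -(open2 + (i - 1) * ext2);
  for (int j = 1; j <= m; ++j)
    GB[j] = free_end ? 0 : -(open2 + (j - 1) * ext2);

  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] * na;
    for (int j = 1; j <= m; ++j) {
      const int p = i * w + j, pd = p - w - 1, pu = p - w, pl = p - 1;
      M[p] = max3i(M[pd], GA[pd], GB[pd]) + S[ai + b[j - 1]];
      GA[p] = max3i(M[pu] - open2, GA[pu] - ext2, GB[pu] - open2);
      GB[p] = max3i(M[pl] - open2, GB[pl] - ext2, GA[pl] - open2);
    }
  }

  int bi = n, bj = m;
  int best = max3i(M[n * w + m], GA[n * w + m], GB[n * w + m]);
  if (free_end) {
    for (int i = 0; i < n; ++i) {
      int v = max3i(M[i * w + m], GA[i * w + m], GB[i * w + m]);
      if (v > best) { best = v; bi = i; bj = m; }
    }
    for (int j = 0; j < m; ++j) {
      int v = max3i(M[n * w + j], GA[n * w + j], GB[n * w + j]);
      if (v > best) { best = v; bi = n; bj = j; }
    }
  }

  AlnResult res;
  res.score2 = best;
  res.a_begin = n > 0 ? 1 : 0; res.a_end = n;
  res.b_begin = m > 0 ? 1 : 0; res.b_end = m;
  if (!traceback) return res;

  std::vector<int>& rev = res.ops;
  for (int k = n; k > bi; --k) rev.push_back(1);  // trailing free end gaps
  for (int k = m; k > bj; --k) rev.push_back(2);

  int i = bi, j = bj;
  int p = i * w + j;
  int state;  // 0 = M, 1 = GA (up), 2 = GB (left)
  if (M[p] == best) state = 0;
  else if (GA[p] == best) state = 1;
  else state = 2;

  while (i > 0 || j > 0) {
    if (i == 0) { rev.push_back(2); --j; continue; }
    if (j == 0) { rev.push_back(1); --i; continue; }
    p = i * w + j;
    if (state == 0) {
      rev.push_back(0);
      const int target = M[p] - S[a[i - 1] * na + b[j - 1]];
      --i; --j; p = i * w + j;
      if (M[p] == target) state = 0;
      else if (GA[p] == target) state = 1;
      else state = 2;
    } else if (state == 1) {
      rev.push_back(1);
      const int v = GA[p], pu = p - w;
      if (M[pu] - open2 == v) state = 0;
      else if (GA[pu] - ext2 == v) state = 1;
      else state = 2;
      --i;
    } else {
      rev.push_back(2);
      const int v = GB[p], pl = p - 1;
      if (M[pl] - open2 == v) state = 0;
      else if (GB[pl] - ext2 == v) state = 2;
      else state = 1;
      --j;
    }
  }
  std::reverse(rev.begin(), rev.end());
  return res;
}

// ---------------------------------------------------------------------------
// local (Gotoh Smith-Waterman)
static AlnResult align_local(const std::vector<int>& a, const std::vector<int>& b,
                             const std::vector<int>& S, int na,
                             int open2, int ext2, bool traceback) {
  const int n = (int)a.size(), m = (int)b.size();
  const int w = m + 1;
  std::vector<int> H((n + 1) * w, 0), E((n + 1) * w, NEG), F((n + 1) * w, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int ai = a[i - 1] * na;
    for (int j = 1; j <= m; ++j) {
      const int p = i * w + j, pu = p - w, pl = p - 1;
      E[p] = std::max(H[pl] - open2, E[pl] - ext2);
      F[p] = std::max(H[pu] - open2, F[pu] - ext2);
      int h = max3i(H[pu - 1] + S[ai + b[j - 1]], E[p], F[p]);
      if (h < 0) h = 0;
      H[p] = h;
      if (h > best) { best = h; bi = i; bj = j; }  // first maximum in row-major order
    }
  }

  AlnResult res;
  res.score2 = best;
  if (best == 0 || !traceback) {
    res.a_begin = res.a_end = res.b_begin = res.b_end = 0;
    if (best > 0) { res.a_end = bi; res.b_end = bj; res.a_begin = -1; res.b_begin = -1; }
    return res;
  }

  std::vector<int>& rev = res.ops;
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = F (up), 2 = E (left)
  while (true) {
    const int p = i * w + j;
    if (state == 0) {
      if (H[p] == 0) break;
      if (i > 0 && j > 0 && H[p] == H[p - w - 1] + S[a[i - 1] * na + b[j - 1]]) {
        rev.push_back(0); --i; --j;
      } else if (H[p] == F[p]) state = 1;
      else state = 2;
    } else if (state == 1) {
      rev.push_back(1);
      if (H[p - w] - open2 == F[p]) state = 0;
      --i;
    } else {
      rev.push_back(2);
      if (H[p - 1] - open2 == E[p]) state = 0;
      --j;
    }
  }
  std::reverse(rev.begin(), rev.end());
  res.a_begin = i + 1; res.a_end = bi;
  res.b_begin = j + 1; res.b_end = bj;
  return res;
}

static std::vector<int> flatten(const IntegerMatrix& S) {
  std::vector<int> out(S.nrow() * S.ncol());
  for (int i = 0; i < S.nrow(); ++i)
    for (int j = 0; j < S.ncol(); ++j)
      out[i * S.ncol() + j] = S(i, j);
  return out;
}

static AlnResult dispatch(const std::vector<int>& a, const std::vector<int>& b,
                          const std::vector<int>& S, int na,
                          int open2, int ext2, int type, bool traceback) {
  if (type == 2) return align_local(a, b, S, na, open2, ext2, traceback);
  return align_global(a, b, S, na, type == 1, open2, ext2, traceback);
}

// [[Rcpp::export]]
List align_pair_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                    int open2, int ext2, int type) {
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<int> Sv = flatten(S);
  AlnResult r = dispatch(av, bv, Sv, S.ncol(), open2, ext2, type, true);
  return List::create(
    _["score2"] = r.score2,
    _["ops"] = IntegerVector(r.ops.begin(), r.ops.end()),
    _["a_begin"] = r.a_begin, _["a_end"] = r.a_end,
    _["b_begin"] = r.b_begin, _["b_end"] = r.b_end);
}

// Column counts for one alignment: identity, similar-only (distinct residues
// with positive substitution score), gap columns.
static void count_cols(const AlnResult& r, const std::vector<int>& a,
                       const std::vector<int>& b, const std::vector<int>& S, int na,
                       int& n_id, int& n_sim, int& n_gap) {
  n_id = 0; n_sim = 0; n_gap = 0;
  size_t ai = 0, bi = 0;
  for (size_t k = 0; k < r.ops.size(); ++k) {
    if (r.ops[k] == 0) {
      const int x = a[ai++], y = b[bi++];
      if (x == y) ++n_id;
      else if (S[x * na + y] > 0) ++n_sim;
    } else if (r.ops[k] == 1) { ++ai; ++n_gap; }
    else { ++bi; ++n_gap; }
  }
}

// All-vs-all fragment alignment: one row per (a fragment, b fragment) pair
// with columns a_idx, b_idx (0-based positions in the input lists), columns,
// n_identity, n_similar_only, n_gap_columns, score2.
// [[Rcpp::export]]
IntegerMatrix fragment_stats_cpp(List a_frags, List b_frags, IntegerMatrix S,
                                 int open2, int ext2, int type) {
  const int la = a_frags.size(), lb = b_frags.size();
  std::vector<int> Sv = flatten(S);
  const int na = S.ncol();
  std::vector<std::vector<int> > av(la), bv(lb);
  for (int i = 0; i < la; ++i) {
    IntegerVector v = a_frags[i];
    av[i].assign(v.begin(), v.end());
  }
  for (int j = 0; j < lb; ++j) {
    IntegerVector v = b_frags[j];
    bv[j].assign(v.begin(), v.end());
  }
  IntegerMatrix out(la * lb, 7);
  int row = 0;
  for (int i = 0; i < la; ++i) {
    for (int j = 0; j < lb; ++j, ++row) {
      AlnResult r = dispatch(av[i], bv[j], Sv, na, open2, ext2, type, true);
      int n_id, n_sim, n_gap;
      count_cols(r, av[i], bv[j], Sv, na, n_id, n_sim, n_gap);
      out(row, 0) = i; out(row, 1) = j;
      out(row, 2) = (int)r.ops.size();
      out(row, 3) = n_id; out(row, 4) = n_sim; out(row, 5) = n_gap;
      out(row, 6) = r.score2;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Score-only Smith-Waterman (two-row), used for shuffle nulls.
// [[Rcpp::export]]
int local_score_cpp(IntegerVector a, IntegerVector b, IntegerMatrix S,
                    int open2, int ext2) {
  const int n = a.size(), m = b.size();
  std::vector<int> Sv = flatten(S);
  const int na = S.ncol();
  std::vector<int> Hp(m + 1, 0), H(m + 1, 0), Ep(m + 1, NEG), E(m + 1, NEG);
  std::vector<int> Fp(m + 1, NEG), F(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    H[0] = 0; E[0] = NEG; F[0] = NEG;
    const int ai = a[i - 1] * na;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(H[j - 1] - open2, E[j - 1] - ext2);
      F[j] = std::max(Hp[j] - open2, Fp[j] - ext2);
      int h = max3i(Hp[j - 1] + Sv[ai + b[j - 1]], E[j], F[j]);
      if (h < 0) h = 0;
      H[j] = h;
      if (h > best) best = h;
    }
    std::swap(H, Hp); std::swap(E, Ep); std::swap(F, Fp);
  }
  return best;
}
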