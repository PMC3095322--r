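// Antisense duplex search kernels.
//
// Both kernels work in "scan space": the caller passes the miRNA 5'->3'
// (RNA alphabet) and a target-derived string S such that walking S left to
// right visits the bases that pair with miRNA positions 1..L in order
// (S = reverse(plus strand) for plus-strand sites, S = complement(plus
// strand) for minus-strand sites; coordinate mapping is done in R).
//
// An alignment is an operation string over {P, D, I}:
//   P  consume one miRNA base and one target base (pair column)
//   D  consume one miRNA base against a gap (deletion in target)
//   I  consume one target base against a gap (insertion in target)
// constrained to at most `band` indel columns in total and never starting
// with I (a leading insertion merely shifts the anchor). Gap costs are
// affine: `gap_open` for the first column of a run, `gap_extend` after,
// with D and I runs opened separately.
//
// Canonical alignment per anchor: maximum DP score, ties resolved to the
// lexicographically smallest operation string under P < D < I. The banded
// DP realises this by greedy forward reconstruction over exact suffix
// optima; the exhaustive kernel by depth-first enumeration in P,D,I order
// keeping the first maximum. The two must agree exactly.

#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstring>
using namespace Rcpp;

static const int NEG = -1000000000;

// 2 = Watson-Crick, 1 = G:U wobble, 0 = mismatch (duplex orientation)
static inline int pair_class(char m, char t) {
  if (t == 'T') t = 'U';
  switch (m) {
  case 'A': return t == 'U' ? 2 : 0;
  case 'U': return t == 'A' ? 2 : (t == 'G' ? 1 : 0);
  case 'G': return t == 'C' ? 2 : (t == 'U' ? 1 : 0);
  case 'C': return t == 'G' ? 2 : 0;
  default:  return 0;
  }
}

struct Params {
  int pair_reward, wobble_reward, mismatch_penalty, gap_open, gap_extend;
  int band;
  double min_cov;
};

static inline int col_score(int cls, const Params &pp) {
  return cls == 2 ? pp.pair_reward : (cls == 1 ? pp.wobble_reward : pp.mismatch_penalty);
}

struct Hit {
  int anchor, tend, score, paired;
  std::string ops;
};

// ---------------------------------------------------------------- banded DP

// Suffix table B[i][o][r][s]: best score aligning miRNA[i..L] against S
// starting at target position a + (i-1) + o, with r indel columns still
// allowed, having just emitted a column of type s (0 pair/none, 1 D, 2 I).
// Indexing helpers keep the table flat.
class SuffixDP {
public:
  SuffixDP(const std::string &m, const std::string &S, const Params &pp)
    : m_(m), S_(S), pp_(pp), L_((int)m.size()), n_((int)S.size()),
      W_(2 * pp.band + 1), R_(pp.band + 1),
      tab_((L_ + 2) * W_ * R_ * 3, NEG) {}

  inline int &at(int i, int o, int r, int s) {
    return tab_[((i * W_ + (o + pp_.band)) * R_ + r) * 3 + s];
  }

  // fill for a given anchor a (1-based position in S)
  void fill(int a) {
    for (int o = -pp_.band; o <= pp_.band; ++o)
      for (int r = 0; r <= pp_.band; ++r)
        for (int s = 0; s < 3; ++s)
          at(L_ + 1, o, r, s) = 0;
    for (int i = L_; i >= 1; --i) {
      // o descending: the I transition reads (i, o+1, r-1, 2)
      for (int o = pp_.band; o >= -pp_.band; --o) {
        for (int r = 0; r <= pp_.band; ++r) {
          int p = a + (i - 1) + o;  // next target position consumed
          for (int s = 0; s < 3; ++s) {
            int best = NEG;
            if (p >= 1 && p <= n_) {  // P
              int nx = at(i + 1, o, r, 0);
              if (nx > NEG) {
                int v = col_score(pair_class(m_[i - 1], S_[p - 1]), pp_) + nx;
                if (v > best) best = v;
              }
            }
            if (r >= 1 && o - 1 >= -pp_.band) {  // D
              int nx = at(i + 1, o - 1, r - 1, 1);
              if (nx > NEG) {
                int v = (s == 1 ? pp_.gap_extend : pp_.gap_open) + nx;
                if (v > best) best = v;
              }
            }
            if (r >= 1 && o + 1 <= pp_.band && p >= 1 && p <= n_) {  // I
              int nx = at(i, o + 1, r - 1, 2);
              if (nx > NEG) {
                int v = (s == 2 ? pp_.gap_extend : pp_.gap_open) + nx;
                if (v > best) best = v;
              }
            }
            at(i, o, r, s) = best;
          }
        }
      }
    }
  }

  // greedy forward reconstruction; returns false if anchor has no valid
  // alignment. Leading I excluded by skipping I while no column emitted.
  bool reconstruct(int a, Hit &hit) {
    int total = at(1, 0, pp_.band, 0);
    if (total <= NEG / 2) return false;
    int i = 1, o = 0, r = pp_.band, s = 0, rem = total;
    std::string ops;
    ops.reserve(L_ + pp_.band);
    int paired = 0, lastp = a - 1;
    while (i <= L_) {
      int p = a + (i - 1) + o;
      bool took = false;
      if (p >= 1 && p <= n_) {  // try P first
        int nx = at(i + 1, o, r, 0);
        int cls = pair_class(m_[i - 1], S_[p - 1]);
        if (nx > NEG && col_score(cls, pp_) + nx == rem) {
          ops.push_back('P');
          if (cls >= 1) ++paired;
          lastp = p;
          rem -= col_score(cls, pp_);
          i += 1; s = 0; took = true;
        }
      }
      if (!took && r >= 1 && o - 1 >= -pp_.band) {  // D
        int nx = at(i + 1, o - 1, r - 1, 1);
        int g = (s == 1 ? pp_.gap_extend : pp_.gap_open);
        if (nx > NEG && g + nx == rem) {
          ops.push_back('D');
          rem -= g;
          i += 1; o -= 1; r -= 1; s = 1; took = true;
        }
      }
      if (!took && r >= 1 && o + 1 <= pp_.band && p >= 1 && p <= n_ &&
          !ops.empty()) {  // I (never first)
        int nx = at(i, o + 1, r - 1, 2);
        int g = (s == 2 ? pp_.gap_extend : pp_.gap_open);
        if (nx > NEG && g + nx == rem) {
          ops.push_back('I');
          lastp = p;
          rem -= g;
          o += 1; r -= 1; s = 2; took = true;
        }
      }
      if (!took) return false;  // defensive: table/trace mismatch
    }
    hit.anchor = a;
    hit.tend = lastp;
    hit.score = total;
    hit.paired = paired;
    hit.ops = ops;
    return true;
  }

private:
  const std::string m_, S_;
  Params pp_;
  int L_, n_, W_, R_;
  std::vector<int> tab_;
};

// value of the restricted start (no leading I) — must equal the table root
// except in degenerate cases where only an I-first path attains the max.
// The table's I transition at (1,0,band,0) would allow a leading insertion,
// so compute the root as max over P-first and D-first explicitly.
static int root_score(SuffixDP &dp, const std::string &m, const std::string &S,
                      const Params &pp, int a) {
  int best = NEG;
  int n = (int)S.size();
  if (a >= 1 && a <= n) {
    int nx = dp.at(2, 0, pp.band, 0);
    if (nx > NEG) {
      int v = col_score(pair_class(m[0], S[a - 1]), pp) + nx;
      if (v > best) best = v;
    }
  }
  if (pp.band >= 1) {
    int nx = dp.at(2, -1, pp.band - 1, 1);
    if (nx > NEG) {
      int v = pp.gap_open + nx;
      if (v > best) best = v;
    }
  }
  return best;
}

static List hits_to_list(const std::vector<Hit> &hits) {
  int k = (int)hits.size();
  IntegerVector anchor(k), tend(k), score(k), paired(k);
  CharacterVector ops(k);
  for (int i = 0; i < k; ++i) {
    anchor[i] = hits[i].anchor;
    tend[i] = hits[i].tend;
    score[i] = hits[i].score;
    paired[i] = hits[i].paired;
    ops[i] = hits[i].ops;
  }
  return List::create(_["anchor"] = anchor, _["tend"] = tend,
                      _["score"] = score, _["paired"] = paired,
                      _["ops"] = ops);
}

static Params make_params(List par) {
  Params pp;
  pp.pair_reward = as<int>(par["pair_reward"]);
  pp.wobble_reward = as<int>(par["wobble_reward"]);
  pp.mismatch_penalty = as<int>(par["mismatch_penalty"]);
  pp.gap_open = as<int>(par["gap_open"]);
  pp.gap_extend = as<int>(par["gap_extend"]);
  pp.band = as<int>(par["band_width"]);
  pp.min_cov = as<double>(par["min_mirna_coverage"]);
  return pp;
}

// [[Rcpp::export(name = ".scan_kernel_dp")]]
List scan_kernel_dp(std::string mirna, std::string target_scanspace, List par) {
  Params pp = make_params(par);
  const std::string &m = mirna, &S = target_scanspace;
  int L = (int)m.size(), n = (int)S.size();
  std::vector<Hit> hits;
  if (n < 1 || L < 1) return hits_to_list(hits);
  int min_paired = (int)std::ceil(pp.min_cov * L - 1e-9);
  SuffixDP dp(m, S, pp);
  // anchors where the miRNA can still fit (allowing band deletions)
  for (int a = 1; a <= n - (L - pp.band) + 1 && a <= n; ++a) {
    dp.fill(a);
    Hit h;
    // replace the root value with the I-restricted one before traceback
    int rs = root_score(dp, m, S, pp, a);
    if (rs <= NEG / 2) continue;
    dp.at(1, 0, pp.band, 0) = rs;
    if (!dp.reconstruct(a, h)) continue;
    if (h.paired < min_paired) continue;
    hits.push_back(h);
  }
  return hits_to_list(hits);
}

// ------------------------------------------------------------- exhaustive

struct DfsCtx {
  const std::string *m, *S;
  Params pp;
  int L, n, a;
  long best;
  bool have;
  std::string best_ops, cur;
};

static void dfs(DfsCtx &c, int i, int p, int r, int s, long score) {
  // optimistic bound: every remaining miRNA position pairs perfectly
  if (c.have && score + (long)c.pp.pair_reward * (c.L - i + 1) < c.best)
    return;
  if (i > c.L) {
    if (!c.have || score > c.best) {  // ties keep first found (P<D<I order)
      c.have = true;
      c.best = score;
      c.best_ops = c.cur;
    }
    return;
  }
  if (p <= c.n) {  // P
    c.cur.push_back('P');
    dfs(c, i + 1, p + 1, r, 0,
        score + col_score(pair_class((*c.m)[i - 1], (*c.S)[p - 1]), c.pp));
    c.cur.pop_back();
  }
  if (r > 0) {  // D
    c.cur.push_back('D');
    dfs(c, i + 1, p, r - 1, 1,
        score + (s == 1 ? c.pp.gap_extend : c.pp.gap_open));
    c.cur.pop_back();
  }
  if (r > 0 && p <= c.n && !c.cur.empty()) {  // I, never first
    c.cur.push_back('I');
    dfs(c, i, p + 1, r - 1, 2,
        score + (s == 2 ? c.pp.gap_extend : c.pp.gap_open));
    c.cur.pop_back();
  }
}

// [[Rcpp::export(name = ".scan_kernel_exhaustive")]]
List scan_kernel_exhaustive(std::string mirna, std::string target_scanspace,
                            List par) {
  Params pp = make_params(par);
  const std::string &m = mirna, &S = target_scanspace;
  int L = (int)m.size(), n = (int)S.size();
  std::vector<Hit> hits;
  int min_paired = (int)std::ceil(pp.min_cov * L - 1e-9);
  for (int a = 1; a <= n - (L - pp.band) + 1 && a <= n; ++a) {
    DfsCtx c;
    c.m = &m; c.S = &S; c.pp = pp; c.L = L; c.n = n; c.a = a;
    c.best = NEG; c.have = false;
    c.cur.reserve(L + pp.band);
    dfs(c, 1, a, pp.band, 0, 0);
    if (!c.have) continue;
    Hit h;
    h.anchor = a;
    h.score = (int)c.best;
    h.ops = c.best_ops;
    h.paired = 0;
    int i = 1, q = a, lastp = a - 1;
    for (char op : h.ops) {
      if (op == 'P') {
        if (pair_class(m[i - 1], S[q - 1]) >= 1) ++h.paired;
        ++i; lastp = q; ++q;
      } else if (op == 'D') {
        ++i;
      } else {
        lastp = q; ++q;
      }
    }
    h.tend = lastp;
    if (h.paired < min_paired) continue;
    hits.push_back(h);
  }
  return hits_to_list(hits);
}
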