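#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Bases are encoded 0=A, 1=C, 2=G, 3=U. Watson-Crick pairs sum to 3
// (A+U, C+G); the G:U wobble pairs sum to 5. Everything else mismatches.
static inline int pair_score(int m, int u, int wc, int gu, int mm) {
  int s = m + u;
  if (s == 3) return wc;
  if (s == 5) return gu;
  return mm;
}

static const int NEG = -1000000000;

// Local (Smith-Waterman/Gotoh) alignment of the reversed miRNA against the
// UTR read 5'->3'.  Row i of the matrix is base i of the reversed miRNA
// (i.e. miRNA position m - i + 1 counted from the miRNA 5' end); weight_rev
// carries the seed multiplier per row.  Gap columns are never weighted.
// Returns one candidate site per UTR end position: the best-scoring cell in
// that column, provided it reaches `threshold`, with a full traceback.
// [[Rcpp::export]]
List cpp_scan_pair(IntegerVector mir_rev, IntegerVector utr,
                   IntegerVector weight_rev,
                   int wc, int gu, int mm,
                   int gap_open, int gap_extend, int threshold) {
  const int m = mir_rev.size(), n = utr.size();
  std::vector<int> H((m + 1) * (n + 1), 0);
  std::vector<int> E((m + 1) * (n + 1), NEG);
  std::vector<int> F((m + 1) * (n + 1), NEG);
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int e = std::max(H[at(i, j - 1)] + gap_open, E[at(i, j - 1)] + gap_extend);
      int f = std::max(H[at(i - 1, j)] + gap_open, F[at(i - 1, j)] + gap_extend);
      int s = pair_score(mir_rev[i - 1], utr[j - 1], wc, gu, mm) * weight_rev[i - 1];
      int h = H[at(i - 1, j - 1)] + s;
      h = std::max(std::max(h, e), std::max(f, 0));
      E[at(i, j)] = e;
      F[at(i, j)] = f;
      H[at(i, j)] = h;
    }
  }

  std::vector<int> score_v, start_v, end_v, mstart_v, mend_v,
      nwc_v, ngu_v, ngap_v;
  std::vector<std::string> maln_v, ualn_v;
  const char BASE[] = "ACGU";

  for (int j = 1; j <= n; ++j) {
    int bi = 0, bs = threshold - 1;
    for (int i = 1; i <= m; ++i)
      if (H[at(i, j)] > bs) { bs = H[at(i, j)]; bi = i; }
    if (bi == 0) continue;

    // traceback from (bi, j), state 0 = H, 1 = E (gap in miRNA), 2 = F
    int i = bi, jj = j, state = 0, nwcs = 0, ngus = 0, ngaps = 0;
    std::string am, au;  // collected end-to-start along the UTR
    while (true) {
      if (state == 0) {
        if (H[at(i, jj)] == 0) break;
        int s = pair_score(mir_rev[i - 1], utr[jj - 1], wc, gu, mm) * weight_rev[i - 1];
        if (H[at(i, jj)] == H[at(i - 1, jj - 1)] + s) {
          am.push_back(BASE[mir_rev[i - 1]]);
          au.push_back(BASE[utr[jj - 1]]);
          int ps = mir_rev[i - 1] + utr[jj - 1];
          if (ps == 3) ++nwcs; else if (ps == 5) ++ngus;
          --i; --jj;
        } else if (H[at(i, jj)] == E[at(i, jj)]) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        am.push_back('-');
        au.push_back(BASE[utr[jj - 1]]);
        ++ngaps;
        if (E[at(i, jj)] == H[at(i, jj - 1)] + gap_open) state = 0;
        --jj;
      } else {
        am.push_back(BASE[mir_rev[i - 1]]);
        au.push_back('-');
        ++ngaps;
        if (F[at(i, jj)] == H[at(i - 1, jj)] + gap_open) state = 0;
        --i;
      }
    }
    // Because columns were collected walking back along the UTR, the stored
    // strings read miRNA 5'->3' against UTR 3'->5' -- the reporting
    // orientation used by score_alignment().
    score_v.push_back(bs);
    start_v.push_back(jj + 1);
    end_v.push_back(j);
    // rows i+1..bi of the reversed miRNA were consumed; row r is miRNA
    // position m - r + 1, so the 5'-most aligned position is m - bi + 1
    mstart_v.push_back(m - bi + 1);
    mend_v.push_back(m - i);
    nwc_v.push_back(nwcs);
    ngu_v.push_back(ngus);
    ngap_v.push_back(ngaps);
    maln_v.push_back(am);
    ualn_v.push_back(au);
  }

  return List::create(
    _["score"] = wrap(score_v), _["utr_start"] = wrap(start_v),
    _["utr_end"] = wrap(end_v), _["mirna_start"] = wrap(mstart_v),
    _["mirna_end"] = wrap(mend_v), _["n_wc"] = wrap(nwc_v),
    _["n_gu"] = wrap(ngu_v), _["n_gaps"] = wrap(ngap_v),
    _["mirna_aln"] = wrap(maln_v), _["utr_aln"] = wrap(ualn_v));
}

struct EnumCtx {
  const int *mir, *utr, *w;
  int m, n, wc, gu, mm, go, ge, max_gaps;
  std::vector<int> best;  // best score per UTR end position (1-based)
};

// last: 0 after a pair column, 1 in a miRNA-side gap, 2 in a UTR-side gap
static void enum_rec(EnumCtx &c, int i, int j, int score, int gaps, int last) {
  if (i < c.m && j < c.n) {
    int s = score + pair_score(c.mir[i], c.utr[j], c.wc, c.gu, c.mm) * c.w[i];
    if (s > c.best[j + 1]) c.best[j + 1] = s;
    enum_rec(c, i + 1, j + 1, s, gaps, 0);
  }
  if (gaps < c.max_gaps) {
    if (j < c.n)
      enum_rec(c, i, j + 1, score + (last == 1 ? c.ge : c.go), gaps + 1, 1);
    if (i < c.m)
      enum_rec(c, i + 1, j, score + (last == 2 ? c.ge : c.go), gaps + 1, 2);
  }
}

// Exhaustive enumeration of local alignments with at most `max_gaps` gap
// columns; alignments start and end on a pair column (gap columns at either
// end only lower the score, so maxima are unaffected).  Returns the best
// score per UTR end position (NA where no alignment ends).
// [[Rcpp::export]]
IntegerVector cpp_enum_best(IntegerVector mir_rev, IntegerVector utr,
                            IntegerVector weight_rev,
                            int wc, int gu, int mm,
                            int gap_open, int gap_extend, int max_gaps) {
  EnumCtx c;
  c.mir = mir_rev.begin(); c.utr = utr.begin(); c.w = weight_rev.begin();
  c.m = mir_rev.size(); c.n = utr.size();
  c.wc = wc; c.gu = gu; c.mm = mm; c.go = gap_open; c.ge = gap_extend;
  c.max_gaps = max_gaps;
  c.best.assign(c.n + 1, NEG);
  for (int i0 = 0; i0 < c.m; ++i0)
    for (int j0 = 0; j0 < c.n; ++j0) {
      int s = pair_score(c.mir[i0], c.utr[j0], c.wc, c.gu, c.mm) * c.w[i0];
      if (s > c.best[j0 + 1]) c.best[j0 + 1] = s;
      enum_rec(c, i0 + 1, j0 + 1, s, 0, 0);
    }
  IntegerVector out(c.n);
  for (int j = 1; j <= c.n; ++j)
    out[j - 1] = (c.best[j] <= NEG / 2) ? NA_INTEGER : c.best[j];
  return out;
}
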