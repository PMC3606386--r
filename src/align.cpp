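// Seed-and-extend local similarity search and affine-gap global alignment.
//
// Sequences arrive as 0-based integer codes into the scoring matrix; the R
// layer owns alphabets, strand handling and E-value statistics.  Gap of
// length k costs open + k * extend (BLAST convention).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

namespace {

struct RawHsp {
  int qb, qe, sb, se;      // 0-based half-open
  int score;
  int nident, length, mismatch, gapopen;
};

// ---- seeding -------------------------------------------------------------

typedef std::unordered_map<uint64_t, std::vector<int> > WordIndex;

inline bool word_code(const int* s, int pos, int w, int alpha, int wild,
                      uint64_t& code) {
  uint64_t c = 0;
  for (int k = 0; k < w; ++k) {
    int r = s[pos + k];
    if (r >= wild) return false;  // wildcard (N/X) never seeds
    c = c * (uint64_t)alpha + (uint64_t)r;
  }
  code = c;
  return true;
}

void index_words(const int* s, int n, int w, int alpha, int wild,
                 WordIndex& idx) {
  uint64_t code;
  for (int j = 0; j + w <= n; ++j)
    if (word_code(s, j, w, alpha, wild, code)) idx[code].push_back(j);
}

// Enumerate all words scoring >= threshold against the query word
// (branch-and-bound over the non-wildcard alphabet).
void enum_neighbors(const int* qword, int w, int alpha,
                    const IntegerMatrix& sc, const std::vector<int>& rowmax,
                    int thresh, int depth, int partial, uint64_t code,
                    std::vector<uint64_t>& out) {
  if (depth == w) {
    if (partial >= thresh) out.push_back(code);
    return;
  }
  int rest = 0;
  for (int k = depth + 1; k < w; ++k) rest += rowmax[qword[k]];
  for (int a = 0; a < alpha; ++a) {
    int p2 = partial + sc(qword[depth], a);
    if (p2 + rest < thresh) continue;
    enum_neighbors(qword, w, alpha, sc, rowmax, thresh, depth + 1, p2,
                   code * (uint64_t)alpha + (uint64_t)a, out);
  }
}

// ---- ungapped x-drop extension ------------------------------------------

void ungapped_extend(const int* q, int m, const int* s, int n,
                     const IntegerMatrix& sc, int qi, int si, int w,
                     int xdrop, RawHsp& h) {
  // score the seed word itself
  int score = 0;
  for (int k = 0; k < w; ++k) score += sc(q[qi + k], s[si + k]);
  int best = score, bqe = qi + w, bse = si + w;
  // right
  int run = score;
  for (int i = qi + w, j = si + w; i < m && j < n; ++i, ++j) {
    run += sc(q[i], s[j]);
    if (run > best) { best = run; bqe = i + 1; bse = j + 1; }
    if (best - run > xdrop) break;
  }
  // left
  int bqb = qi, bsb = si;
  run = best;
  for (int i = qi - 1, j = si - 1; i >= 0 && j >= 0; --i, --j) {
    run += sc(q[i], s[j]);
    if (run > best) { best = run; bqb = i; bsb = j; }
    if (best - run > xdrop) break;
  }
  h.qb = bqb; h.qe = bqe; h.sb = bsb; h.se = bse; h.score = best;
}

// ---- banded local (Smith-Waterman-like) refinement ----------------------

// Local alignment within window [qlo,qhi) x [slo,shi), diagonals j - i
// restricted to [dlo, dhi] (absolute coordinates).  Returns the best local
// alignment with traceback statistics.
bool banded_local(const int* q, const int* s, const IntegerMatrix& sc,
                  int go, int ge, int qlo, int qhi, int slo, int shi,
                  int dlo, int dhi, RawHsp& out) {
  const int NEG = -1000000000;
  int L = qhi - qlo;                 // rows (query), 1..L map to qlo..qhi-1
  int W = dhi - dlo + 1;             // band width in diagonals
  if (L <= 0 || W <= 0) return false;
  // H/E/F as (L+1) x W, k = j - i - dlo where i,j are 0-based window-relative
  // offsets against absolute coordinates: i in [0,L], j = (qlo+i) + dlo + k - slo? --
  // keep absolute: for row r (=number of query chars consumed, query pos qlo+r-1),
  // the subject position consumed at band slot k is j = (qlo + r - 1) + dlo + k.
  std::vector<int> H((size_t)(L + 1) * W, NEG), E((size_t)(L + 1) * W, NEG),
      F((size_t)(L + 1) * W, NEG);
  std::vector<uint8_t> TB((size_t)(L + 1) * W, 0), TE((size_t)(L + 1) * W, 0),
      TF((size_t)(L + 1) * W, 0);
  // traceback codes in TB: 0 = local start, 1 = diag, 2 = from E, 3 = from F
  int best = 0, br = -1, bk = -1;
  for (int r = 0; r <= L; ++r) {
    for (int k = 0; k < W; ++k) {
      size_t at = (size_t)r * W + k;
      int j = (qlo + r - 1) + dlo + k;     // absolute subject index consumed
      if (r == 0) { H[at] = 0; continue; } // row 0: empty prefix, score 0
      if (j == slo - 1) { H[at] = 0; continue; } // no subject consumed yet
      if (j < slo || j >= shi) { H[at] = NEG; continue; }
      // E: gap in query (consume subject char j); predecessor (r, k-1)
      if (k > 0) {
        size_t p = (size_t)r * W + (k - 1);
        int open_e = (H[p] == NEG) ? NEG : H[p] - go - ge;
        int ext_e  = (E[p] == NEG) ? NEG : E[p] - ge;
        if (open_e >= ext_e) { E[at] = open_e; TE[at] = 0; }
        else { E[at] = ext_e; TE[at] = 1; }
      }
      // F: gap in subject (consume query char qlo+r-1); predecessor (r-1, k+1)
      if (k < W - 1) {
        size_t p = (size_t)(r - 1) * W + (k + 1);
        int open_f = (H[p] == NEG) ? NEG : H[p] - go - ge;
        int ext_f  = (F[p] == NEG) ? NEG : F[p] - ge;
        if (open_f >= ext_f) { F[at] = open_f; TF[at] = 0; }
        else { F[at] = ext_f; TF[at] = 1; }
      }
      // H: diagonal from (r-1, k)
      int h = 0; uint8_t tb = 0;
      size_t p = (size_t)(r - 1) * W + k;
      if (H[p] != NEG) {
        int d = H[p] + sc(q[qlo + r - 1], s[j]);
        if (d > h) { h = d; tb = 1; }
      }
      if (E[at] != NEG && E[at] > h) { h = E[at]; tb = 2; }
      if (F[at] != NEG && F[at] > h) { h = F[at]; tb = 3; }
      H[at] = h; TB[at] = tb;
      if (h > best) { best = h; br = r; bk = k; }
    }
  }
  if (best <= 0) return false;
  // traceback
  int r = br, k = bk;
  int qe = qlo + r;                       // half-open end
  int se = (qlo + r - 1) + dlo + k + 1;
  int nident = 0, len = 0, mism = 0, gapopen = 0;
  int state = 0;                          // 0 = in H, 1 = in E, 2 = in F
  while (true) {
    size_t at = (size_t)r * W + k;
    if (state == 0) {
      uint8_t tb = TB[at];
      if (tb == 0) break;
      if (tb == 1) {
        int j = (qlo + r - 1) + dlo + k;
        ++len;
        if (q[qlo + r - 1] == s[j]) ++nident; else ++mism;
        --r;  // k unchanged on diagonal moves
      } else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {              // E: consumed subject char, (r,k-1)
      ++len;
      uint8_t te = TE[at];
      if (te == 0) { ++gapopen; state = 0; }
      --k;
    } else {                              // F: consumed query char, (r-1,k+1)
      ++len;
      uint8_t tf = TF[at];
      if (tf == 0) { ++gapopen; state = 0; }
      --r; ++k;
    }
  }
  int qb = qlo + r;
  int sb = (qlo + r - 1) + dlo + k + 1;   // next consumed subject index
  out.qb = qb; out.qe = qe; out.sb = sb; out.se = se;
  out.score = best; out.nident = nident; out.length = len;
  out.mismatch = mism; out.gapopen = gapopen;
  return true;
}

inline bool contained(const RawHsp& a, const RawHsp& b) {
  // a inside b (both query and subject intervals)
  return a.qb >= b.qb && a.qe <= b.qe && a.sb >= b.sb && a.se <= b.se;
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_hsp_search(IntegerVector query, IntegerVector subject,
                         IntegerMatrix score_matrix, int wild_code,
                         int gap_open, int gap_extend, int word_size,
                         int seed_threshold, bool neighborhood,
                         int xdrop_ungapped, int band_pad, int min_score) {
  int m = query.size(), n = subject.size();
  std::vector<RawHsp> hsps;
  if (m >= word_size && n >= word_size) {
    const int* q = INTEGER(query);
    const int* s = INTEGER(subject);
    int alpha = wild_code;  // wildcard is the last code; seeds use 0..wild-1
    WordIndex idx;
    index_words(s, n, word_size, alpha, wild_code, idx);
    std::vector<int> rowmax(alpha + 1, 0);
    if (neighborhood) {
      for (int a = 0; a <= alpha; ++a) {
        int mx = -1000;
        for (int b = 0; b < alpha; ++b) mx = std::max(mx, score_matrix(a, b));
        rowmax[a] = mx;
      }
    }
    // per-diagonal furthest extension (query end) to skip redundant seeds
    std::unordered_map<int, int> diag_end;
    std::vector<uint64_t> codes;
    for (int i = 0; i + word_size <= m; ++i) {
      codes.clear();
      if (neighborhood) {
        bool ok = true;
        for (int k = 0; k < word_size; ++k)
          if (q[i + k] >= wild_code) { ok = false; break; }
        if (!ok) continue;
        enum_neighbors(q + i, word_size, alpha, score_matrix, rowmax,
                       seed_threshold, 0, 0, 0, codes);
      } else {
        uint64_t code;
        if (word_code(q, i, word_size, alpha, wild_code, code))
          codes.push_back(code);
      }
      for (uint64_t code : codes) {
        WordIndex::const_iterator it = idx.find(code);
        if (it == idx.end()) continue;
        for (int j : it->second) {
          int diag = j - i;
          std::unordered_map<int, int>::iterator de = diag_end.find(diag);
          if (de != diag_end.end() && i < de->second) continue;
          RawHsp ug;
          ungapped_extend(q, m, s, n, score_matrix, i, j, word_size,
                          xdrop_ungapped, ug);
          diag_end[diag] = ug.qe;
          if (ug.score < seed_threshold) continue;
          // gapped refinement in a band around the ungapped diagonal
          int qlo = std::max(0, ug.qb - band_pad);
          int qhi = std::min(m, ug.qe + band_pad);
          int slo = std::max(0, ug.sb - band_pad);
          int shi = std::min(n, ug.se + band_pad);
          RawHsp g;
          if (banded_local(q, s, score_matrix, gap_open, gap_extend, qlo, qhi,
                           slo, shi, diag - band_pad, diag + band_pad, g) &&
              g.score >= min_score)
            hsps.push_back(g);
        }
      }
    }
  }
  // drop duplicates / contained lower-scoring HSPs
  std::sort(hsps.begin(), hsps.end(), [](const RawHsp& a, const RawHsp& b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.qb != b.qb) return a.qb < b.qb;
    return a.sb < b.sb;
  });
  std::vector<RawHsp> kept;
  for (const RawHsp& h : hsps) {
    bool dup = false;
    for (const RawHsp& k : kept)
      if (contained(h, k)) { dup = true; break; }
    if (!dup) kept.push_back(h);
  }
  int nk = kept.size();
  IntegerVector qb(nk), qe(nk), sb(nk), se(nk), sc(nk), ni(nk), ln(nk),
      mi(nk), gp(nk);
  for (int i = 0; i < nk; ++i) {
    qb[i] = kept[i].qb; qe[i] = kept[i].qe; sb[i] = kept[i].sb;
    se[i] = kept[i].se; sc[i] = kept[i].score; ni[i] = kept[i].nident;
    ln[i] = kept[i].length; mi[i] = kept[i].mismatch; gp[i] = kept[i].gapopen;
  }
  return DataFrame::create(
      _["q_start"] = qb, _["q_end"] = qe, _["s_start"] = sb, _["s_end"] = se,
      _["raw_score"] = sc, _["nident"] = ni, _["align_len"] = ln,
      _["mismatch"] = mi, _["gapopen"] = gp);
}

// Global (Needleman-Wunsch) alignment with affine gaps.  Returns aligned
// index vectors (0-based positions into each input, NA at gaps).
// [[Rcpp::export]]
List cpp_global_align(IntegerVector a, IntegerVector b,
                      IntegerMatrix score_matrix, int gap_open,
                      int gap_extend) {
  const int NEG = -1000000000;
  int m = a.size(), n = b.size();
  const int* x = INTEGER(a);
  const int* y = INTEGER(b);
  size_t W = (size_t)n + 1;
  std::vector<int> H((size_t)(m + 1) * W, NEG), E((size_t)(m + 1) * W, NEG),
      F((size_t)(m + 1) * W, NEG);
  std::vector<uint8_t> TB((size_t)(m + 1) * W, 0), TE((size_t)(m + 1) * W, 0),
      TF((size_t)(m + 1) * W, 0);
  H[0] = 0;
  for (int j = 1; j <= n; ++j) {
    E[j] = -gap_open - gap_extend * j;
    TE[j] = (j > 1);
    H[j] = E[j]; TB[j] = 2;
  }
  for (int i = 1; i <= m; ++i) {
    size_t row = (size_t)i * W, prow = (size_t)(i - 1) * W;
    F[row] = -gap_open - gap_extend * i;
    TF[row] = (i > 1);
    H[row] = F[row]; TB[row] = 3;
    for (int j = 1; j <= n; ++j) {
      int open_e = H[row + j - 1] - gap_open - gap_extend;
      int ext_e = (E[row + j - 1] == NEG) ? NEG : E[row + j - 1] - gap_extend;
      if (open_e >= ext_e) { E[row + j] = open_e; TE[row + j] = 0; }
      else { E[row + j] = ext_e; TE[row + j] = 1; }
      int open_f = H[prow + j] - gap_open - gap_extend;
      int ext_f = (F[prow + j] == NEG) ? NEG : F[prow + j] - gap_extend;
      if (open_f >= ext_f) { F[row + j] = open_f; TF[row + j] = 0; }
      else { F[row + j] = ext_f; TF[row + j] = 1; }
      int d = H[prow + j - 1] + score_matrix(x[i - 1], y[j - 1]);
      int h = d; uint8_t tb = 1;
      if (E[row + j] > h) { h = E[row + j]; tb = 2; }
      if (F[row + j] > h) { h = F[row + j]; tb = 3; }
      H[row + j] = h; TB[row + j] = tb;
    }
  }
  // traceback
  std::vector<int> ia, ib;
  int i = m, j = n, state = 0;
  while (i > 0 || j > 0) {
    size_t at = (size_t)i * W + j;
    if (state == 0) {
      uint8_t tb = TB[at];
      if (tb == 1) { ia.push_back(i - 1); ib.push_back(j - 1); --i; --j; }
      else if (tb == 2) state = 1;
      else state = 2;
    } else if (state == 1) {  // gap in a, consume b[j-1]
      ia.push_back(NA_INTEGER); ib.push_back(j - 1);
      if (TE[at] == 0) state = 0;
      --j;
    } else {                  // gap in b, consume a[i-1]
      ia.push_back(i - 1); ib.push_back(NA_INTEGER);
      if (TF[at] == 0) state = 0;
      --i;
    }
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());
  int score = H[(size_t)m * W + n];
  return List::create(_["a_pos"] = wrap(ia), _["b_pos"] = wrap(ib),
                      _["score"] = score);
}
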