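// Alignment engine: exact affine-gap local DP, seeded banded heuristic, and
// semiglobal (pattern-anchored, text-free) edit-distance location.
// Coordinates in this file are 0-based half-open; R wrappers convert to
// 1-based inclusive.
#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

namespace {

const int NEG_INF = INT_MIN / 4;

// traceback codes for the M (match/mismatch) state
const uint8_t TB_STOP = 0, TB_M = 1, TB_E = 2, TB_F = 3;

struct Aln {
  bool found = false;
  int score = 0;
  int qs = 0, qe = 0, ss = 0, se = 0;
  int nm = 0, nmm = 0, nins = 0, ndel = 0;
  bool touched = false;  // traceback touched a band boundary
};

inline bool base_match(char x, char y) {
  return x == y && x != 'N';
}

// Exhaustive Gotoh local alignment with affine gaps.
// Gap of length L scores gap_open + L * gap_ext.
// M state: column consumes one char of each sequence.
// E state: gap consuming subject b only (deletion w.r.t. query a).
// F state: gap consuming query a only (insertion w.r.t. subject b).
Aln align_exact(const std::string& a, const std::string& b,
                int ma, int mi, int go, int ge) {
  const int m = (int)a.size(), n = (int)b.size();
  Aln res;
  if (m == 0 || n == 0) return res;

  std::vector<int> Mprev(n + 1, 0), Mcur(n + 1, 0);
  std::vector<int> Eprev(n + 1, NEG_INF), Ecur(n + 1, NEG_INF);
  std::vector<int> Fprev(n + 1, NEG_INF), Fcur(n + 1, NEG_INF);
  // full traceback matrices (bytes); tbE/tbF: 1 = from M, 2 = from same
  // gap state, 3 = from the other gap state
  std::vector<uint8_t> tbM((size_t)(m + 1) * (n + 1), TB_STOP);
  std::vector<uint8_t> tbE((size_t)(m + 1) * (n + 1), 1);
  std::vector<uint8_t> tbF((size_t)(m + 1) * (n + 1), 1);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Mcur[0] = 0; Ecur[0] = NEG_INF; Fcur[0] = NEG_INF;
    const size_t row = (size_t)i * (n + 1);
    for (int j = 1; j <= n; ++j) {
      // E: gap in query (consume b[j-1])
      int eM = Mcur[j - 1] + go + ge;
      int eE = Ecur[j - 1] + ge;
      int eF = Fcur[j - 1] + go + ge;
      int e = eM; uint8_t te = 1;
      if (eE > e) { e = eE; te = 2; }
      if (eF > e) { e = eF; te = 3; }
      Ecur[j] = e; tbE[row + j] = te;
      // F: gap in subject (consume a[i-1])
      int fM = Mprev[j] + go + ge;
      int fF = Fprev[j] + ge;
      int fE = Eprev[j] + go + ge;
      int f = fM; uint8_t tf = 1;
      if (fF > f) { f = fF; tf = 2; }
      if (fE > f) { f = fE; tf = 3; }
      Fcur[j] = f; tbF[row + j] = tf;
      // M: consume both
      int s = base_match(a[i - 1], b[j - 1]) ? ma : mi;
      int dM = Mprev[j - 1], dE = Eprev[j - 1], dF = Fprev[j - 1];
      int d = dM; uint8_t tm = TB_M;
      if (dE > d) { d = dE; tm = TB_E; }
      if (dF > d) { d = dF; tm = TB_F; }
      // a local alignment starts with an aligned column: a predecessor value
      // <= 0 means this cell's column is the first of the alignment
      int v;
      if (d <= 0) { v = s; tm = TB_STOP; }
      else v = d + s;
      if (v < 0) { v = 0; tm = TB_STOP; } // dead cell, never traced into
      Mcur[j] = v; tbM[row + j] = tm;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  if (best <= 0) return res;
  res.found = true; res.score = best;
  // traceback
  int i = bi, j = bj; uint8_t st = TB_M; // current state: M
  res.qe = bi; res.se = bj;
  while (true) {
    const size_t idx = (size_t)i * (n + 1) + j;
    if (st == TB_M) {
      if (base_match(a[i - 1], b[j - 1])) res.nm++; else res.nmm++;
      uint8_t pred = tbM[idx];
      if (pred == TB_STOP) { res.qs = i - 1; res.ss = j - 1; break; }
      st = pred; --i; --j;
    } else if (st == TB_E) {
      res.ndel++;
      uint8_t pred = tbE[idx];
      st = (pred == 1) ? TB_M : (pred == 2 ? TB_E : TB_F);
      --j;
    } else { // TB_F
      res.nins++;
      uint8_t pred = tbF[idx];
      st = (pred == 1) ? TB_M : (pred == 2 ? TB_F : TB_E);
      --i;
    }
  }
  return res;
}

// Banded Gotoh local alignment over diagonals d = j - i in [dlo, dhi].
Aln align_banded(const std::string& a, const std::string& b,
                 int ma, int mi, int go, int ge, int dlo, int dhi) {
  const int m = (int)a.size(), n = (int)b.size();
  Aln res;
  if (m == 0 || n == 0) return res;
  dlo = std::max(dlo, -(m - 1) - 1); // allow one guard diagonal
  dhi = std::min(dhi, n - 1 + 1);
  const int W = dhi - dlo + 1;
  if (W <= 0) return res;

  // band-local storage, index c = j - i - dlo in [0, W)
  std::vector<int> Mprev(W + 2, NEG_INF), Mcur(W + 2, NEG_INF);
  std::vector<int> Eprev(W + 2, NEG_INF), Ecur(W + 2, NEG_INF);
  std::vector<int> Fprev(W + 2, NEG_INF), Fcur(W + 2, NEG_INF);
  std::vector<uint8_t> tbM((size_t)(m + 1) * W, TB_STOP);
  std::vector<uint8_t> tbE((size_t)(m + 1) * W, 1);
  std::vector<uint8_t> tbF((size_t)(m + 1) * W, 1);

  // row 0: cells (0, j) with j in band are "empty" starts
  {
    for (int c = 0; c < W + 2; ++c) { Mprev[c] = NEG_INF; }
    for (int j = 0; j <= n; ++j) {
      int c = j - 0 - dlo;
      if (c >= 0 && c < W) Mprev[c + 1] = 0; // store with +1 offset guard
    }
  }

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    int jlo = std::max(1, i + dlo), jhi = std::min(n, i + dhi);
    std::fill(Mcur.begin(), Mcur.end(), NEG_INF);
    std::fill(Ecur.begin(), Ecur.end(), NEG_INF);
    std::fill(Fcur.begin(), Fcur.end(), NEG_INF);
    // cell (i, j=i+dlo-? ) left of band start treated as empty start when j==0
    if (i + dlo <= 0) {
      int c = 0 - i - dlo; // j = 0 column if inside band
      if (c >= 0 && c < W) Mcur[c + 1] = 0;
    }
    const size_t row = (size_t)i * W;
    for (int j = jlo; j <= jhi; ++j) {
      const int c = j - i - dlo;      // 0..W-1
      const int cc = c + 1;           // guarded index
      // predecessors: diag (i-1,j-1) -> prev row same c; E (i,j-1) -> cur row
      // c-1; F (i-1,j) -> prev row c+1
      int eM = Mcur[cc - 1], eE = Ecur[cc - 1], eF = Fcur[cc - 1];
      int e = NEG_INF; uint8_t te = 1;
      if (eM > NEG_INF / 2) { e = eM + go + ge; te = 1; }
      if (eE > NEG_INF / 2 && eE + ge > e) { e = eE + ge; te = 2; }
      if (eF > NEG_INF / 2 && eF + go + ge > e) { e = eF + go + ge; te = 3; }
      Ecur[cc] = e; tbE[row + c] = te;

      int fM = Mprev[cc + 1], fF = Fprev[cc + 1], fE = Eprev[cc + 1];
      int f = NEG_INF; uint8_t tf = 1;
      if (fM > NEG_INF / 2) { f = fM + go + ge; tf = 1; }
      if (fF > NEG_INF / 2 && fF + ge > f) { f = fF + ge; tf = 2; }
      if (fE > NEG_INF / 2 && fE + go + ge > f) { f = fE + go + ge; tf = 3; }
      Fcur[cc] = f; tbF[row + c] = tf;

      int s = base_match(a[i - 1], b[j - 1]) ? ma : mi;
      int dM = Mprev[cc], dE = Eprev[cc], dF = Fprev[cc];
      int d = dM; uint8_t tm = TB_M;
      if (dE > d) { d = dE; tm = TB_E; }
      if (dF > d) { d = dF; tm = TB_F; }
      int v;
      if (d <= 0) { v = s; tm = TB_STOP; }
      else v = d + s;
      if (v < 0) { v = 0; tm = TB_STOP; }
      Mcur[cc] = v; tbM[row + c] = tm;
      if (v > best) { best = v; bi = i; bj = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }

  if (best <= 0) return res;
  res.found = true; res.score = best;
  int i = bi, j = bj; uint8_t st = TB_M;
  res.qe = bi; res.se = bj;
  while (true) {
    const int c = j - i - dlo;
    const int dtrue_lo = std::max(dlo, -(m - 1) - 1);
    if (j - i == dtrue_lo || j - i == dhi) res.touched = true;
    const size_t idx = (size_t)i * W + c;
    if (st == TB_M) {
      if (base_match(a[i - 1], b[j - 1])) res.nm++; else res.nmm++;
      uint8_t pred = tbM[idx];
      if (pred == TB_STOP) { res.qs = i - 1; res.ss = j - 1; break; }
      st = pred; --i; --j;
    } else if (st == TB_E) {
      res.ndel++;
      uint8_t pred = tbE[idx];
      st = (pred == 1) ? TB_M : (pred == 2 ? TB_E : TB_F);
      --j;
    } else {
      res.nins++;
      uint8_t pred = tbF[idx];
      st = (pred == 1) ? TB_M : (pred == 2 ? TB_F : TB_E);
      --i;
    }
  }
  return res;
}

inline bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t v = 0;
  for (int t = 0; t < k; ++t) {
    int c;
    switch (s[t]) {
      case 'A': c = 0; break; case 'C': c = 1; break;
      case 'G': c = 2; break; case 'T': c = 3; break;
      default: return false;
    }
    v = (v << 2) | (uint64_t)c;
  }
  out = v;
  return true;
}

typedef std::unordered_map<uint64_t, std::vector<int>> KIndex;

KIndex build_index(const std::string& a, int k) {
  KIndex idx;
  const int m = (int)a.size();
  for (int i = 0; i + k <= m; ++i) {
    uint64_t v;
    if (encode_kmer(a.c_str() + i, k, v)) idx[v].push_back(i);
  }
  return idx;
}

// diagonals (j_b - i_a) of all shared k-mers between indexed a and subject b
std::vector<int> seed_diagonals(const KIndex& idx, const std::string& b, int k) {
  std::vector<int> diags;
  const int n = (int)b.size();
  for (int j = 0; j + k <= n; ++j) {
    uint64_t v;
    if (!encode_kmer(b.c_str() + j, k, v)) continue;
    KIndex::const_iterator it = idx.find(v);
    if (it == idx.end()) continue;
    for (size_t t = 0; t < it->second.size(); ++t)
      diags.push_back(j - it->second[t]);
  }
  return diags;
}

// densest window of width `width` over sorted diagonals; returns [lo, hi]
void densest_window(std::vector<int>& diags, int width, int& lo, int& hi) {
  std::sort(diags.begin(), diags.end());
  size_t bestcnt = 0, bestl = 0; size_t r = 0;
  for (size_t l = 0; l < diags.size(); ++l) {
    if (r < l) r = l;
    while (r + 1 < diags.size() && diags[r + 1] - diags[l] <= width) ++r;
    size_t cnt = r - l + 1;
    if (cnt > bestcnt) { bestcnt = cnt; bestl = l; }
  }
  lo = diags[bestl];
  size_t rr = bestl;
  while (rr + 1 < diags.size() && diags[rr + 1] - diags[bestl] <= width) ++rr;
  hi = diags[rr];
}

// seeded, banded alignment with band widening until the traceback no longer
// touches a band edge (or the band covers the whole matrix)
// seed support: at least `min_chain` seeds must cluster within one band-wide
// diagonal window (a BLAST-two-hit-style filter); pairs with weaker seed
// evidence are treated as seedless
Aln align_seeded(const std::string& a, const std::string& b,
                 const KIndex& idx,
                 int ma, int mi, int go, int ge, int k, int band,
                 int min_chain, bool& has_seeds) {
  Aln res;
  std::vector<int> diags = seed_diagonals(idx, b, k);
  has_seeds = false;
  if ((int)diags.size() < min_chain) return res;
  int wlo, whi;
  densest_window(diags, band, wlo, whi);
  int support = 0;
  for (size_t t = 0; t < diags.size(); ++t)
    if (diags[t] >= wlo && diags[t] <= whi) ++support;
  if (support < min_chain) return res;
  has_seeds = true;
  const int m = (int)a.size(), n = (int)b.size();
  int dlo = wlo - band, dhi = whi + band;
  int grow = band;
  for (int iter = 0; iter < 40; ++iter) {
    res = align_banded(a, b, ma, mi, go, ge, dlo, dhi);
    bool full = (dlo <= -(m - 1)) && (dhi >= n - 1);
    if (!res.found || !res.touched || full) break;
    dlo -= grow; dhi += grow; grow *= 2;
  }
  return res;
}

std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (size_t i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break; case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break; case 'T': r[i] = 'A'; break;
      default: r[i] = 'N';
    }
  }
  return r;
}

List aln_to_list(const Aln& r, bool fwd, int nb) {
  // convert reverse-strand subject coordinates back to the forward strand
  int ss = r.ss, se = r.se;
  if (!fwd) { ss = nb - r.se; se = nb - r.ss; }
  return List::create(
    _["found"] = r.found, _["score"] = r.score,
    _["q_start"] = r.qs, _["q_end"] = r.qe,
    _["s_start"] = ss, _["s_end"] = se,
    _["strand"] = fwd ? "+" : "-",
    _["matches"] = r.nm, _["mismatches"] = r.nmm,
    _["insertions"] = r.nins, _["deletions"] = r.ndel);
}

} // namespace

// [[Rcpp::export(name = ".cpp_align_exact")]]
List cpp_align_exact(std::string a, std::string b,
                     int match, int mismatch, int gap_open, int gap_ext,
                     bool both_strands = true) {
  Aln fw = align_exact(a, b, match, mismatch, gap_open, gap_ext);
  if (!both_strands) return aln_to_list(fw, true, (int)b.size());
  Aln rv = align_exact(a, revcomp(b), match, mismatch, gap_open, gap_ext);
  if (rv.found && (!fw.found || rv.score > fw.score))
    return aln_to_list(rv, false, (int)b.size());
  return aln_to_list(fw, true, (int)b.size());
}

// [[Rcpp::export(name = ".cpp_align_seeded")]]
List cpp_align_seeded(std::string a, std::string b,
                      int match, int mismatch, int gap_open, int gap_ext,
                      int seed_k, int band, int min_chain = 2,
                      bool both_strands = true) {
  KIndex idx = build_index(a, seed_k);
  bool sf = false, sr = false;
  Aln fw = align_seeded(a, b, idx, match, mismatch, gap_open, gap_ext,
                        seed_k, band, min_chain, sf);
  Aln best = fw; bool fwd = true;
  if (both_strands) {
    Aln rv = align_seeded(a, revcomp(b), idx, match, mismatch, gap_open,
                          gap_ext, seed_k, band, min_chain, sr);
    if (rv.found && (!best.found || rv.score > best.score)) {
      best = rv; fwd = false;
    }
  }
  List out = aln_to_list(best, fwd, (int)b.size());
  out["has_seeds"] = sf || sr;
  return out;
}

// Map one query against many subjects (both strands); returns one row per
// subject. Subjects without any shared k-mer seed are reported found = FALSE.
// If stop_score >= 0, scanning stops after a subject reaches that score
// (remaining subjects reported found = FALSE).
// [[Rcpp::export(name = ".cpp_map_one")]]
List cpp_map_one(std::string a, CharacterVector subjects,
                 int match, int mismatch, int gap_open, int gap_ext,
                 int seed_k, int band, int min_chain = 2,
                 int stop_score = -1) {
  const int ns = subjects.size();
  KIndex idx = build_index(a, seed_k);
  LogicalVector found(ns);
  IntegerVector score(ns), qs(ns), qe(ns), ss(ns), se(ns),
      nm(ns), nmm(ns), nins(ns), ndel(ns);
  CharacterVector strand(ns);
  for (int u = 0; u < ns; ++u) {
    std::string b = as<std::string>(subjects[u]);
    bool sf = false, sr = false;
    Aln fw = align_seeded(a, b, idx, match, mismatch, gap_open, gap_ext,
                          seed_k, band, min_chain, sf);
    Aln rv = align_seeded(a, revcomp(b), idx, match, mismatch, gap_open,
                          gap_ext, seed_k, band, min_chain, sr);
    Aln best = fw; bool is_fwd = true;
    if (rv.found && (!best.found || rv.score > best.score)) {
      best = rv; is_fwd = false;
    }
    found[u] = best.found;
    if (best.found) {
      int s0 = best.ss, s1 = best.se;
      if (!is_fwd) { s0 = (int)b.size() - best.se; s1 = (int)b.size() - best.ss; }
      score[u] = best.score; qs[u] = best.qs; qe[u] = best.qe;
      ss[u] = s0; se[u] = s1; strand[u] = is_fwd ? "+" : "-";
      nm[u] = best.nm; nmm[u] = best.nmm; nins[u] = best.nins; ndel[u] = best.ndel;
      if (stop_score >= 0 && best.score >= stop_score) break;
    } else {
      strand[u] = NA_STRING;
    }
  }
  return List::create(
    _["found"] = found, _["score"] = score, _["q_start"] = qs,
    _["q_end"] = qe, _["s_start"] = ss, _["s_end"] = se,
    _["strand"] = strand, _["matches"] = nm, _["mismatches"] = nmm,
    _["insertions"] = nins, _["deletions"] = ndel);
}

// Semiglobal pattern location: full pattern aligned (both ends anchored),
// text ends free, unit-cost edit distance. Returns all end positions e with
// edit distance <= max_edits, with a traced-back start for each.
// Matrix columns: start, end (0-based half-open on text), edits.
// [[Rcpp::export(name = ".cpp_edit_locate")]]
IntegerMatrix cpp_edit_locate(std::string pattern, std::string text,
                              int max_edits) {
  const int m = (int)pattern.size(), n = (int)text.size();
  std::vector<uint16_t> D((size_t)(m + 1) * (n + 1));
  for (int j = 0; j <= n; ++j) D[j] = 0;           // free start in text
  for (int i = 1; i <= m; ++i) D[(size_t)i * (n + 1)] = (uint16_t)i;
  for (int i = 1; i <= m; ++i) {
    const size_t row = (size_t)i * (n + 1), prow = row - (n + 1);
    for (int j = 1; j <= n; ++j) {
      uint16_t diag = D[prow + j - 1] +
        (base_match(pattern[i - 1], text[j - 1]) ? 0 : 1);
      uint16_t up = D[prow + j] + 1;     // consume pattern char
      uint16_t left = D[row + j - 1] + 1; // consume text char
      uint16_t v = diag;
      if (up < v) v = up;
      if (left < v) v = left;
      D[row + j] = v;
    }
  }
  std::vector<int> starts, ends, edits;
  for (int e = 1; e <= n; ++e) {
    int d = D[(size_t)m * (n + 1) + e];
    if (d > max_edits) continue;
    // traceback for start; preference: diag, up, left (deterministic)
    int i = m, j = e;
    while (i > 0 && j > 0) {
      uint16_t cur = D[(size_t)i * (n + 1) + j];
      uint16_t diag = D[(size_t)(i - 1) * (n + 1) + j - 1];
      if (cur == diag + (base_match(pattern[i - 1], text[j - 1]) ? 0 : 1)) {
        --i; --j; continue;
      }
      if (cur == D[(size_t)(i - 1) * (n + 1) + j] + 1) { --i; continue; }
      --j;
    }
    if (j >= e) continue; // zero-width span (possible only if m == 0)
    starts.push_back(j); ends.push_back(e); edits.push_back(d);
  }
  IntegerMatrix out((int)starts.size(), 3);
  for (int r = 0; r < (int)starts.size(); ++r) {
    out(r, 0) = starts[r]; out(r, 1) = ends[r]; out(r, 2) = edits[r];
  }
  colnames(out) = CharacterVector::create("start", "end", "edits");
  return out;
}

// [[Rcpp::export(name = ".cpp_revcomp")]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  out.names() = x.names();
  return out;
}
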