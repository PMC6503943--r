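#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <string>
using namespace Rcpp;

// IUPAC nucleotide bit masks: A=1, C=2, G=4, T=8; ambiguity codes are unions.
static inline int iupac_mask(char c) {
  switch (c) {
  case 'A': case 'a': return 1;
  case 'C': case 'c': return 2;
  case 'G': case 'g': return 4;
  case 'T': case 't': case 'U': case 'u': return 8;
  case 'R': case 'r': return 1 | 4;
  case 'Y': case 'y': return 2 | 8;
  case 'S': case 's': return 2 | 4;
  case 'W': case 'w': return 1 | 8;
  case 'K': case 'k': return 4 | 8;
  case 'M': case 'm': return 1 | 2;
  case 'B': case 'b': return 2 | 4 | 8;
  case 'D': case 'd': return 1 | 4 | 8;
  case 'H': case 'h': return 1 | 2 | 8;
  case 'V': case 'v': return 1 | 2 | 4;
  case 'N': case 'n': return 15;
  default: return 0;
  }
}

// Substitution cost. With iupac matching, overlapping base sets align free
// (degenerate primers); without it, only literal equality matches and 'N'
// mismatches everything, itself included.
static inline int sub_cost(char a, char b, bool iupac) {
  if (iupac) return (iupac_mask(a) & iupac_mask(b)) ? 0 : 1;
  if (a == 'N' || a == 'n' || b == 'N' || b == 'n') return 1;
  return (a == b) ? 0 : 1;
}

static int edit_distance_one(const std::string& a, const std::string& b,
                             bool iupac) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + sub_cost(ai, b[j - 1], iupac);
      int u = prev[j] + 1;
      int l = cur[j - 1] + 1;
      cur[j] = d < u ? (d < l ? d : l) : (u < l ? u : l);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector cpp_edit_distance(CharacterVector a, CharacterVector b,
                                bool iupac = false) {
  const R_xlen_t n = std::max(a.size(), b.size());
  if (a.size() != n && a.size() != 1) stop("length mismatch");
  if (b.size() != n && b.size() != 1) stop("length mismatch");
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string sa = as<std::string>(a[a.size() == 1 ? 0 : i]);
    std::string sb = as<std::string>(b[b.size() == 1 ? 0 : i]);
    out[i] = edit_distance_one(sa, sb, iupac);
  }
  return out;
}

// Semi-global (infix) search of a short pattern in a text: gaps flanking the
// pattern's span in the text are free.  Returns c(distance, start, end)
// (0-based, half-open) for the best hit, or c(-1, -1, -1) when no span is
// within max_edits.  Ties at the minimum distance break to the leftmost
// start, then the shortest span.
// [[Rcpp::export]]
IntegerVector cpp_infix_search(std::string pattern, std::string text,
                               int max_edits, bool iupac = true) {
  const int m = pattern.size(), n = text.size();
  if (m == 0) stop("pattern must be non-empty");
  std::vector<int> dprev(n + 1), dcur(n + 1), oprev(n + 1), ocur(n + 1);
  for (int j = 0; j <= n; ++j) { dprev[j] = 0; oprev[j] = j; }
  for (int i = 1; i <= m; ++i) {
    dcur[0] = i; ocur[0] = 0;
    const char pi = pattern[i - 1];
    for (int j = 1; j <= n; ++j) {
      int best = dprev[j - 1] + sub_cost(pi, text[j - 1], iupac);
      int orig = oprev[j - 1];
      int u = dprev[j] + 1;
      if (u < best || (u == best && oprev[j] < orig)) { best = u; orig = oprev[j]; }
      int l = dcur[j - 1] + 1;
      if (l < best || (l == best && ocur[j - 1] < orig)) { best = l; orig = ocur[j - 1]; }
      dcur[j] = best; ocur[j] = orig;
    }
    std::swap(dprev, dcur); std::swap(oprev, ocur);
  }
  int bd = INT_MAX, bs = -1, be = -1;
  for (int j = 0; j <= n; ++j) {
    const int d = dprev[j], s = oprev[j];
    if (d < bd || (d == bd && (s < bs || (s == bs && j - s < be - bs)))) {
      bd = d; bs = s; be = j;
    }
  }
  if (bd > max_edits) return IntegerVector::create(-1, -1, -1);
  return IntegerVector::create(bd, bs, be);
}

// Pairwise alignment of a read against a reference with unit costs.
// free_ref_ends = true gives the "glocal" mode used for consensus voting:
// the read is aligned end to end while unaligned reference flanks are
// free (read overhangs beyond the reference are charged as insertions).
// free_ref_ends = false is plain global (Needleman-Wunsch) alignment.
// Returns the aligned core as two gapped strings, 0-based half-open spans
// of the core on each sequence, and the alignment cost.
// traceback codes: 0 = diag, 1 = up (ref char vs gap), 2 = left (gap vs read char)
// [[Rcpp::export]]
List cpp_align_overlap(std::string ref, std::string read,
                       bool free_ref_ends = true, bool iupac = false) {
  const int n = ref.size(), m = read.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1));
  std::vector<int> prev(m + 1), cur(m + 1), lastcol(n + 1);
  for (int j = 0; j <= m; ++j) { prev[j] = j; tb[j] = 2; }
  lastcol[0] = prev[m];
  for (int i = 1; i <= n; ++i) {
    cur[0] = free_ref_ends ? 0 : i;
    uint8_t* tbi = &tb[(size_t)i * (m + 1)];
    tbi[0] = 1;
    const char ri = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      int d = prev[j - 1] + sub_cost(ri, read[j - 1], iupac);
      int u = prev[j] + 1;
      int l = cur[j - 1] + 1;
      if (d <= u && d <= l)      { cur[j] = d; tbi[j] = 0; }
      else if (u <= l)           { cur[j] = u; tbi[j] = 1; }
      else                       { cur[j] = l; tbi[j] = 2; }
    }
    lastcol[i] = cur[m];
    std::swap(prev, cur);
  }
  // Endpoint: global ends at the corner; glocal ends anywhere in the last
  // column (free ref suffix), preferring the corner then larger i.
  int bi = n, bj = m, bc = lastcol[n];
  if (free_ref_ends)
    for (int i = n - 1; i >= 0; --i)
      if (lastcol[i] < bc) { bc = lastcol[i]; bi = i; }
  std::string ra, ba;
  ra.reserve(n + m); ba.reserve(n + m);
  int i = bi, j = bj;
  while (i > 0 || j > 0) {
    if (i == 0) { ra.push_back('-'); ba.push_back(read[j - 1]); --j; continue; }
    if (j == 0) {
      if (free_ref_ends) break;  // free ref prefix
      ra.push_back(ref[i - 1]); ba.push_back('-'); --i; continue;
    }
    uint8_t t = tb[(size_t)i * (m + 1) + j];
    if (t == 0)      { ra.push_back(ref[i - 1]); ba.push_back(read[j - 1]); --i; --j; }
    else if (t == 1) { ra.push_back(ref[i - 1]); ba.push_back('-'); --i; }
    else             { ra.push_back('-'); ba.push_back(read[j - 1]); --j; }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(ba.begin(), ba.end());
  return List::create(
    _["ref_aln"] = ra, _["read_aln"] = ba,
    _["ref_start"] = i, _["ref_end"] = bi,
    _["read_start"] = j, _["read_end"] = bj,
    _["dist"] = bc);
}

// Minimum edit distance from one candidate to each member of a set
// (used by the index designer's violation scoring).
// [[Rcpp::export]]
IntegerVector cpp_dist_to_set(std::string x, CharacterVector set,
                              bool iupac = false) {
  IntegerVector out(set.size());
  for (R_xlen_t i = 0; i < set.size(); ++i)
    out[i] = edit_distance_one(x, as<std::string>(set[i]), iupac);
  return out;
}
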