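#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks (A=1, C=2, G=4, T=8).
static inline int iupac_mask(char c) {
  switch (toupper(c)) {
    case 'A': return 1; case 'C': return 2; case 'G': return 4;
    case 'T': case 'U': return 8;
    case 'R': return 5;  case 'Y': return 10; case 'S': return 6;
    case 'W': return 9;  case 'K': return 12; case 'M': return 3;
    case 'B': return 14; case 'D': return 13; case 'H': return 11;
    case 'V': return 7;  case 'N': return 15;
    default:  return 0;
  }
}

static inline bool unambiguous(int m) { return m == 1 || m == 2 || m == 4 || m == 8; }

// A query (read) base counts as a match only when it is unambiguous and
// contained in the reference code's set; ambiguous read bases never match.
static inline bool base_match_strict(int qm, int rm) {
  return unambiguous(qm) && (qm & rm);
}

// Primer matching: any intersection of the two code sets counts.
static inline bool base_match_iupac(int pm, int tm) { return (pm & tm) != 0; }

static std::vector<int> to_masks(const std::string& s) {
  std::vector<int> m(s.size());
  for (size_t i = 0; i < s.size(); ++i) m[i] = iupac_mask(s[i]);
  return m;
}

// Affine-gap local alignment (Gotoh) with traceback statistics.
// Returns score, matches, alignment columns, and the 1-based span of the
// alignment on the reference (for the reference-coverage rule).
// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(std::string query, std::string ref,
                  double match = 1.0, double mismatch = -2.0,
                  double gap_open = -5.0, double gap_extend = -2.0) {
  std::vector<int> q = to_masks(query), r = to_masks(ref);
  int m = q.size(), n = r.size();
  if (m == 0 || n == 0)
    return List::create(_["score"] = 0.0, _["matches"] = 0, _["columns"] = 0,
                        _["ref_start"] = 0, _["ref_end"] = 0,
                        _["query_start"] = 0, _["query_end"] = 0);
  // H, E (gap in query / horizontal), F (gap in ref / vertical)
  std::vector<double> Hprev(n + 1, 0.0), Hcur(n + 1, 0.0);
  std::vector<double> Eprev(n + 1, R_NegInf), Ecur(n + 1, R_NegInf);
  std::vector<double> Fcur(n + 1, R_NegInf), Fprev(n + 1, R_NegInf);
  // traceback: 0 stop, 1 diag, 2 from E (left), 3 from F (up)
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0);
  std::vector<unsigned char> tbE((m + 1) * (n + 1), 0); // 1: opened, 0: extended
  std::vector<unsigned char> tbF((m + 1) * (n + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0.0; Ecur[0] = R_NegInf;
    for (int j = 1; j <= n; ++j) {
      size_t k = (size_t)i * (n + 1) + j;
      double eo = Hcur[j - 1] + gap_open, ee = Ecur[j - 1] + gap_extend;
      Ecur[j] = (eo >= ee) ? eo : ee;
      tbE[k] = (eo >= ee) ? 1 : 0;
      double fo = Hprev[j] + gap_open, fe = Fprev[j] + gap_extend;
      Fcur[j] = (fo >= fe) ? fo : fe;
      tbF[k] = (fo >= fe) ? 1 : 0;
      double s = base_match_strict(q[i - 1], r[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double h = 0.0; unsigned char tb = 0;
      if (diag > h) { h = diag; tb = 1; }
      if (Ecur[j] > h) { h = Ecur[j]; tb = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; tb = 3; }
      Hcur[j] = h; tbH[k] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  // traceback from (bi, bj)
  int i = bi, j = bj, matches = 0, cols = 0;
  int ref_end = bj, ref_start = bj + 1, q_end = bi, q_start = bi + 1;
  int state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    size_t k = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[k];
      if (tb == 0) break;
      if (tb == 1) {
        ++cols;
        if (base_match_strict(q[i - 1], r[j - 1])) ++matches;
        q_start = i; ref_start = j; --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // gap in query: consume ref base
      ++cols; ref_start = j;
      if (tbE[k]) state = 0;
      --j;
    } else { // gap in ref: consume query base
      ++cols; q_start = i;
      if (tbF[k]) state = 0;
      --i;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["columns"] = cols,
                      _["ref_start"] = ref_start, _["ref_end"] = ref_end,
                      _["query_start"] = q_start, _["query_end"] = q_end);
}

// Batch local alignment of one query against many references.
// Returns a matrix with columns score, identity, ref_coverage.
// [[Rcpp::export(name = ".cpp_sw_batch")]]
NumericMatrix cpp_sw_batch(std::string query, CharacterVector refs,
                           double match = 1.0, double mismatch = -2.0,
                           double gap_open = -5.0, double gap_extend = -2.0) {
  int nref = refs.size();
  NumericMatrix out(nref, 3);
  colnames(out) = CharacterVector::create("score", "identity", "ref_coverage");
  for (int a = 0; a < nref; ++a) {
    std::string r = as<std::string>(refs[a]);
    List al = cpp_sw_align(query, r, match, mismatch, gap_open, gap_extend);
    double cols = as<double>(al["columns"]);
    double mt = as<double>(al["matches"]);
    double rs = as<double>(al["ref_start"]), re = as<double>(al["ref_end"]);
    out(a, 0) = as<double>(al["score"]);
    out(a, 1) = cols > 0 ? mt / cols : 0.0;
    out(a, 2) = r.size() > 0 && re >= rs ? (re - rs + 1.0) / r.size() : 0.0;
  }
  return out;
}

// Score-only local alignment (no traceback): used for bulk clade-level
// scoring where only the best score per reference matters.
static double sw_score(const std::vector<int>& q, const std::vector<int>& r,
                       int match, int mismatch, int gap_open, int gap_extend) {
  int m = q.size(), n = r.size();
  if (m == 0 || n == 0) return 0.0;
  const int NEG = -(1 << 28);
  std::vector<int> Hprev(n + 1, 0), Hcur(n + 1, 0), Ecur(n + 1, NEG),
      Fprev(n + 1, NEG), Fcur(n + 1, NEG);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG;
    const int qi = q[i - 1];
    const bool unamb = unambiguous(qi);
    for (int j = 1; j <= n; ++j) {
      int e = std::max(Hcur[j - 1] + gap_open, Ecur[j - 1] + gap_extend);
      int f = std::max(Hprev[j] + gap_open, Fprev[j] + gap_extend);
      int s = (unamb && (qi & r[j - 1])) ? match : mismatch;
      int h = Hprev[j - 1] + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      Hcur[j] = h; Ecur[j] = e; Fcur[j] = f;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur); std::swap(Fprev, Fcur);
  }
  return (double)best;
}

// [[Rcpp::export(name = ".cpp_sw_score_batch")]]
NumericVector cpp_sw_score_batch(std::string query, CharacterVector refs,
                                 double match = 1.0, double mismatch = -2.0,
                                 double gap_open = -5.0,
                                 double gap_extend = -2.0) {
  std::vector<int> q = to_masks(query);
  int nref = refs.size();
  NumericVector out(nref);
  for (int a = 0; a < nref; ++a)
    out[a] = sw_score(q, to_masks(as<std::string>(refs[a])),
                      (int)match, (int)mismatch, (int)gap_open,
                      (int)gap_extend);
  return out;
}

// Global (Needleman-Wunsch, affine) identity: matches / alignment columns,
// terminal and internal gaps all counted as columns.
// [[Rcpp::export(name = ".cpp_global_identity")]]
double cpp_global_identity(std::string a, std::string b,
                           double match = 1.0, double mismatch = -1.0,
                           double gap_open = -2.0, double gap_extend = -1.0) {
  std::vector<int> q = to_masks(a), r = to_masks(b);
  int m = q.size(), n = r.size();
  if (m == 0 && n == 0) return 1.0;
  if (m == 0 || n == 0) return 0.0;
  const double NEG = -1e18;
  std::vector<double> Hprev(n + 1), Hcur(n + 1), Eprev(n + 1), Ecur(n + 1),
      Fprev(n + 1), Fcur(n + 1);
  std::vector<unsigned char> tbH((m + 1) * (n + 1), 0), tbE((m + 1) * (n + 1), 0),
      tbF((m + 1) * (n + 1), 0);
  Hprev[0] = 0; Eprev[0] = NEG; Fprev[0] = NEG;
  for (int j = 1; j <= n; ++j) {
    Eprev[j] = gap_open + (j - 1) * gap_extend;
    Hprev[j] = Eprev[j]; Fprev[j] = NEG;
    tbH[j] = 2; tbE[j] = (j == 1);
  }
  for (int i = 1; i <= m; ++i) {
    Fcur[0] = gap_open + (i - 1) * gap_extend;
    Hcur[0] = Fcur[0]; Ecur[0] = NEG;
    tbH[(size_t)i * (n + 1)] = 3; tbF[(size_t)i * (n + 1)] = (i == 1);
    for (int j = 1; j <= n; ++j) {
      size_t k = (size_t)i * (n + 1) + j;
      double eo = Hcur[j - 1] + gap_open, ee = Ecur[j - 1] + gap_extend;
      Ecur[j] = (eo >= ee) ? eo : ee; tbE[k] = (eo >= ee) ? 1 : 0;
      double fo = Hprev[j] + gap_open, fe = Fprev[j] + gap_extend;
      Fcur[j] = (fo >= fe) ? fo : fe; tbF[k] = (fo >= fe) ? 1 : 0;
      double s = base_match_strict(q[i - 1], r[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double h = diag; unsigned char tb = 1;
      if (Ecur[j] > h) { h = Ecur[j]; tb = 2; }
      if (Fcur[j] > h) { h = Fcur[j]; tb = 3; }
      Hcur[j] = h; tbH[k] = tb;
    }
    std::swap(Hprev, Hcur); std::swap(Eprev, Ecur); std::swap(Fprev, Fcur);
  }
  int i = m, j = n, matches = 0, cols = 0, state = 0;
  while (i > 0 || j > 0) {
    size_t k = (size_t)i * (n + 1) + j;
    if (state == 0) {
      unsigned char tb = tbH[k];
      if (tb == 1) {
        ++cols;
        if (base_match_strict(q[i - 1], r[j - 1])) ++matches;
        --i; --j;
      } else if (tb == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ++cols; if (tbE[k]) state = 0; --j;
    } else {
      ++cols; if (tbF[k]) state = 0; --i;
    }
  }
  return cols > 0 ? (double)matches / cols : 0.0;
}

// [[Rcpp::export(name = ".cpp_identity_batch")]]
NumericVector cpp_identity_batch(std::string query, CharacterVector refs,
                                 double match = 1.0, double mismatch = -1.0,
                                 double gap_open = -2.0, double gap_extend = -1.0) {
  int nref = refs.size();
  NumericVector out(nref);
  for (int a = 0; a < nref; ++a)
    out[a] = cpp_global_identity(query, as<std::string>(refs[a]),
                                 match, mismatch, gap_open, gap_extend);
  return out;
}

// Semi-global edit-distance search for a primer in a read: the pattern must
// align end-to-end, the text offers free leading/trailing bases. IUPAC codes
// in the pattern match any intersecting read base. Unit costs for
// substitutions and indels. Returns the minimal distance and the 1-based
// text span of the best occurrence (leftmost end on ties, then shortest).
// [[Rcpp::export(name = ".cpp_locate_primer")]]
List cpp_locate_primer(std::string pattern, std::string text) {
  std::vector<int> p = to_masks(pattern), t = to_masks(text);
  int m = p.size(), n = t.size();
  if (m == 0 || n == 0)
    return List::create(_["distance"] = m, _["start"] = 0, _["end"] = 0);
  // D[i][j]: min edits aligning pattern[1..i] with text ending at j.
  std::vector<std::vector<int>> D(m + 1, std::vector<int>(n + 1));
  for (int j = 0; j <= n; ++j) D[0][j] = 0;
  for (int i = 1; i <= m; ++i) D[i][0] = i;
  for (int i = 1; i <= m; ++i)
    for (int j = 1; j <= n; ++j) {
      int sub = D[i - 1][j - 1] + (base_match_iupac(p[i - 1], t[j - 1]) ? 0 : 1);
      int del = D[i - 1][j] + 1; // pattern base unmatched
      int ins = D[i][j - 1] + 1; // extra text base inside the match
      int d = sub; if (del < d) d = del; if (ins < d) d = ins;
      D[i][j] = d;
    }
  int best = D[m][0], bj = 0;
  for (int j = 1; j <= n; ++j)
    if (D[m][j] < best) { best = D[m][j]; bj = j; }
  // traceback to find the start of the occurrence
  int i = m, j = bj;
  while (i > 0) {
    if (j > 0 && D[i][j] == D[i - 1][j - 1] +
        (base_match_iupac(p[i - 1], t[j - 1]) ? 0 : 1)) { --i; --j; }
    else if (j > 0 && D[i][j] == D[i][j - 1] + 1) { --j; }
    else { --i; } // deletion of a pattern base
  }
  return List::create(_["distance"] = best, _["start"] = j + 1, _["end"] = bj);
}
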