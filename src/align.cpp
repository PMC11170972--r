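// Affine-gap alignment kernels used by the 16S, gene-catalog and protein
// homology layers. Gap convention throughout: a gap of length L costs
// open + (L-1) * ext (the first gapped position pays the opening charge).
#include <Rcpp.h>
#include <cstring>
#include <vector>
#include <limits>
using namespace Rcpp;

static const int NEG = std::numeric_limits<int>::min() / 4;

// BLOSUM62, alphabet order ARNDCQEGHILKMFPSTWYVBZX; any other letter maps to X.
// X is forced to score 0 against everything (undetermined residues are neutral).
static const char AA_ORDER[] = "ARNDCQEGHILKMFPSTWYVBZX";
static const int NAA = 23;
static const int BLOSUM62[NAA][NAA] = {
  { 4,-1,-2,-2, 0,-1,-1, 0,-2,-1,-1,-1,-1,-2,-1, 1, 0,-3,-2, 0,-2,-1, 0},
  {-1, 5, 0,-2,-3, 1, 0,-2, 0,-3,-2, 2,-1,-3,-2,-1,-1,-3,-2,-3,-1, 0, 0},
  {-2, 0, 6, 1,-3, 0, 0, 0, 1,-3,-3, 0,-2,-3,-2, 1, 0,-4,-2,-3, 3, 0, 0},
  {-2,-2, 1, 6,-3, 0, 2,-1,-1,-3,-4,-1,-3,-3,-1, 0,-1,-4,-3,-3, 4, 1, 0},
  { 0,-3,-3,-3, 9,-3,-4,-3,-3,-1,-1,-3,-1,-2,-3,-1,-1,-2,-2,-1,-3,-3, 0},
  {-1, 1, 0, 0,-3, 5, 2,-2, 0,-3,-2, 1, 0,-3,-1, 0,-1,-2,-1,-2, 0, 3, 0},
  {-1, 0, 0, 2,-4, 2, 5,-2, 0,-3,-3, 1,-2,-3,-1, 0,-1,-3,-2,-2, 1, 4, 0},
  { 0,-2, 0,-1,-3,-2,-2, 6,-2,-4,-4,-2,-3,-3,-2, 0,-2,-2,-3,-3,-1,-2, 0},
  {-2, 0, 1,-1,-3, 0, 0,-2, 8,-3,-3,-1,-2,-1,-2,-1,-2,-2, 2,-3, 0, 0, 0},
  {-1,-3,-3,-3,-1,-3,-3,-4,-3, 4, 2,-3, 1, 0,-3,-2,-1,-3,-1, 3,-3,-3, 0},
  {-1,-2,-3,-4,-1,-2,-3,-4,-3, 2, 4,-2, 2, 0,-3,-2,-1,-2,-1, 1,-4,-3, 0},
  {-1, 2, 0,-1,-3, 1, 1,-2,-1,-3,-2, 5,-1,-3,-1, 0,-1,-3,-2,-2, 0, 1, 0},
  {-1,-1,-2,-3,-1, 0,-2,-3,-2, 1, 2,-1, 5, 0,-2,-1,-1,-1,-1, 1,-3,-1, 0},
  {-2,-3,-3,-3,-2,-3,-3,-3,-1, 0, 0,-3, 0, 6,-4,-2,-2, 1, 3,-1,-3,-3, 0},
  {-1,-2,-2,-1,-3,-1,-1,-2,-2,-3,-3,-1,-2,-4, 7,-1,-1,-4,-3,-2,-2,-1, 0},
  { 1,-1, 1, 0,-1, 0, 0, 0,-1,-2,-2, 0,-1,-2,-1, 4, 1,-3,-2,-2, 0, 0, 0},
  { 0,-1, 0,-1,-1,-1,-1,-2,-2,-1,-1,-1,-1,-2,-1, 1, 5,-2,-2, 0,-1,-1, 0},
  {-3,-3,-4,-4,-2,-2,-3,-2,-2,-3,-2,-3,-1, 1,-4,-3,-2,11, 2,-3,-4,-3, 0},
  {-2,-2,-2,-3,-2,-1,-2,-3, 2,-1,-1,-2,-1, 3,-3,-2,-2, 2, 7,-1,-3,-2, 0},
  { 0,-3,-3,-3,-1,-2,-2,-3,-3, 3, 1,-2, 1,-1,-2,-2, 0,-3,-1, 4,-3,-2, 0},
  {-2,-1, 3, 4,-3, 0, 1,-1, 0,-3,-4, 0,-3,-3,-2, 0,-1,-4,-3,-3, 4, 1, 0},
  {-1, 0, 0, 1,-3, 3, 4,-2, 0,-3,-3, 1,-1,-3,-1, 0,-1,-3,-2,-2, 1, 4, 0},
  { 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0}
};

static inline int aa_index(char c) {
  if (c >= 'a' && c <= 'z') c = c - 'a' + 'A';
  const char *p = std::strchr(AA_ORDER, c);
  return p ? (int)(p - AA_ORDER) : (NAA - 1); // unknown -> X
}

// [[Rcpp::export]]
List cpp_global_align(std::string a, std::string b,
                      int match = 2, int mismatch = -3,
                      int gap_open = 5, int gap_ext = 2,
                      bool blosum = false) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int> ai, bi;
  if (blosum) {
    ai.resize(n); bi.resize(m);
    for (int i = 0; i < n; ++i) ai[i] = aa_index(a[i]);
    for (int j = 0; j < m; ++j) bi[j] = aa_index(b[j]);
  }
  // Scores: M (diagonal), E (gap in b: consumes a), F (gap in a: consumes b).
  std::vector<int> M0(m + 1), M1(m + 1), E0(m + 1), E1(m + 1), F0(m + 1), F1(m + 1);
  // Traceback: 2 bits per state per cell.
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  // codes in tb: bits 0-1 = predecessor of M (1=M,2=E,3=F)
  //              bits 2-3 = predecessor of E (1=M,2=E)
  //              bits 4-5 = predecessor of F (1=M,3=F -> store 1 or 3)
  M0[0] = 0; E0[0] = NEG; F0[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEG; E0[j] = NEG;
    F0[j] = -(gap_open + (j - 1) * gap_ext);
    tb[j] |= (unsigned char)(((j == 1 ? 1 : 3)) << 4);
  }
  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG; F1[0] = NEG;
    E1[0] = -(gap_open + (i - 1) * gap_ext);
    tb[(size_t)i * (m + 1)] |= (unsigned char)((i == 1 ? 1 : 2) << 2);
    for (int j = 1; j <= m; ++j) {
      int s = blosum ? BLOSUM62[ai[i - 1]][bi[j - 1]]
                     : (a[i - 1] == b[j - 1] ? match : mismatch);
      // M
      int bm = M0[j - 1], code = 1;
      if (E0[j - 1] > bm) { bm = E0[j - 1]; code = 2; }
      if (F0[j - 1] > bm) { bm = F0[j - 1]; code = 3; }
      M1[j] = (bm <= NEG / 2) ? NEG : bm + s;
      unsigned char t = (unsigned char)code;
      // E: gap in b (vertical), from row i-1
      int eo = (M0[j] <= NEG / 2) ? NEG : M0[j] - gap_open;
      int ee = (E0[j] <= NEG / 2) ? NEG : E0[j] - gap_ext;
      if (eo >= ee) { E1[j] = eo; t |= (unsigned char)(1 << 2); }
      else          { E1[j] = ee; t |= (unsigned char)(2 << 2); }
      // F: gap in a (horizontal), from column j-1 in this row
      int fo = (M1[j - 1] <= NEG / 2) ? NEG : M1[j - 1] - gap_open;
      int fe = (F1[j - 1] <= NEG / 2) ? NEG : F1[j - 1] - gap_ext;
      if (fo >= fe) { F1[j] = fo; t |= (unsigned char)(1 << 4); }
      else          { F1[j] = fe; t |= (unsigned char)(3 << 4); }
      tb[(size_t)i * (m + 1) + j] = t;
    }
    std::swap(M0, M1); std::swap(E0, E1); std::swap(F0, F1);
  }
  int best = M0[m], state = 1;
  if (E0[m] > best) { best = E0[m]; state = 2; }
  if (F0[m] > best) { best = F0[m]; state = 3; }
  // Traceback
  int i = n, j = m;
  long columns = 0, matches = 0, aligned_pairs = 0;
  while (i > 0 || j > 0) {
    unsigned char t = tb[(size_t)i * (m + 1) + j];
    ++columns;
    if (state == 1) {            // M: consume a[i-1], b[j-1]
      ++aligned_pairs;
      if (a[i - 1] == b[j - 1]) ++matches;
      state = t & 3; --i; --j;
    } else if (state == 2) {     // E: consume a[i-1]
      state = (t >> 2) & 3; --i;
    } else {                     // F: consume b[j-1]
      int prev = (t >> 4) & 3;
      state = prev; --j;
    }
  }
  return List::create(_["score"] = best, _["matches"] = (double)matches,
                      _["columns"] = (double)columns,
                      _["aligned_pairs"] = (double)aligned_pairs);
}

// [[Rcpp::export]]
List cpp_local_align(std::string q, std::string t_,
                     int gap_open = 11, int gap_ext = 1) {
  const int n = (int)q.size(), m = (int)t_.size();
  if (n == 0 || m == 0) stop("empty sequence");
  std::vector<int> qi(n), ti(m);
  for (int i = 0; i < n; ++i) qi[i] = aa_index(q[i]);
  for (int j = 0; j < m; ++j) ti[j] = aa_index(t_[j]);
  std::vector<int> H0(m + 1, 0), H1(m + 1, 0), E0(m + 1, NEG), E1(m + 1, NEG),
                   F0(m + 1, NEG), F1(m + 1, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1), 0);
  // codes: bits 0-1 predecessor of H (0=alignment starts here, 1=H, 2=E, 3=F);
  //        bit 2: E from H (set) or E; bit 3: F from H (set) or F.
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    H1[0] = 0; E1[0] = NEG; F1[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      int s = BLOSUM62[qi[i - 1]][ti[j - 1]];
      int diag = H0[j - 1], code = 1;
      if (E0[j - 1] > diag) { diag = E0[j - 1]; code = 2; }
      if (F0[j - 1] > diag) { diag = F0[j - 1]; code = 3; }
      if (diag <= 0) { diag = 0; code = 0; } // fresh start at this cell
      int h = diag + s;
      if (h < 0) h = 0;
      H1[j] = h;
      unsigned char t = (unsigned char)code;
      int eo = H0[j] - gap_open;
      int ee = (E0[j] <= NEG / 2) ? NEG : E0[j] - gap_ext;
      if (eo >= ee) { E1[j] = eo; t |= 4; } else { E1[j] = ee; }
      int fo = H1[j - 1] - gap_open;
      int fe = (F1[j - 1] <= NEG / 2) ? NEG : F1[j - 1] - gap_ext;
      if (fo >= fe) { F1[j] = fo; t |= 8; } else { F1[j] = fe; }
      tb[(size_t)i * (m + 1) + j] = t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(H0, H1); std::swap(E0, E1); std::swap(F0, F1);
  }
  long columns = 0, matches = 0;
  int i = bi, j = bj, state = 1;
  int q_end = bi, t_end = bj, q_start = bi, t_start = bj;
  if (best > 0) {
    while (i > 0 && j > 0) {
      unsigned char t = tb[(size_t)i * (m + 1) + j];
      if (state == 1) {
        int code = t & 3;
        ++columns;
        if (q[i - 1] == t_[j - 1]) ++matches;
        q_start = i; t_start = j;
        --i; --j;
        if (code == 0) break;
        state = code;
      } else if (state == 2) {
        ++columns;
        state = (t & 4) ? 1 : 2;
        --i;
      } else {
        ++columns;
        state = (t & 8) ? 1 : 3;
        --j;
      }
    }
  } else {
    q_start = q_end = t_start = t_end = 0;
  }
  return List::create(_["score"] = best, _["matches"] = (double)matches,
                      _["columns"] = (double)columns,
                      _["q_start"] = q_start, _["q_end"] = q_end,
                      _["t_start"] = t_start, _["t_end"] = t_end);
}
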