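#include <Rcpp.h>
#include <climits>
#include <cstdlib>
using namespace Rcpp;

static const int NEG = INT_MIN / 4;

// Banded Needleman-Wunsch with linear gap costs. Band is measured around the
// main diagonal; it is widened to cover the length difference so the corner
// cell is always reachable. Ties resolve diagonal > up > left so the
// traceback is deterministic.
// [[Rcpp::export(name = ".align_global_banded_cpp")]]
List align_global_banded_cpp(std::string a, std::string b,
                             int match, int mismatch, int gap,
                             int band, bool return_alignment) {
  int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0) stop("empty sequence");
  int shift = std::abs(la - lb);
  if (band < shift + 1) band = shift + 1;
  std::vector<int> S((size_t)(la + 1) * (lb + 1), NEG);
  std::vector<signed char> D((size_t)(la + 1) * (lb + 1), 0);
  size_t W = lb + 1;
  S[0] = 0;
  for (int j = 1; j <= lb && j <= band; j++) { S[j] = -gap * j; D[j] = 3; }
  for (int i = 1; i <= la && i <= band; i++) { S[i * W] = -gap * i; D[i * W] = 2; }
  for (int i = 1; i <= la; i++) {
    int jlo = std::max(1, i - band), jhi = std::min(lb, i + band);
    for (int j = jlo; j <= jhi; j++) {
      int best = NEG; signed char dir = 0;
      int sd = S[(i - 1) * W + (j - 1)];
      if (sd > NEG) {
        int v = sd + (a[i - 1] == b[j - 1] ? match : mismatch);
        if (v > best) { best = v; dir = 1; }
      }
      int su = S[(i - 1) * W + j];
      if (su > NEG) { int v = su - gap; if (v > best) { best = v; dir = 2; } }
      int sl = S[i * W + (j - 1)];
      if (sl > NEG) { int v = sl - gap; if (v > best) { best = v; dir = 3; } }
      S[i * W + j] = best; D[i * W + j] = dir;
    }
  }
  int score = S[la * W + lb];
  if (score <= NEG) stop("band too narrow: no global path");
  // traceback
  int i = la, j = lb, matches = 0, alen = 0;
  std::string aa, ab;
  while (i > 0 || j > 0) {
    signed char d = D[i * W + j];
    alen++;
    if (d == 1) {
      if (a[i - 1] == b[j - 1]) matches++;
      if (return_alignment) { aa.push_back(a[i - 1]); ab.push_back(b[j - 1]); }
      i--; j--;
    } else if (d == 2) {
      if (return_alignment) { aa.push_back(a[i - 1]); ab.push_back('-'); }
      i--;
    } else if (d == 3) {
      if (return_alignment) { aa.push_back('-'); ab.push_back(b[j - 1]); }
      j--;
    } else stop("corrupt traceback");
  }
  List out = List::create(_["score"] = score, _["matches"] = matches,
                          _["aligned_length"] = alen);
  if (return_alignment) {
    std::string ra(aa.rbegin(), aa.rend()), rb(ab.rbegin(), ab.rend());
    out["alignment_a"] = ra;
    out["alignment_b"] = rb;
  }
  return out;
}

// Smith-Waterman local alignment with linear gap costs. The reported hit is
// the highest-scoring cell; among equal scores the first in row-major order
// wins, keeping results reproducible.
// [[Rcpp::export(name = ".align_local_cpp")]]
List align_local_cpp(std::string a, std::string b,
                     int match, int mismatch, int gap,
                     bool return_alignment) {
  int la = (int)a.size(), lb = (int)b.size();
  if (la == 0 || lb == 0) stop("empty sequence");
  size_t W = lb + 1;
  std::vector<int> S((size_t)(la + 1) * (lb + 1), 0);
  std::vector<signed char> D((size_t)(la + 1) * (lb + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= la; i++) {
    for (int j = 1; j <= lb; j++) {
      int v = 0; signed char dir = 0;
      int vd = S[(i - 1) * W + (j - 1)] + (a[i - 1] == b[j - 1] ? match : mismatch);
      if (vd > v) { v = vd; dir = 1; }
      int vu = S[(i - 1) * W + j] - gap;
      if (vu > v) { v = vu; dir = 2; }
      int vl = S[i * W + (j - 1)] - gap;
      if (vl > v) { v = vl; dir = 3; }
      S[i * W + j] = v; D[i * W + j] = dir;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, matches = 0, alen = 0;
  std::string aa, ab;
  while (i > 0 && j > 0 && S[i * W + j] > 0) {
    signed char d = D[i * W + j];
    if (d == 0) break;
    alen++;
    if (d == 1) {
      if (a[i - 1] == b[j - 1]) matches++;
      if (return_alignment) { aa.push_back(a[i - 1]); ab.push_back(b[j - 1]); }
      i--; j--;
    } else if (d == 2) {
      if (return_alignment) { aa.push_back(a[i - 1]); ab.push_back('-'); }
      i--;
    } else {
      if (return_alignment) { aa.push_back('-'); ab.push_back(b[j - 1]); }
      j--;
    }
  }
  List out = List::create(_["score"] = best, _["matches"] = matches,
                          _["aligned_length"] = alen,
                          _["start_a"] = i + 1, _["start_b"] = j + 1,
                          _["end_a"] = bi, _["end_b"] = bj);
  if (return_alignment) {
    std::string ra(aa.rbegin(), aa.rend()), rb(ab.rbegin(), ab.rend());
    out["alignment_a"] = ra;
    out["alignment_b"] = rb;
  }
  return out;
}

// Pairwise transition/transversion/comparable-site counts over a coded
// alignment matrix (rows = sequences; 0=A,1=C,2=G,3=T, negative = missing).
// Transitions are A<->G (0,2) and C<->T (1,3).
// [[Rcpp::export(name = ".k2p_counts_cpp")]]
List k2p_counts_cpp(IntegerMatrix codes) {
  int n = codes.nrow(), L = codes.ncol();
  IntegerMatrix ts(n, n), tv(n, n), ns(n, n);
  for (int i = 0; i < n; i++) {
    for (int j = i + 1; j < n; j++) {
      int cts = 0, ctv = 0, cns = 0;
      for (int k = 0; k < L; k++) {
        int x = codes(i, k), y = codes(j, k);
        if (x < 0 || y < 0) continue;
        cns++;
        if (x == y) continue;
        if ((x + y == 2 && x != 1) || (x + y == 4 && x != 2)) cts++;  // {0,2} or {1,3}
        else ctv++;
      }
      ts(i, j) = ts(j, i) = cts;
      tv(i, j) = tv(j, i) = ctv;
      ns(i, j) = ns(j, i) = cns;
    }
  }
  return List::create(_["transitions"] = ts, _["transversions"] = tv,
                      _["n_sites"] = ns);
}
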