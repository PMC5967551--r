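#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// Alignment primitives shared by the merging, denoising, taxonomy and MSA
// stages. All dynamic programming is full-matrix (no banding, no heuristics)
// so results are exactly reproducible and comparable to brute-force oracles.

// ---------------------------------------------------------------------------
// Paired-end overlap merge.
// s2 / q2 must already be the reverse-complemented mate (qualities reversed).
// Candidate overlaps o in [min_overlap, min(n1, n2)]: the last o bases of s1
// against the first o bases of s2. The candidate minimizing mismatch fraction
// wins; ties go to the longest overlap. Rejected (NULL) if the best fraction
// exceeds max_mm_frac or no candidate exists.
// Consensus: agreement keeps the base with quality max(q1, q2); disagreement
// keeps the higher-quality base with its own quality; quality ties keep the
// forward-read base.
// [[Rcpp::export]]
SEXP merge_overlap_cpp(std::string s1, IntegerVector q1,
                       std::string s2, IntegerVector q2,
                       int min_overlap, double max_mm_frac) {
  int n1 = s1.size(), n2 = s2.size();
  if (min_overlap < 1) min_overlap = 1;
  int omax = std::min(n1, n2);
  int best_o = -1;
  double best_frac = 2.0;
  for (int o = min_overlap; o <= omax; ++o) {
    int mm = 0;
    const char *a = s1.data() + (n1 - o);
    const char *b = s2.data();
    for (int k = 0; k < o; ++k) if (a[k] != b[k]) ++mm;
    double frac = (double)mm / o;
    if (frac < best_frac || (frac == best_frac && o > best_o)) {
      best_frac = frac;
      best_o = o;
    }
  }
  if (best_o < 0 || best_frac > max_mm_frac) return R_NilValue;

  int o = best_o;
  int mlen = n1 + n2 - o;
  std::string seq(mlen, 'N');
  IntegerVector qual(mlen);
  for (int i = 0; i < n1 - o; ++i) { seq[i] = s1[i]; qual[i] = q1[i]; }
  for (int k = 0; k < o; ++k) {
    int i1 = n1 - o + k;
    char b1 = s1[i1], b2 = s2[k];
    int Q1 = q1[i1], Q2 = q2[k];
    int pos = n1 - o + k;
    if (b1 == b2) {
      seq[pos] = b1; qual[pos] = std::max(Q1, Q2);
    } else if (Q1 >= Q2) {           // tie -> forward-read base
      seq[pos] = b1; qual[pos] = Q1;
    } else {
      seq[pos] = b2; qual[pos] = Q2;
    }
  }
  for (int k = o; k < n2; ++k) { seq[n1 + k - o] = s2[k]; qual[n1 + k - o] = q2[k]; }
  return List::create(_["sequence"] = seq, _["qualities"] = qual,
                      _["overlap_len"] = o, _["mismatch_frac"] = best_frac);
}

// ---------------------------------------------------------------------------
// End-gap-free global alignment (overlap alignment), linear gap penalty.
// First row/column initialised to 0 and the optimum taken over the last
// row/column, so terminal gaps are free. Identity statistics are computed
// from the traceback over the aligned region only (overhangs excluded).
// [[Rcpp::export]]
List align_endsfree_cpp(std::string a, std::string b,
                        double match = 1.0, double mismatch = -1.0,
                        double gap = -2.0) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1);   // 0 stop, 1 diag, 2 up (gap in b), 3 left
  for (int i = 0; i <= n; ++i) { H(i, 0) = 0; P(i, 0) = 0; }
  for (int j = 0; j <= m; ++j) { H(0, j) = 0; P(0, j) = 0; }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double sd = H(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double su = H(i - 1, j) + gap;
      double sl = H(i, j - 1) + gap;
      double best = sd; int ptr = 1;
      if (su > best) { best = su; ptr = 2; }
      if (sl > best) { best = sl; ptr = 3; }
      H(i, j) = best; P(i, j) = ptr;
    }
  }
  // best end on last row or last column; ties -> larger i, then larger j
  int bi = n, bj = m; double bs = H(n, m);
  for (int j = 0; j <= m; ++j) if (H(n, j) > bs) { bs = H(n, j); bi = n; bj = j; }
  for (int i = 0; i <= n; ++i) if (H(i, m) > bs) { bs = H(i, m); bi = i; bj = m; }
  int i = bi, j = bj, matches = 0, mismatches = 0, gaps = 0, cols = 0;
  while (i > 0 && j > 0) {
    int ptr = P(i, j);
    if (ptr == 1) {
      ++cols; if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
      --i; --j;
    } else if (ptr == 2) { ++cols; ++gaps; --i; }
    else { ++cols; ++gaps; --j; }
  }
  return List::create(_["score"] = bs, _["matches"] = matches,
                      _["mismatches"] = mismatches, _["gaps"] = gaps,
                      _["columns"] = cols,
                      _["identity"] = cols > 0 ? (double)matches / cols : 0.0);
}

// ---------------------------------------------------------------------------
// Plain global (Needleman-Wunsch) alignment with linear gaps, returning the
// aligned strings. Traceback preference diag > up > left (deterministic).
// [[Rcpp::export]]
List align_global_cpp(std::string a, std::string b,
                      double match = 1.0, double mismatch = -1.0,
                      double gap = -2.0) {
  int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  for (int i = 0; i <= n; ++i) H(i, 0) = gap * i;
  for (int j = 0; j <= m; ++j) H(0, j) = gap * j;
  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double sd = H(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double su = H(i - 1, j) + gap;
      double sl = H(i, j - 1) + gap;
      H(i, j) = std::max(sd, std::max(su, sl));
    }
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        H(i, j) == H(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch)) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && H(i, j) == H(i - 1, j) + gap) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = H(n, m));
}

// ---------------------------------------------------------------------------
// Local (Smith-Waterman) alignment with affine gaps. A gap of length k costs
// gap_open + k * gap_ext (blastn-like -5/-2 means the first gapped base costs
// -7), matching the convention of Biostrings::pairwiseAlignment so scores can
// be cross-checked. Returns BLAST-tabular-style statistics: aligned_length
// counts all alignment columns including gaps; mismatches excludes gap
// columns; gap_opens counts runs of gaps.
// [[Rcpp::export]]
List align_local_cpp(std::string a, std::string b,
                     double match = 2.0, double mismatch = -3.0,
                     double gap_open = 5.0, double gap_ext = 2.0) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence in alignment");
  const double NEG = -1e18;
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> X((n + 1) * (m + 1), NEG);  // gap in a (consumes b)
  std::vector<double> Y((n + 1) * (m + 1), NEG);  // gap in b (consumes a)
  std::vector<unsigned char> PM((n + 1) * (m + 1), 0); // 0 start,1 M,2 X,3 Y
  std::vector<unsigned char> PX((n + 1) * (m + 1), 0); // 1 from M, 2 extend
  std::vector<unsigned char> PY((n + 1) * (m + 1), 0);
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int idx = i * (m + 1) + j;
      int di = (i - 1) * (m + 1) + (j - 1);
      int up = (i - 1) * (m + 1) + j;
      int lf = i * (m + 1) + (j - 1);
      // X: gap in a, consumes b[j-1]
      double xo = M[lf] - gap_open - gap_ext;
      double xe = X[lf] - gap_ext;
      if (xo >= xe) { X[idx] = xo; PX[idx] = 1; } else { X[idx] = xe; PX[idx] = 2; }
      // Y: gap in b, consumes a[i-1]
      double yo = M[up] - gap_open - gap_ext;
      double ye = Y[up] - gap_ext;
      if (yo >= ye) { Y[idx] = yo; PY[idx] = 1; } else { Y[idx] = ye; PY[idx] = 2; }
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double mm = M[di], mx = X[di], my = Y[di];
      double prev = mm; unsigned char ptr = 1;
      if (mx > prev) { prev = mx; ptr = 2; }
      if (my > prev) { prev = my; ptr = 3; }
      if (prev <= 0.0 && ptr == 1) { prev = 0.0; ptr = 0; } // start fresh
      double val = prev + s;
      if (val <= 0.0) { M[idx] = 0.0; PM[idx] = 0; }
      else { M[idx] = val; PM[idx] = ptr; }
      if (M[idx] > best) { best = M[idx]; bi = i; bj = j; }
    }
  }
  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["aligned_length"] = 0,
                        _["matches"] = 0, _["mismatches"] = 0,
                        _["gap_opens"] = 0, _["gap_cols"] = 0,
                        _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0);
  // traceback from (bi, bj) in state M until a zero-scored M cell
  int i = bi, j = bj, state = 1;
  int matches = 0, mismatches = 0, gap_opens = 0, gap_cols = 0, cols = 0;
  int qend = bi, send = bj, qstart = bi, sstart = bj;
  while (true) {
    int idx = i * (m + 1) + j;
    if (state == 1) {
      ++cols;
      if (a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
      qstart = i; sstart = j;
      int ptr = PM[idx];
      --i; --j;
      if (ptr == 0) break;      // score came from 0: alignment starts here
      state = ptr;
    } else if (state == 2) {    // gap in a, consumed b[j-1]
      ++cols; ++gap_cols;
      int ptr = PX[idx];
      --j;
      if (ptr == 1) { ++gap_opens; state = 1; }
    } else {                    // gap in b, consumed a[i-1]
      ++cols; ++gap_cols;
      int ptr = PY[idx];
      --i;
      if (ptr == 1) { ++gap_opens; state = 1; }
    }
  }
  return List::create(_["score"] = best, _["aligned_length"] = cols,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gap_opens"] = gap_opens, _["gap_cols"] = gap_cols,
                      _["qstart"] = qstart, _["qend"] = qend,
                      _["sstart"] = sstart, _["send"] = send);
}

// ---------------------------------------------------------------------------
// Hamming mismatch count between equal-length strings (primer placement).
// [[Rcpp::export]]
int hamming_cpp(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming_cpp: unequal lengths");
  int mm = 0;
  for (size_t k = 0; k < a.size(); ++k) if (a[k] != b[k]) ++mm;
  return mm;
}
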