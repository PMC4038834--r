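#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh, three-state DP).
// Gap convention: a gap run of length L costs gap_open + L * gap_extend
// (both parameters are <= 0); gap runs in opposite sequences may abut.
// Matching is IUPAC-aware: two symbols match iff their degeneracy sets
// intersect (so N matches everything, R matches A and G, ...).

static const double NEG_INF = -1e30;

static inline int iupac_mask(char c) {
  switch (c) {
    case 'A': return 1;  case 'C': return 2;  case 'G': return 4;  case 'T': return 8;
    case 'U': return 8;  case 'R': return 5;  case 'Y': return 10; case 'S': return 6;
    case 'W': return 9;  case 'K': return 12; case 'M': return 3;  case 'B': return 14;
    case 'D': return 13; case 'H': return 11; case 'V': return 7;  case 'N': return 15;
    default:  return 0;
  }
}

// mode: 0 = global, 1 = local, 2 = fit (all of `a` aligned, end gaps in `b` free)
// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_extend,
                    int mode) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("empty sequence passed to aligner");
  if ((double)n * (double)m > 6e7)
    stop("sequences too long for exact DP (%d x %d)", n, m);

  std::vector<int> ma(n + 1), mb(m + 1);
  for (int i = 1; i <= n; ++i) ma[i] = iupac_mask(a[i - 1]);
  for (int j = 1; j <= m; ++j) mb[j] = iupac_mask(b[j - 1]);

  const size_t W = (size_t)m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG_INF);
  std::vector<double> Ia((size_t)(n + 1) * W, NEG_INF); // gap in b, consumes a ("up")
  std::vector<double> Ib((size_t)(n + 1) * W, NEG_INF); // gap in a, consumes b ("left")
  #define AT(V, i, j) V[(size_t)(i) * W + (j)]

  AT(M, 0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) {
    if (mode == 1) AT(M, i, 0) = 0.0;
    else AT(Ia, i, 0) = gap_open + i * gap_extend;
  }
  for (int j = 1; j <= m; ++j) {
    if (mode == 0) AT(Ib, 0, j) = gap_open + j * gap_extend;
    else AT(M, 0, j) = 0.0; // local restart / free leading b in fit mode
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = ((ma[i] & mb[j]) != 0) ? match : mismatch;
      double prev = AT(M, i - 1, j - 1);
      if (AT(Ia, i - 1, j - 1) > prev) prev = AT(Ia, i - 1, j - 1);
      if (AT(Ib, i - 1, j - 1) > prev) prev = AT(Ib, i - 1, j - 1);
      double mv = (prev <= NEG_INF / 2) ? NEG_INF : s + prev;
      if (mode == 1 && mv < 0.0) mv = 0.0;
      AT(M, i, j) = mv;

      double ia = AT(M, i - 1, j) + gap_open + gap_extend;
      if (AT(Ia, i - 1, j) + gap_extend > ia) ia = AT(Ia, i - 1, j) + gap_extend;
      if (AT(Ib, i - 1, j) + gap_open + gap_extend > ia)
        ia = AT(Ib, i - 1, j) + gap_open + gap_extend;
      AT(Ia, i, j) = ia;

      double ib = AT(M, i, j - 1) + gap_open + gap_extend;
      if (AT(Ib, i, j - 1) + gap_extend > ib) ib = AT(Ib, i, j - 1) + gap_extend;
      if (AT(Ia, i, j - 1) + gap_open + gap_extend > ib)
        ib = AT(Ia, i, j - 1) + gap_open + gap_extend;
      AT(Ib, i, j) = ib;
    }
  }

  // Locate the end cell. State preference everywhere: M, then Ia, then Ib.
  int ei = n, ej = m, estate = 0;
  double best;
  if (mode == 0) {
    best = AT(M, n, m); estate = 0;
    if (AT(Ia, n, m) > best) { best = AT(Ia, n, m); estate = 1; }
    if (AT(Ib, n, m) > best) { best = AT(Ib, n, m); estate = 2; }
  } else if (mode == 2) {
    best = NEG_INF; ej = -1;
    for (int j = 0; j <= m; ++j) {  // smallest j on ties
      double vM = AT(M, n, j), vI = AT(Ia, n, j);
      double v = vM >= vI ? vM : vI;
      if (v > best) { best = v; ej = j; estate = (vM >= vI) ? 0 : 1; }
    }
  } else {
    // local: strictly-greater scan, j (subject) outer => lowest subject end,
    // then lowest query end, among tied maxima
    best = 0.0; ei = 0; ej = 0; estate = 0;
    for (int j = 1; j <= m; ++j)
      for (int i = 1; i <= n; ++i)
        if (AT(M, i, j) > best) { best = AT(M, i, j); ei = i; ej = j; }
    if (best <= 0.0) {
      return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = 0,
                          _["b_start"] = 0, _["b_end"] = 0,
                          _["a_row"] = "", _["b_row"] = "");
    }
  }

  // Traceback (recompute decisions; preference M > Ia > Ib).
  std::string ra, rb;
  int i = ei, j = ej, state = estate;
  int a_min = n + 1, b_min = m + 1;
  while (true) {
    if (state == 0) {
      if (i == 0) break;                      // fit/local start row
      if (mode == 1 && AT(M, i, j) == 0.0) break;
      if (i == 0 || j == 0) break;
      double s = ((ma[i] & mb[j]) != 0) ? match : mismatch;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      if (i < a_min) a_min = i;
      if (j < b_min) b_min = j;
      double v = AT(M, i, j);
      double pM = AT(M, i - 1, j - 1), pIa = AT(Ia, i - 1, j - 1), pIb = AT(Ib, i - 1, j - 1);
      --i; --j;
      if (mode == 1) {
        // restart contributes 0
        if (v == s + pM && pM > 0.0) { state = 0; continue; }
        if (v == s + pIa) { state = 1; continue; }
        if (v == s + pIb) { state = 2; continue; }
        break;                                 // alignment started here
      }
      if (v == s + pM) { state = 0; continue; }
      if (v == s + pIa) { state = 1; continue; }
      if (v == s + pIb) { state = 2; continue; }
      stop("internal traceback failure (M)");
    } else if (state == 1) {
      if (i == 0) break;
      ra.push_back(a[i - 1]); rb.push_back('-');
      if (i < a_min) a_min = i;
      double v = AT(Ia, i, j);
      double pM = AT(M, i - 1, j), pIa = AT(Ia, i - 1, j), pIb = AT(Ib, i - 1, j);
      --i;
      if (v == pM + gap_open + gap_extend) { state = 0; continue; }
      if (v == pIa + gap_extend) { state = 1; continue; }
      if (v == pIb + gap_open + gap_extend) { state = 2; continue; }
      if (i == 0 && j == 0) break;             // boundary gap chain
      stop("internal traceback failure (Ia)");
    } else {
      if (j == 0) break;
      ra.push_back('-'); rb.push_back(b[j - 1]);
      if (j < b_min) b_min = j;
      double v = AT(Ib, i, j);
      double pM = AT(M, i, j - 1), pIb = AT(Ib, i, j - 1), pIa = AT(Ia, i, j - 1);
      --j;
      if (v == pM + gap_open + gap_extend) { state = 0; continue; }
      if (v == pIb + gap_extend) { state = 2; continue; }
      if (v == pIa + gap_open + gap_extend) { state = 1; continue; }
      if (i == 0 && j == 0) break;
      stop("internal traceback failure (Ib)");
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int a_start = (a_min <= n) ? a_min : 0;
  int b_start = (b_min <= m) ? b_min : 0;
  int a_end = (a_min <= n) ? ei : 0;
  int b_end = (b_min <= m) ? ej : 0;
  return List::create(_["score"] = best,
                      _["a_start"] = a_start, _["a_end"] = a_end,
                      _["b_start"] = b_start, _["b_end"] = b_end,
                      _["a_row"] = ra, _["b_row"] = rb);
  #undef AT
}

// Global affine alignment of two column-frequency profiles (rows = A,C,G,T,
// frequencies over non-gap residues; an all-gap column has colSums 0 and is
// scored 0 against anything). Returns the merge path: for each output column
// the source column index in each profile (0 = gap).
// [[Rcpp::export(name = ".align_profiles_cpp")]]
List align_profiles_cpp(NumericMatrix pa, NumericMatrix pb,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  const int n = pa.ncol(), m = pb.ncol();
  if (n == 0 || m == 0) stop("empty profile");
  if ((double)n * (double)m > 6e7) stop("profiles too long for exact DP");

  std::vector<double> sa(n + 1, 0.0), sb(m + 1, 0.0);
  for (int i = 1; i <= n; ++i) for (int r = 0; r < 4; ++r) sa[i] += pa(r, i - 1);
  for (int j = 1; j <= m; ++j) for (int r = 0; r < 4; ++r) sb[j] += pb(r, j - 1);

  const size_t W = (size_t)m + 1;
  std::vector<double> M((size_t)(n + 1) * W, NEG_INF), Ia(M), Ib(M);
  #define AT(V, i, j) V[(size_t)(i) * W + (j)]
  AT(M, 0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) AT(Ia, i, 0) = gap_open + i * gap_extend;
  for (int j = 1; j <= m; ++j) AT(Ib, 0, j) = gap_open + j * gap_extend;

  auto colscore = [&](int i, int j) -> double {
    if (sa[i] == 0.0 || sb[j] == 0.0) return 0.0;
    double dot = 0.0;
    for (int r = 0; r < 4; ++r) dot += (pa(r, i - 1) / sa[i]) * (pb(r, j - 1) / sb[j]);
    return dot * match + (1.0 - dot) * mismatch;
  };

  for (int i = 1; i <= n; ++i)
    for (int j = 1; j <= m; ++j) {
      double s = colscore(i, j);
      double prev = AT(M, i - 1, j - 1);
      if (AT(Ia, i - 1, j - 1) > prev) prev = AT(Ia, i - 1, j - 1);
      if (AT(Ib, i - 1, j - 1) > prev) prev = AT(Ib, i - 1, j - 1);
      AT(M, i, j) = s + prev;
      double ia = AT(M, i - 1, j) + gap_open + gap_extend;
      if (AT(Ia, i - 1, j) + gap_extend > ia) ia = AT(Ia, i - 1, j) + gap_extend;
      if (AT(Ib, i - 1, j) + gap_open + gap_extend > ia)
        ia = AT(Ib, i - 1, j) + gap_open + gap_extend;
      AT(Ia, i, j) = ia;
      double ib = AT(M, i, j - 1) + gap_open + gap_extend;
      if (AT(Ib, i, j - 1) + gap_extend > ib) ib = AT(Ib, i, j - 1) + gap_extend;
      if (AT(Ia, i, j - 1) + gap_open + gap_extend > ib)
        ib = AT(Ia, i, j - 1) + gap_open + gap_extend;
      AT(Ib, i, j) = ib;
    }

  int i = n, j = m, state = 0;
  double best = AT(M, n, m);
  if (AT(Ia, n, m) > best) { best = AT(Ia, n, m); state = 1; }
  if (AT(Ib, n, m) > best) { best = AT(Ib, n, m); state = 2; }

  std::vector<int> ai, bi;
  while (i > 0 || j > 0) {
    if (state == 0) {
      double s = colscore(i, j), v = AT(M, i, j);
      ai.push_back(i); bi.push_back(j);
      double pM = AT(M, i - 1, j - 1), pIa = AT(Ia, i - 1, j - 1), pIb = AT(Ib, i - 1, j - 1);
      --i; --j;
      if (i == 0 && j == 0) break;
      if (v == s + pM) state = 0;
      else if (v == s + pIa) state = 1;
      else if (v == s + pIb) state = 2;
      else stop("internal profile traceback failure (M)");
    } else if (state == 1) {
      double v = AT(Ia, i, j);
      ai.push_back(i); bi.push_back(0);
      double pM = AT(M, i - 1, j), pIa = AT(Ia, i - 1, j), pIb = AT(Ib, i - 1, j);
      --i;
      if (i == 0 && j == 0) break;
      if (v == pM + gap_open + gap_extend) state = 0;
      else if (v == pIa + gap_extend) state = 1;
      else if (v == pIb + gap_open + gap_extend) state = 2;
      else if (j == 0) state = 1;  // boundary column of leading gaps
      else stop("internal profile traceback failure (Ia)");
    } else {
      double v = AT(Ib, i, j);
      ai.push_back(0); bi.push_back(j);
      double pM = AT(M, i, j - 1), pIb = AT(Ib, i, j - 1), pIa = AT(Ia, i, j - 1);
      --j;
      if (i == 0 && j == 0) break;
      if (v == pM + gap_open + gap_extend) state = 0;
      else if (v == pIb + gap_extend) state = 2;
      else if (v == pIa + gap_open + gap_extend) state = 1;
      else if (i == 0) state = 2;
      else stop("internal profile traceback failure (Ib)");
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["score"] = best,
                      _["a_path"] = IntegerVector(ai.begin(), ai.end()),
                      _["b_path"] = IntegerVector(bi.begin(), bi.end()));
  #undef AT
}
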