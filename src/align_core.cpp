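#include <Rcpp.h>
#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3")
#endif
#include <cstdint>
#include <climits>
#include <cctype>
#include <string>
#include <vector>

using namespace Rcpp;

// Semi-global ("overlap") affine-gap alignment on IUPAC nucleotide codes.
// End gaps are free on both sequences; a column matches iff the IUPAC sets
// of the two symbols intersect.  Scores are integer: +match for an
// intersecting column, +mismatch (negative) otherwise; a gap of length L
// costs gap_open + (L - 1) * gap_ext (the opening column costs gap_open).
//
// Banded mode restricts the DP to diagonals d = j - i in
// [min(0, m-n) - w, max(0, m-n) + w].  Any path that touches a diagonal
// outside this band aligns at most min(n, m) - w residue pairs, so it
// scores at most match * (min(n, m) - w).  If the banded optimum reaches
// that bound, it is the global optimum (certificate used by the adaptive
// driver below); otherwise the band is doubled.

static const int NEG_INF = INT_MIN / 4;

static inline const uint8_t *mask_table() {
  static uint8_t tab[256];
  static bool init = false;
  if (!init) {
    for (int i = 0; i < 256; ++i) tab[i] = 0;
    const char *codes = "ACGTUMRWSYKVHDBN";
    const uint8_t masks[] = {1, 2, 4, 8, 8, 3, 5, 9, 6, 10, 12, 7, 11, 13, 14, 15};
    for (int i = 0; codes[i]; ++i) {
      tab[(unsigned char)codes[i]] = masks[i];
      tab[(unsigned char)std::tolower(codes[i])] = masks[i];
    }
    init = true;
  }
  return tab;
}

static void encode(const std::string &s, std::vector<uint8_t> &out) {
  const uint8_t *tab = mask_table();
  out.resize(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    uint8_t m = tab[(unsigned char)s[i]];
    if (m == 0) stop("non-IUPAC nucleotide character '%s' at position %d",
                     std::string(1, s[i]).c_str(), (int)(i + 1));
    out[i] = m;
  }
}

struct AlnOut {
  long score;
  int matches;     // intersecting residue columns
  int comparable;  // columns with a residue in both sequences
  std::string aligned_a, aligned_b;
};


#if defined(__SSE2__)
#include <emmintrin.h>
#endif

// pass 1 of the row update: F state, diagonal, tentative H, traceback
// bits 0-2.  Overloaded so the int16 path can use SSE2 (8 lanes).
static inline void pass1_row(const int *hp, const int *fp, int *hc, int *fc,
                             uint8_t *trow, const uint8_t *bb, long jstart,
                             long jend, uint8_t ai, int MA, int MI, int GO,
                             int GE) {
  for (long j = jstart; j <= jend; ++j) {
    int fo = hp[j] - GO, fe = fp[j] - GE;
    int f = fo >= fe ? fo : fe;
    int sgn = (ai & bb[j - 1]) ? MA : MI;
    int hd = hp[j - 1] + sgn;
    int h = hd >= f ? hd : f;
    fc[j] = f; hc[j] = h;
    trow[j] = (uint8_t)((hd >= f ? 1 : 2) | (fo >= fe ? 0 : 4));
  }
}

static inline void pass1_row(const int16_t *hp, const int16_t *fp,
                             int16_t *hc, int16_t *fc, uint8_t *trow,
                             const uint8_t *bb, long jstart, long jend,
                             uint8_t ai, int16_t MA, int16_t MI, int16_t GO,
                             int16_t GE) {
  long j = jstart;
#if defined(__SSE2__)
  const __m128i vGO = _mm_set1_epi16(GO), vGE = _mm_set1_epi16(GE);
  const __m128i vMA = _mm_set1_epi16(MA), vMI = _mm_set1_epi16(MI);
  const __m128i vai = _mm_set1_epi16((int16_t)ai);
  const __m128i zero = _mm_setzero_si128();
  const __m128i one = _mm_set1_epi16(1), four = _mm_set1_epi16(4);
  for (; j + 7 <= jend; j += 8) {
    __m128i vhp = _mm_loadu_si128((const __m128i *)(hp + j));
    __m128i vhpd = _mm_loadu_si128((const __m128i *)(hp + j - 1));
    __m128i vfp = _mm_loadu_si128((const __m128i *)(fp + j));
    __m128i fo = _mm_sub_epi16(vhp, vGO);
    __m128i fe = _mm_sub_epi16(vfp, vGE);
    __m128i f = _mm_max_epi16(fo, fe);
    __m128i ftb = _mm_and_si128(_mm_cmpgt_epi16(fe, fo), four);
    __m128i b16 = _mm_unpacklo_epi8(
        _mm_loadl_epi64((const __m128i *)(bb + j - 1)), zero);
    __m128i nomatch = _mm_cmpeq_epi16(_mm_and_si128(b16, vai), zero);
    __m128i sc = _mm_or_si128(_mm_and_si128(nomatch, vMI),
                              _mm_andnot_si128(nomatch, vMA));
    __m128i hd = _mm_add_epi16(vhpd, sc);
    __m128i h = _mm_max_epi16(hd, f);
    __m128i htb = _mm_add_epi16(one,
        _mm_and_si128(_mm_cmpgt_epi16(f, hd), one));
    _mm_storeu_si128((__m128i *)(fc + j), f);
    _mm_storeu_si128((__m128i *)(hc + j), h);
    __m128i tb16 = _mm_or_si128(htb, ftb);
    _mm_storel_epi64((__m128i *)(trow + j), _mm_packs_epi16(tb16, tb16));
  }
#endif
  for (; j <= jend; ++j) {
    int16_t fo = (int16_t)(hp[j] - GO), fe = (int16_t)(fp[j] - GE);
    int16_t f = fo >= fe ? fo : fe;
    int16_t sgn = (ai & bb[j - 1]) ? MA : MI;
    int16_t hd = (int16_t)(hp[j - 1] + sgn);
    int16_t h = hd >= f ? hd : f;
    fc[j] = f; hc[j] = h;
    trow[j] = (uint8_t)((hd >= f ? 1 : 2) | (fo >= fe ? 0 : 4));
  }
}

// Templated on the score type: int16_t keeps the working set in L1 for
// 16S-length problems (scores are bounded by match*min(n,m) and the
// sentinel can drift by at most gap_ext per row, so int16_t is safe for
// the lengths the int16 path is dispatched to); int is the general path.
template <typename T>
static AlnOut dp_align(const std::vector<uint8_t> &A, const std::string &sa,
                       const std::vector<uint8_t> &B, const std::string &sb,
                       int match, int mismatch, int gap_open, int gap_ext,
                       long dlo, long dhi, bool want_strings) {
  const long n = (long)A.size(), m = (long)B.size();
  const long W = m + 1;
  const T NEG = (T)(sizeof(T) == 2 ? -20000 : NEG_INF);
  const T MA = (T)match, MI = (T)mismatch, GO = (T)gap_open, GE = (T)gap_ext;

  std::vector<T> Hp(m + 1), Hc(m + 1), Fp(m + 1), Fc(m + 1);
  std::vector<long> colH(n + 1, (long)NEG_INF);  // H(i, m) where computed
  // packed traceback: bits 0-1 H (0=start,1=diag,2=up,3=left),
  // bit 2 F-extend, bit 3 E-extend
  static thread_local std::vector<uint8_t> tb;
  size_t cells = (size_t)(n + 1) * (size_t)W;
  if (tb.size() < cells) tb.resize(cells);

  for (long j = 0; j <= m; ++j) { Hp[j] = 0; Fp[j] = NEG; tb[j] = 0; }
  colH[0] = 0;

  long row_n_lo = 0, row_n_hi = 0;  // band of the final row, for the end scan
  for (long i = 1; i <= n; ++i) {
    long jstart = std::max(1L, i + dlo), jend = std::min(m, i + dhi);
    Hc[0] = 0;
    if (jstart > 1) Hc[jstart - 1] = NEG;
    const uint8_t ai = A[i - 1];
    uint8_t *__restrict trow = &tb[i * W];
    trow[0] = 0;
    const T *__restrict hp = Hp.data(), *__restrict fp = Fp.data();
    T *__restrict hc = Hc.data(), *__restrict fc = Fc.data();
    const uint8_t *__restrict bb = B.data();
    // pass 1: diagonal + vertical gap state (SIMD for the int16 path)
    pass1_row(hp, fp, hc, fc, trow, bb, jstart, jend, ai, MA, MI, GO, GE);
    // pass 2: lazy horizontal gap state; the correction rarely fires, so
    // the only carried dependency is e itself
    {
      T e = NEG;
      T hprev = hc[jstart - 1];
      for (long j = jstart; j <= jend; ++j) {
        T eo = (T)(hprev - GO), ee = (T)(e - GE);
        if (eo >= ee) { e = eo; } else { e = ee; trow[j] |= 8; }
        hprev = hc[j];
        if (e > hprev) {                        // E wins only when strictly better
          hc[j] = e; hprev = e;
          trow[j] = (uint8_t)((trow[j] & 0x0C) | 3);
        }
      }
    }
    if (jend < m) { Hc[jend + 1] = NEG; Fc[jend + 1] = NEG; }
    if (jend == m) colH[i] = (long)Hc[m];
    if (i == n) { row_n_lo = jstart; row_n_hi = jend; }
    std::swap(Hp, Hc); std::swap(Fp, Fc);
  }

  // End cell: free end gaps mean the best cell on the last row or last
  // column wins.  Deterministic preference: corner (n,m), then last row
  // right-to-left (plus the always-valid (n,0) = 0), then last column
  // bottom-up (plus (0,m) = 0).  Strictly-greater replaces.
  long best = NEG_INF, bi = -1, bj = -1;
  if (row_n_hi == m) { best = (long)Hp[m]; bi = n; bj = m; }
  for (long j = std::min(m - 1, row_n_hi); j >= row_n_lo; --j)
    if ((long)Hp[j] > best) { best = (long)Hp[j]; bi = n; bj = j; }
  if (0 > best) { best = 0; bi = n; bj = 0; }
  for (long i2 = n - 1; i2 >= 1; --i2)
    if (colH[i2] > best) { best = colH[i2]; bi = i2; bj = m; }
  if (0 > best) { best = 0; bi = 0; bj = m; }

  AlnOut out; out.score = best; out.matches = 0; out.comparable = 0;

  std::string ra, rb;  // built reversed
  long i = bi, j = bj;
  while (i > 0 && j > 0) {
    uint8_t code = tb[i * W + j] & 3;
    if (code == 1) {
      out.comparable++;
      if (A[i - 1] & B[j - 1]) out.matches++;
      if (want_strings) { ra.push_back(sa[i - 1]); rb.push_back(sb[j - 1]); }
      --i; --j;
    } else if (code == 2) {
      while (true) {
        if (want_strings) { ra.push_back(sa[i - 1]); rb.push_back('-'); }
        bool ext = (tb[i * W + j] & 4) != 0;
        --i;
        if (!ext || i == 0) break;
      }
    } else if (code == 3) {
      while (true) {
        if (want_strings) { ra.push_back('-'); rb.push_back(sb[j - 1]); }
        bool ext = (tb[i * W + j] & 8) != 0;
        --j;
        if (!ext || j == 0) break;
      }
    } else {  // free-start cell
      break;
    }
  }
  if (want_strings) {
    std::string pa, pb;
    for (long k = 0; k < i; ++k) { pa.push_back(sa[k]); pb.push_back('-'); }
    for (long k = 0; k < j; ++k) { pa.push_back('-'); pb.push_back(sb[k]); }
    pa.append(ra.rbegin(), ra.rend()); pb.append(rb.rbegin(), rb.rend());
    for (long k = bi; k < n; ++k) { pa.push_back(sa[k]); pb.push_back('-'); }
    for (long k = bj; k < m; ++k) { pa.push_back('-'); pb.push_back(sb[k]); }
    out.aligned_a = pa; out.aligned_b = pb;
  }
  return out;
}

// int16 path is safe when scores and sentinel drift stay well inside the
// int16 range
static inline bool fits_int16(long n, long m, int match, int gap_open,
                              int gap_ext) {
  long mx = std::max(n, m);
  return mx <= 4000 && (long)match * std::min(n, m) <= 20000 &&
         std::max(std::max(gap_open, gap_ext), match) <= 64;
}

static AlnOut dp_align_any(const std::vector<uint8_t> &A, const std::string &sa,
                           const std::vector<uint8_t> &B, const std::string &sb,
                           int match, int mismatch, int gap_open, int gap_ext,
                           long dlo, long dhi, bool want_strings) {
  if (fits_int16((long)A.size(), (long)B.size(), match, gap_open, gap_ext) &&
      mismatch >= -64)
    return dp_align<int16_t>(A, sa, B, sb, match, mismatch, gap_open, gap_ext,
                             dlo, dhi, want_strings);
  return dp_align<int>(A, sa, B, sb, match, mismatch, gap_open, gap_ext,
                       dlo, dhi, want_strings);
}

static AlnOut align_adaptive(const std::string &sa, const std::string &sb,
                             int match, int mismatch, int gap_open, int gap_ext,
                             bool want_strings, bool force_full) {
  std::vector<uint8_t> A, B;
  encode(sa, A); encode(sb, B);
  const long n = (long)A.size(), m = (long)B.size();
  if (n == 0 || m == 0) stop("cannot align an empty sequence");
  const long dfull_lo = -n, dfull_hi = m;
  const long mn = std::min(n, m);

  bool certOK = (match > 0 && mismatch <= 0 && gap_open >= 0 && gap_ext >= 0);
  if (force_full || !certOK || (double)n * (double)m <= 262144.0)
    return dp_align_any(A, sa, B, sb, match, mismatch, gap_open, gap_ext,
                        dfull_lo, dfull_hi, want_strings);

  long w;
  if (n == m) {
    long s0 = 0;
    for (long k = 0; k < n; ++k) s0 += (A[k] & B[k]) ? match : mismatch;
    w = std::max(32L, mn - (s0 > 0 ? s0 / match : 0L) + 1);
  } else {
    w = std::max(64L, std::labs(m - n) + 64);
  }

  while (true) {
    long dlo = std::max(std::min(0L, m - n) - w, dfull_lo);
    long dhi = std::min(std::max(0L, m - n) + w, dfull_hi);
    bool full = (dlo <= dfull_lo && dhi >= dfull_hi);
    AlnOut r = dp_align_any(A, sa, B, sb, match, mismatch, gap_open, gap_ext,
                            dlo, dhi, want_strings);
    if (full || r.score >= (long)match * (mn - w)) return r;
    w *= 2;
  }
}

// [[Rcpp::export]]
List cpp_align_pair(std::string a, std::string b, int match, int mismatch,
                    int gap_open, int gap_ext, bool full = false) {
  AlnOut r = align_adaptive(a, b, match, mismatch, gap_open, gap_ext, true, full);
  return List::create(_["score"] = (double)r.score,
                      _["aligned_a"] = r.aligned_a,
                      _["aligned_b"] = r.aligned_b,
                      _["matches"] = r.matches,
                      _["comparable"] = r.comparable);
}

// All-vs-all percent identities under pairwise deletion.  NA when a pair
// has no comparable columns (caller raises the undefined-identity error).
// [[Rcpp::export]]
NumericMatrix cpp_identity_matrix(CharacterVector seqs, int match, int mismatch,
                                  int gap_open, int gap_ext) {
  int n = seqs.size();
  NumericMatrix out(n, n);
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < n; ++i) out(i, i) = 100.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      // canonical operand order: keeps tie-broken tracebacks identical to
      // align_pair(), which orders by residue string
      bool swap = ss[j] < ss[i];
      AlnOut r = align_adaptive(swap ? ss[j] : ss[i], swap ? ss[i] : ss[j],
                                match, mismatch, gap_open, gap_ext,
                                false, false);
      double pid = (r.comparable == 0) ? NA_REAL
                                       : 100.0 * r.matches / r.comparable;
      out(i, j) = pid; out(j, i) = pid;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Cross identities: rows = xs, cols = ys (reference screening).
// [[Rcpp::export]]
NumericMatrix cpp_identity_cross(CharacterVector xs, CharacterVector ys,
                                 int match, int mismatch, int gap_open,
                                 int gap_ext) {
  int n = xs.size(), m = ys.size();
  NumericMatrix out(n, m);
  std::vector<std::string> yss(m);
  for (int j = 0; j < m; ++j) yss[j] = as<std::string>(ys[j]);
  for (int i = 0; i < n; ++i) {
    std::string a = as<std::string>(xs[i]);
    for (int j = 0; j < m; ++j) {
      bool swap = yss[j] < a;
      AlnOut r = align_adaptive(swap ? yss[j] : a, swap ? a : yss[j],
                                match, mismatch, gap_open, gap_ext,
                                false, false);
      out(i, j) = (r.comparable == 0) ? NA_REAL
                                      : 100.0 * r.matches / r.comparable;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
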