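#include <Rcpp.h>
#include <cstring>
#include <climits>
#include <vector>
using namespace Rcpp;

// Affine-gap pairwise alignment over a user-supplied alphabet and scoring
// matrix. One kernel serves three modes:
//   mode 0: global (Needleman-Wunsch)
//   mode 1: local  (Smith-Waterman)
//   mode 2: semiglobal (free terminal gaps in b; a aligned end to end)
// An optional diagonal band (j - i within [band_lo, band_hi]) keeps the
// fragment-vs-window alignments used by ANIb close to linear time; scores
// and traceback are touched only inside the band.
//
// Gap penalties are positive costs; opening a gap of length L costs
// gap_open + L * gap_ext (BLAST-style).

static const double NEG_INF = -1e30;

struct AlnStats {
  double score;
  int n_match, n_mismatch, n_gap_internal, n_gap_lead, n_gap_trail;
  int a_first, a_last, b_first, b_last; // 1-based; 0 if nothing aligned
};

// packed traceback byte per cell:
//   bits 0-1: M origin (0 local start / origin, 1 from M, 2 from X, 3 from Y)
//   bit 2:    X extends (else opens from M)
//   bit 3:    Y extends (else opens from M)

struct AlignWork { // reusable buffers across batch items
  std::vector<double> Mc, Xc, Yc, Mp, Xp, Yp;
  std::vector<unsigned char> tb;
};

static AlnStats align_core(const int *a, int m, const int *b, int n,
                           const double *S, int K,
                           double gap_open, double gap_ext,
                           int mode, int band_lo, int band_hi,
                           AlignWork &wk,
                           std::vector<signed char> *path_out) {
  const size_t W = (size_t)(n + 1);
  wk.Mc.assign(W, NEG_INF); wk.Xc.assign(W, NEG_INF); wk.Yc.assign(W, NEG_INF);
  wk.Mp.assign(W, NEG_INF); wk.Xp.assign(W, NEG_INF); wk.Yp.assign(W, NEG_INF);
  wk.tb.assign((size_t)(m + 1) * W, 0);
  double *Mc = wk.Mc.data(), *Xc = wk.Xc.data(), *Yc = wk.Yc.data();
  double *Mp = wk.Mp.data(), *Xp = wk.Xp.data(), *Yp = wk.Yp.data();
  unsigned char *tb = wk.tb.data();

  const bool banded = band_lo > INT_MIN / 2 || band_hi < INT_MAX / 2;

  // row 0
  Mp[0] = 0.0;
  if (mode == 0) { // global: leading gaps in a penalized (Y state)
    for (int j = 1; j <= n; ++j) {
      Yp[j] = -(gap_open + j * gap_ext);
      if (j > 1) tb[j] |= 8; // Y extends
    }
  } else { // local / semiglobal: free start anywhere along b
    for (int j = 1; j <= n; ++j) Mp[j] = 0.0;
  }

  double best = NEG_INF;
  int best_i = 0, best_j = 0;
  int jlo_prev = 0, jhi_prev = n;

  for (int i = 1; i <= m; ++i) {
    int jlo = 1, jhi = n;
    if (band_lo > INT_MIN / 2) jlo = std::max(1, i + band_lo);
    if (band_hi < INT_MAX / 2) jhi = std::min(n, i + band_hi);
    if (jlo > jhi) { std::swap(Mc, Mp); std::swap(Xc, Xp); std::swap(Yc, Yp); continue; }
    // reset only the touched range (plus sentinels at both edges)
    {
      int lo = std::max(0, jlo - 1), hi = std::min(n, jhi + 1);
      for (int j = lo; j <= hi; ++j) { Mc[j] = NEG_INF; Xc[j] = NEG_INF; Yc[j] = NEG_INF; }
    }
    const size_t rowoff = (size_t)i * W;
    // column 0: gap in b all the way down
    if (jlo == 1) {
      if (mode == 1) {
        Mc[0] = 0.0;
      } else { // global / semiglobal: a consumed against gap, penalized
        Xc[0] = -(gap_open + i * gap_ext);
        if (i > 1) tb[rowoff] |= 4; // X extends
      }
    }
    const int ai = a[i - 1];
    const double *Srow = S + (size_t)ai * K;
    for (int j = jlo; j <= jhi; ++j) {
      unsigned char t = 0;
      // X: gap in b (consume a)
      double x_open = Mp[j] - (gap_open + gap_ext);
      double x_ext = Xp[j] - gap_ext;
      if (x_open >= x_ext) Xc[j] = x_open;
      else { Xc[j] = x_ext; t |= 4; }
      // Y: gap in a (consume b)
      double y_open = Mc[j - 1] - (gap_open + gap_ext);
      double y_ext = Yc[j - 1] - gap_ext;
      if (y_open >= y_ext) Yc[j] = y_open;
      else { Yc[j] = y_ext; t |= 8; }
      // M: diagonal
      double sub = Srow[b[j - 1]];
      double dM = Mp[j - 1], dX = Xp[j - 1], dY = Yp[j - 1];
      double dbest = dM; unsigned char mo = 1;
      if (dX > dbest) { dbest = dX; mo = 2; }
      if (dY > dbest) { dbest = dY; mo = 3; }
      double mval = dbest + sub;
      if (mode == 1 && mval < 0.0) { mval = 0.0; mo = 0; }
      Mc[j] = mval;
      tb[rowoff + j] = (unsigned char)(t | mo);
      if (mode == 1 && mval > best) { best = mval; best_i = i; best_j = j; }
    }
    std::swap(Mc, Mp); std::swap(Xc, Xp); std::swap(Yc, Yp);
    jlo_prev = jlo; jhi_prev = jhi;
  }
  (void)jlo_prev; (void)jhi_prev; (void)banded;

  // choose end state
  int ei = m, ej = n; char estate = 'M';
  if (mode == 1) {
    ei = best_i; ej = best_j; estate = 'M';
    if (best <= 0.0) { AlnStats s{}; s.score = 0.0; return s; }
  } else if (mode == 2) {
    double bb = NEG_INF; int bj = 0; char st = 'M';
    for (int j = 0; j <= n; ++j) {
      if (Mp[j] > bb) { bb = Mp[j]; bj = j; st = 'M'; }
      if (Xp[j] > bb) { bb = Xp[j]; bj = j; st = 'X'; }
    }
    ej = bj; estate = st; best = bb;
  } else {
    double bb = Mp[n]; estate = 'M';
    if (Xp[n] > bb) { bb = Xp[n]; estate = 'X'; }
    if (Yp[n] > bb) { bb = Yp[n]; estate = 'Y'; }
    best = bb;
  }

  // traceback
  AlnStats st{};
  st.score = best;
  int i = ei, j = ej; char state = estate;
  std::vector<signed char> path; // 0 aligned pair, 1 gap in b, 2 gap in a
  while (i > 0 || j > 0) {
    const unsigned char t = tb[(size_t)i * W + j];
    if (state == 'M') {
      const unsigned char mo = t & 3;
      if (i == 0 && j > 0) {
        if (mode == 0) { state = 'Y'; continue; }
        break; // free leading region
      }
      if (i == 0 && j == 0) break;
      if (mode == 1 && mo == 0) break;
      path.push_back(0);
      i -= 1; j -= 1;
      state = (mo == 1) ? 'M' : (mo == 2 ? 'X' : 'Y');
    } else if (state == 'X') {
      path.push_back(1);
      state = (t & 4) ? 'X' : 'M';
      i -= 1;
    } else {
      path.push_back(2);
      state = (t & 8) ? 'Y' : 'M';
      j -= 1;
    }
    if (mode != 0 && i == 0 && state != 'Y') break; // free leading gaps
  }
  int ca = i, cb = j;
  st.a_first = 0; st.b_first = 0; st.a_last = 0; st.b_last = 0;
  int pend_gap = 0; bool seen_pair = false;
  for (int p = (int)path.size() - 1; p >= 0; --p) {
    signed char op = path[p];
    if (op == 0) {
      ca += 1; cb += 1;
      if (!seen_pair) { st.a_first = ca; st.b_first = cb; seen_pair = true; }
      else st.n_gap_internal += pend_gap;
      pend_gap = 0;
      st.a_last = ca; st.b_last = cb;
      if (a[ca - 1] == b[cb - 1]) st.n_match += 1; else st.n_mismatch += 1;
    } else {
      if (op == 1) ca += 1; else cb += 1;
      if (!seen_pair) st.n_gap_lead += 1; else pend_gap += 1;
    }
  }
  st.n_gap_trail = pend_gap;
  if (path_out) path_out->assign(path.rbegin(), path.rend());
  return st;
}

static void build_lut(const std::string &alpha, int *lut) {
  for (int k = 0; k < 256; ++k) lut[k] = -1;
  for (size_t k = 0; k < alpha.size(); ++k) lut[(unsigned char)alpha[k]] = (int)k;
}

static std::vector<int> encode_seq(const std::string &s, const int *lut,
                                   const std::string &ctx) {
  std::vector<int> v(s.size());
  for (size_t k = 0; k < s.size(); ++k) {
    int c = lut[(unsigned char)s[k]];
    if (c < 0)
      stop("character '%s' at position %d not in alphabet (%s)",
           std::string(1, s[k]).c_str(), (int)(k + 1), ctx.c_str());
    v[k] = c;
  }
  return v;
}

// [[Rcpp::export]]
NumericMatrix cpp_align_stats_batch(CharacterVector a, CharacterVector b,
                                    std::string alphabet, NumericMatrix submat,
                                    double gap_open, double gap_ext,
                                    int mode, int band_lo, int band_hi) {
  const int K = (int)alphabet.size();
  if (submat.nrow() != K || submat.ncol() != K)
    stop("scoring matrix must be %d x %d to match the alphabet", K, K);
  if (a.size() != b.size()) stop("a and b must have equal length");
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<double> Srm((size_t)K * K);
  for (int r = 0; r < K; ++r)
    for (int c = 0; c < K; ++c) Srm[(size_t)r * K + c] = submat(r, c);

  int blo = (band_lo == NA_INTEGER) ? INT_MIN / 2 : band_lo;
  int bhi = (band_hi == NA_INTEGER) ? INT_MAX / 2 : band_hi;

  const int np = (int)a.size();
  NumericMatrix out(np, 10);
  colnames(out) = CharacterVector::create("score", "n_match", "n_mismatch",
                                          "n_gap_internal", "n_gap_lead",
                                          "n_gap_trail", "a_first", "a_last",
                                          "b_first", "b_last");
  AlignWork wk;
  for (int p = 0; p < np; ++p) {
    std::string sa = as<std::string>(a[p]);
    std::string sb = as<std::string>(b[p]);
    if (sa.empty() || sb.empty()) stop("empty sequence in pair %d", p + 1);
    std::vector<int> va = encode_seq(sa, lut, "sequence a");
    std::vector<int> vb = encode_seq(sb, lut, "sequence b");
    AlnStats s = align_core(va.data(), (int)va.size(), vb.data(),
                            (int)vb.size(), Srm.data(), K, gap_open, gap_ext,
                            mode, blo, bhi, wk, nullptr);
    out(p, 0) = s.score; out(p, 1) = s.n_match; out(p, 2) = s.n_mismatch;
    out(p, 3) = s.n_gap_internal; out(p, 4) = s.n_gap_lead;
    out(p, 5) = s.n_gap_trail; out(p, 6) = s.a_first; out(p, 7) = s.a_last;
    out(p, 8) = s.b_first; out(p, 9) = s.b_last;
  }
  return out;
}

// Global alignment returning the two gapped strings (center-star merging).
// [[Rcpp::export]]
CharacterVector cpp_align_global_strings(std::string a, std::string b,
                                         std::string alphabet,
                                         NumericMatrix submat, double gap_open,
                                         double gap_ext) {
  const int K = (int)alphabet.size();
  if (submat.nrow() != K || submat.ncol() != K)
    stop("scoring matrix must match alphabet size");
  if (a.empty() || b.empty()) stop("empty sequence");
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<double> Srm((size_t)K * K);
  for (int r = 0; r < K; ++r)
    for (int c = 0; c < K; ++c) Srm[(size_t)r * K + c] = submat(r, c);
  std::vector<int> va = encode_seq(a, lut, "sequence a");
  std::vector<int> vb = encode_seq(b, lut, "sequence b");
  std::vector<signed char> path;
  AlignWork wk;
  align_core(va.data(), (int)va.size(), vb.data(), (int)vb.size(), Srm.data(),
             K, gap_open, gap_ext, 0, INT_MIN / 2, INT_MAX / 2, wk, &path);
  std::string ga, gb;
  ga.reserve(path.size()); gb.reserve(path.size());
  size_t ia = 0, ib = 0;
  for (signed char op : path) {
    if (op == 0) { ga.push_back(a[ia++]); gb.push_back(b[ib++]); }
    else if (op == 1) { ga.push_back(a[ia++]); gb.push_back('-'); }
    else { ga.push_back('-'); gb.push_back(b[ib++]); }
  }
  return CharacterVector::create(ga, gb);
}
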