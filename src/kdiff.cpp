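#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
using namespace Rcpp;

// Column index for a read base: A=0, C=1, G=2, T=3, anything else = N = 4.
static inline int base_index(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return 4;
  }
}

// 4-bit degeneracy encoding of an IUPAC pattern character (A=1,C=2,G=4,T=8).
// 'N' additionally matches a read 'N'; no other code does (an N base call
// carries no evidence, so it only "matches" a fully degenerate pattern slot).
static int iupac_bits(char c) {
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
  case 'N': case 'n': return 1 | 2 | 4 | 8 | 16;
  default: return -1;
  }
}

// mismatch(i, c): pattern position i does NOT accept read base class c
static inline bool mism(const std::vector<int>& pbits, int i, int cidx) {
  if (cidx == 4) return (pbits[i] & 16) == 0;  // read N matches only pattern N
  return (pbits[i] & (1 << cidx)) == 0;
}

static std::vector<int> pattern_bits(const std::string& pattern) {
  std::vector<int> pbits(pattern.size());
  for (size_t i = 0; i < pattern.size(); ++i) {
    int b = iupac_bits(pattern[i]);
    if (b < 0)
      stop("invalid IUPAC character '%s' in pattern at position %d",
           std::string(1, pattern[i]).c_str(), (int)(i + 1));
    pbits[i] = b;
  }
  return pbits;
}

// [[Rcpp::export]]
LogicalMatrix pattern_mask_cpp(std::string pattern) {
  int m = pattern.size();
  if (m < 1) stop("pattern must be non-empty");
  std::vector<int> pbits = pattern_bits(pattern);
  LogicalMatrix mask(m, 5);
  for (int i = 0; i < m; ++i)
    for (int c = 0; c < 5; ++c)
      mask(i, c) = mism(pbits, i, c);
  return mask;
}

static inline int floor_eps(double x) {
  return (int)std::floor(x + 1e-9);
}

// Bit-masked k-difference search with the Ukkonen cutoff.
//
// The column vector is held as a queue-like array of the active cells
// (rows 0..lac of the current DP column); pushing the new top cell each
// column shifts every stored cell one step down its diagonal, and a dead
// mask marks interior cells whose value exceeded k (they are clamped and
// never updated again; by diagonal monotonicity their whole diagonal stays
// dead). Matched cells copy their diagonal precursor and are not recomputed.
//
// Alignment start positions and minimum penalties propagate along the same
// paths: a matched cell inherits from its diagonal; a mismatched cell takes
// the first value-achieving predecessor in the order diagonal, up, left for
// its start, and the minimum over value-achieving predecessors for its
// penalty. This convention is shared with the reference implementation.
//
// [[Rcpp::export]]
List kdiff_search_cpp(std::string read, IntegerVector qual, std::string pattern,
                      double error_ratio, int min_overlap, int k_override,
                      NumericVector penalty_lut, double p_min, double delta) {
  int n = read.size(), m = pattern.size();
  if (m < 1) stop("pattern must be non-empty");
  if (n < 1) stop("read must be non-empty");
  bool weighted = qual.size() > 0;
  if (weighted && qual.size() != n)
    stop("quality vector length (%d) does not match read length (%d)",
         (int)qual.size(), n);
  std::vector<int> pbits = pattern_bits(pattern);

  int k = (k_override >= 0) ? k_override : floor_eps(n * error_ratio);
  if (k > m - 1) k = m - 1;
  const int CLAMP = k + 1;
  const double BIGW = 1e300;

  std::vector<int> Cp(m + 1), Cc(m + 1), Sp(m + 1), Sc(m + 1);
  std::vector<double> Wp(m + 1), Wc(m + 1);
  std::vector<char> Dp(m + 1, 0), Dc(m + 1, 0);

  // column 0: C[i,0] = i (left boundary), alignment starts at read offset 0
  int lac = std::min(m, k);
  for (int i = 0; i <= lac; ++i) { Cp[i] = i; Sp[i] = 0; Wp[i] = i * delta; Dp[i] = 0; }

  std::vector<int> out_start, out_end, out_diff, out_mlen;
  std::vector<double> out_pen;
  double active_total = 0.0;

  for (int j = 1; j <= n; ++j) {
    char rc = read[j - 1];
    int cidx = base_index(rc);
    double mispen = 0.0;
    if (weighted) {
      if (cidx == 4) mispen = p_min;
      else {
        int q = qual[j - 1];
        if (q < 0) q = 0;
        if (q >= penalty_lut.size()) q = penalty_lut.size() - 1;
        mispen = penalty_lut[q];
      }
    }
    int top = std::min(m, lac + 1);
    Cc[0] = 0; Sc[0] = j; Wc[0] = 0.0; Dc[0] = 0;
    for (int i = 1; i <= top; ++i) {
      if (Dp[i - 1]) {                 // dead diagonal stays dead (Lemma 1)
        Dc[i] = 1; Cc[i] = CLAMP; Sc[i] = Sp[i - 1]; Wc[i] = BIGW;
        continue;
      }
      if (!mism(pbits, i - 1, cidx)) { // matched: copy the diagonal precursor
        Dc[i] = 0; Cc[i] = Cp[i - 1]; Sc[i] = Sp[i - 1]; Wc[i] = Wp[i - 1];
        continue;
      }
      int diag = Cp[i - 1] + 1;
      int up   = Cc[i - 1] + 1;        // Dc[i-1] clamp keeps dead preds losing
      int left = (i <= lac && !Dp[i]) ? Cp[i] + 1 : CLAMP + 1;
      int v = diag;
      if (up < v) v = up;
      if (left < v) v = left;
      if (v > k) { Dc[i] = 1; Cc[i] = CLAMP; Sc[i] = Sp[i - 1]; Wc[i] = BIGW; continue; }
      Dc[i] = 0; Cc[i] = v;
      Sc[i] = (diag == v) ? Sp[i - 1] : (up == v ? Sc[i - 1] : Sp[i]);
      if (weighted) {
        double w = BIGW;
        if (diag == v && Wp[i - 1] + mispen < w) w = Wp[i - 1] + mispen;
        if (up   == v && Wc[i - 1] + delta  < w) w = Wc[i - 1] + delta;
        if (left == v && Wp[i] + delta      < w) w = Wp[i] + delta;
        Wc[i] = w;
      } else Wc[i] = 0.0;
    }
    int lc = top;
    while (lc > 0 && (Dc[lc] || Cc[lc] > k)) --lc;
    lac = lc;
    int live = 0;
    for (int i = 0; i <= lac; ++i) if (!Dc[i]) ++live;
    active_total += live;
    if (lac == m) {
      out_start.push_back(Sc[m]); out_end.push_back(j);
      out_diff.push_back(Cc[m]); out_pen.push_back(weighted ? Wc[m] : 0.0);
      out_mlen.push_back(m);
    }
    std::swap(Cp, Cc); std::swap(Sp, Sc); std::swap(Wp, Wc); std::swap(Dp, Dc);
  }

  // extended problem: read suffixes vs pattern prefixes, from the final queue
  for (int i = 1; i <= std::min(lac, m - 1); ++i) {
    if (Dp[i] || Cp[i] > k) continue;
    int L = n - Sp[i];
    if (L < min_overlap) continue;
    if (Cp[i] > floor_eps(L * error_ratio)) continue;
    out_start.push_back(Sp[i]); out_end.push_back(n);
    out_diff.push_back(Cp[i]); out_pen.push_back(weighted ? Wp[i] : 0.0);
    out_mlen.push_back(i);
  }

  return List::create(
    _["start"] = wrap(out_start), _["end"] = wrap(out_end),
    _["differences"] = wrap(out_diff), _["penalty"] = wrap(out_pen),
    _["matched_pattern_length"] = wrap(out_mlen),
    _["k"] = k, _["mean_active"] = active_total / n);
}

// Penalty/difference alignment of x (anchored and fully consumed) against
// prefixes of y (y's tail is free): the pscore kernel. Mismatch penalty is
// P(q) at the read base's quality (the smaller of the two qualities when
// both sides carry them); indels cost delta. Unit-cost differences are
// minimised independently of the penalty path.
//
// [[Rcpp::export]]
List penalty_align_cpp(std::string x, IntegerVector qx,
                       std::string y, IntegerVector qy,
                       NumericVector penalty_lut, double p_min, double delta) {
  int lx = x.size(), ly = y.size();
  if (qx.size() > 0 && qx.size() != lx)
    stop("quality vector length (%d) does not match sequence length (%d)",
         (int)qx.size(), lx);
  if (qy.size() > 0 && qy.size() != ly)
    stop("quality vector length (%d) does not match sequence length (%d)",
         (int)qy.size(), ly);
  bool wx = qx.size() > 0, wy = qy.size() > 0;
  std::vector<int> ybits = pattern_bits(y);

  std::vector<double> Dp(ly + 1), Dc(ly + 1);
  std::vector<int> Up(ly + 1), Uc(ly + 1);
  for (int j = 0; j <= ly; ++j) { Dp[j] = j * delta; Up[j] = j; }
  double best_pen = Dp[0];
  int best_diff = Up[0];
  if (lx == 0) {
    return List::create(_["penalty"] = 0.0, _["differences"] = 0);
  }
  for (int i = 1; i <= lx; ++i) {
    int cidx = base_index(x[i - 1]);
    Dc[0] = i * delta; Uc[0] = i;
    for (int j = 1; j <= ly; ++j) {
      bool mm = mism(ybits, j - 1, cidx);
      double sub;
      if (!mm) sub = 0.0;
      else if (!wx) sub = p_min;  // no qualities: floor penalty
      else if (cidx == 4) sub = p_min;
      else {
        int q = qx[i - 1];
        if (wy && qy[j - 1] < q) q = qy[j - 1];
        if (q < 0) q = 0;
        if (q >= penalty_lut.size()) q = penalty_lut.size() - 1;
        sub = penalty_lut[q];
      }
      double d = Dp[j - 1] + sub;
      if (Dp[j] + delta < d) d = Dp[j] + delta;
      if (Dc[j - 1] + delta < d) d = Dc[j - 1] + delta;
      Dc[j] = d;
      int u = Up[j - 1] + (mm ? 1 : 0);
      if (Up[j] + 1 < u) u = Up[j] + 1;
      if (Uc[j - 1] + 1 < u) u = Uc[j - 1] + 1;
      Uc[j] = u;
    }
    std::swap(Dp, Dc); std::swap(Up, Uc);
  }
  best_pen = Dp[0]; best_diff = Up[0];
  for (int j = 1; j <= ly; ++j) {
    if (Dp[j] < best_pen) best_pen = Dp[j];
    if (Up[j] < best_diff) best_diff = Up[j];
  }
  return List::create(_["penalty"] = best_pen, _["differences"] = best_diff);
}
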