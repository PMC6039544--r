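#include <Rcpp.h>
#include <vector>
#include <cstring>
using namespace Rcpp;

// Affine-gap (Gotoh) global alignment of two DNA strings with identity
// counting on an optimal path. Scoring: match / mismatch per base, a gap of
// length k costs gap_open + k * gap_extend; end gaps are penalized.
// 'N' scores as a mismatch against everything and never counts as a match.
//
// Returns c(matches, cols, score): identical columns and total columns of
// the optimal alignment, optionally after stripping terminal-gap columns.

static const double NEG = -1e18;

static NumericVector nw_core(const std::string &a, const std::string &b,
                             const std::vector<double> &lut,
                             const std::vector<bool> &match_lut,
                             double gap_open, double gap_extend,
                             bool trim_terminal);

// [[Rcpp::export(name = ".nw_counts")]]
NumericVector nw_counts(std::string a, std::string b,
                        double match = 1.0, double mismatch = -1.0,
                        double gap_open = 5.0, double gap_extend = 1.0,
                        bool trim_terminal = true) {
  // 128x128 substitution lookup: match/mismatch with 'N' never matching
  std::vector<double> lut(128 * 128, mismatch);
  std::vector<bool> match_lut(128 * 128, false);
  const std::string bases = "ACGT";
  for (char x : bases) {
    lut[(size_t)x * 128 + x] = match;
    match_lut[(size_t)x * 128 + x] = true;
  }
  return nw_core(a, b, lut, match_lut, gap_open, gap_extend, trim_terminal);
}

// Affine-gap global alignment with an arbitrary substitution matrix
// (rows/cols named by single characters, e.g. BLOSUM62), returning
// c(matches, cols, score) like .nw_counts.
// [[Rcpp::export(name = ".nw_matrix_counts")]]
NumericVector nw_matrix_counts(std::string a, std::string b,
                               NumericMatrix sub, CharacterVector alphabet,
                               double gap_open, double gap_extend,
                               bool trim_terminal = true) {
  std::vector<double> lut(128 * 128, -1e9);
  std::vector<bool> match_lut(128 * 128, false);
  int K = alphabet.size();
  if (sub.nrow() != K || sub.ncol() != K) stop("matrix/alphabet mismatch");
  std::vector<char> chars(K);
  for (int i = 0; i < K; ++i) chars[i] = Rcpp::as<std::string>(alphabet[i])[0];
  for (int i = 0; i < K; ++i) {
    for (int j = 0; j < K; ++j) {
      lut[(size_t)chars[i] * 128 + chars[j]] = sub(i, j);
    }
    match_lut[(size_t)chars[i] * 128 + chars[i]] = (chars[i] != 'X');
  }
  return nw_core(a, b, lut, match_lut, gap_open, gap_extend, trim_terminal);
}

static NumericVector nw_core(const std::string &a, const std::string &b,
                             const std::vector<double> &lut,
                             const std::vector<bool> &match_lut,
                             double gap_open, double gap_extend,
                             bool trim_terminal) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  if ((double)n * (double)m > 4.5e8) stop("pair too large for direct DP");

  // traceback: 2 bits per state per cell (predecessor state 0=M,1=X,2=Y)
  std::vector<unsigned char> tbM((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> tbX((size_t)(n + 1) * (m + 1));
  std::vector<unsigned char> tbY((size_t)(n + 1) * (m + 1));
  std::vector<double> M0(m + 1), X0(m + 1), Y0(m + 1);
  std::vector<double> M1(m + 1), X1(m + 1), Y1(m + 1);

  M0[0] = 0.0; X0[0] = NEG; Y0[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEG; X0[j] = NEG;
    Y0[j] = -gap_open - j * gap_extend;
    tbY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t)i * (m + 1);
    M1[0] = NEG; Y1[0] = NEG;
    X1[0] = -gap_open - i * gap_extend;
    tbX[row] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      double s = lut[(size_t)(unsigned char)a[i - 1] * 128 +
                     (unsigned char)b[j - 1]];
      // M: diagonal
      double bm = M0[j - 1], bx = X0[j - 1], by = Y0[j - 1];
      int st = 0; double best = bm;
      if (bx > best) { best = bx; st = 1; }
      if (by > best) { best = by; st = 2; }
      M1[j] = best + s; tbM[row + j] = (unsigned char)st;
      // X: gap in b (consume a[i])
      double xm = M0[j] - gap_open - gap_extend;
      double xx = X0[j] - gap_extend;
      double xy = Y0[j] - gap_open - gap_extend;
      st = 0; best = xm;
      if (xx > best) { best = xx; st = 1; }
      if (xy > best) { best = xy; st = 2; }
      X1[j] = best; tbX[row + j] = (unsigned char)st;
      // Y: gap in a (consume b[j])
      double ym = M1[j - 1] - gap_open - gap_extend;
      double yx = X1[j - 1] - gap_open - gap_extend;
      double yy = Y1[j - 1] - gap_extend;
      st = 0; best = ym;
      if (yx > best) { best = yx; st = 1; }
      if (yy > best) { best = yy; st = 2; }
      Y1[j] = best; tbY[row + j] = (unsigned char)st;
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }

  int state = 0; double best = M0[m];
  if (X0[m] > best) { best = X0[m]; state = 1; }
  if (Y0[m] > best) { best = Y0[m]; state = 2; }
  double score = best;

  // walk back, recording column types: 0 = aligned pair, 1/2 = gap column
  std::vector<unsigned char> cols_type;
  std::vector<bool> cols_match;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    size_t row = (size_t)i * (m + 1);
    if (state == 0) {
      cols_type.push_back(0);
      cols_match.push_back(match_lut[(size_t)(unsigned char)a[i - 1] * 128 +
                                     (unsigned char)b[j - 1]]);
      state = tbM[row + j];
      --i; --j;
    } else if (state == 1) {
      cols_type.push_back(1);
      cols_match.push_back(false);
      state = tbX[row + j];
      --i;
    } else {
      cols_type.push_back(2);
      cols_match.push_back(false);
      state = tbY[row + j];
      --j;
    }
  }

  int lo = 0, hi = (int)cols_type.size() - 1;
  if (trim_terminal) {
    while (lo <= hi && cols_type[hi] != 0) --hi;   // alignment start
    while (lo <= hi && cols_type[lo] != 0) ++lo;   // alignment end
  }
  int matches = 0, ncols = 0;
  for (int k = lo; k <= hi; ++k) {
    ++ncols;
    if (cols_match[k]) ++matches;
  }
  return NumericVector::create(_["matches"] = matches, _["cols"] = ncols,
                               _["score"] = score);
}
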