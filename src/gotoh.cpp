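#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps, Gotoh three-state
// recursion. A gap of length L costs gap_open + L * gap_ext. State
// transitions between the two gap states are allowed, so the score is the
// unrestricted affine optimum. Traceback is packed into one byte per cell.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_align_cpp")]]
List gotoh_align_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_ext) {
  const size_t n = a.size(), m = b.size();
  if ((double)(n + 1) * (double)(m + 1) > 2.6e8)
    stop("sequences too long for full dynamic programming (%d x %d)",
         (int)n, (int)m);
  if (n == 0 || m == 0) {
    std::string ga(m, '-'), gb(n, '-');
    double sc = (n + m) > 0 ? -(gap_open + gap_ext * (double)(n + m)) : 0.0;
    return List::create(_["score"] = sc,
                        _["a"] = n ? a : ga,
                        _["b"] = n ? gb : b);
  }

  std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  // trace bits: 0-1 M-source, 2-3 X-source, 4-5 Y-source (0=M,1=X,2=Y)
  std::vector<unsigned char> tb((n + 1) * (m + 1), 0);

  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (size_t j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = -(gap_open + gap_ext * (double)j);
    tb[j] |= (unsigned char)(2u << 4); // Y from Y
  }

  for (size_t i = 1; i <= n; ++i) {
    M[0] = NEG_INF; Y[0] = NEG_INF;
    X[0] = -(gap_open + gap_ext * (double)i);
    tb[i * (m + 1)] |= (unsigned char)(1u << 2); // X from X
    const char ai = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      unsigned char t = 0;
      // M: diagonal
      double s = (ai == b[j - 1]) ? match : mismatch;
      double best = Mp[j - 1]; unsigned char src = 0;
      if (Xp[j - 1] > best) { best = Xp[j - 1]; src = 1; }
      if (Yp[j - 1] > best) { best = Yp[j - 1]; src = 2; }
      M[j] = best + s; t |= src;
      // X: gap in b (consume a_i)
      best = Mp[j] - gap_open - gap_ext; src = 0;
      if (Xp[j] - gap_ext > best) { best = Xp[j] - gap_ext; src = 1; }
      if (Yp[j] - gap_open - gap_ext > best) {
        best = Yp[j] - gap_open - gap_ext; src = 2;
      }
      X[j] = best; t |= (unsigned char)(src << 2);
      // Y: gap in a (consume b_j)
      best = M[j - 1] - gap_open - gap_ext; src = 0;
      if (X[j - 1] - gap_open - gap_ext > best) {
        best = X[j - 1] - gap_open - gap_ext; src = 1;
      }
      if (Y[j - 1] - gap_ext > best) { best = Y[j - 1] - gap_ext; src = 2; }
      Y[j] = best; t |= (unsigned char)(src << 4);
      tb[i * (m + 1) + j] = t;
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }

  double sc = Mp[m]; int state = 0;
  if (Xp[m] > sc) { sc = Xp[m]; state = 1; }
  if (Yp[m] > sc) { sc = Yp[m]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  size_t i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char t = tb[i * (m + 1) + j];
    if (state == 0) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      state = t & 3u; --i; --j;
    } else if (state == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      state = (t >> 2) & 3u; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      state = (t >> 4) & 3u; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = sc, _["a"] = ra, _["b"] = rb);
}

// Score-only variant used by the anchored aligner's oracle checks; identical
// recursion without traceback storage, so it handles longer inputs.
// [[Rcpp::export(name = ".gotoh_score_cpp")]]
double gotoh_score_cpp(std::string a, std::string b,
                       double match, double mismatch,
                       double gap_open, double gap_ext) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    return (n + m) > 0 ? -(gap_open + gap_ext * (double)(n + m)) : 0.0;
  std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
  std::vector<double> Mp(m + 1), Xp(m + 1), Yp(m + 1);
  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (size_t j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = -(gap_open + gap_ext * (double)j);
  }
  for (size_t i = 1; i <= n; ++i) {
    M[0] = NEG_INF; Y[0] = NEG_INF;
    X[0] = -(gap_open + gap_ext * (double)i);
    const char ai = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      double s = (ai == b[j - 1]) ? match : mismatch;
      double d = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      M[j] = d + s;
      X[j] = std::max(Mp[j] - gap_open, std::max(Xp[j], Yp[j] - gap_open)) -
             gap_ext;
      Y[j] = std::max(M[j - 1] - gap_open,
                      std::max(X[j - 1] - gap_open, Y[j - 1])) - gap_ext;
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  return std::max(Mp[m], std::max(Xp[m], Yp[m]));
}
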