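#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// LZ76 exhaustive-history phrase count (Kaspar & Schuster scan-and-copy
// formulation). The sequence is parsed left to right; each new phrase is the
// shortest extension of the current suffix that cannot be copied from the
// extended history, with a one-symbol innovation allowed at the end.
// [[Rcpp::export(name = ".lz76Count")]]
int lz76Count(const IntegerVector& s) {
  const int n = s.size();
  if (n == 0) return 0;
  for (int t = 0; t < n; ++t)
    if (s[t] != 0 && s[t] != 1) stop("sequence must be binary (0/1)");
  int c = 1;      // first symbol is always a phrase
  int i = 0;      // history end (phrase start is i)
  int k = 1;      // current extension length
  int l = 1;      // start of the phrase being parsed
  int kmax = 1;
  while (l + k <= n) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
    } else {
      kmax = std::max(k, kmax);
      ++i;
      if (i == l) {         // no copy source left: phrase complete
        ++c;
        l += kmax;
        i = 0;
        k = 1;
        kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  if (k > 1 || l < n) ++c;  // unfinished (reproducible) tail counts once
  return c;
}

// Direct-form-II-transposed IIR filter, applied down each column.
// a[0] must be 1 (the caller normalizes).
// [[Rcpp::export(name = ".iirFilter")]]
NumericMatrix iirFilter(const NumericMatrix& x, const NumericVector& b,
                        const NumericVector& a) {
  const int n = x.nrow(), nc = x.ncol();
  const int nb = b.size(), na = a.size();
  const int nw = std::max(nb, na);
  NumericMatrix y(n, nc);
  std::vector<double> w(nw, 0.0);
  for (int c = 0; c < nc; ++c) {
    std::fill(w.begin(), w.end(), 0.0);
    for (int t = 0; t < n; ++t) {
      const double xt = x(t, c);
      const double yt = b[0] * xt + w[0];
      for (int k = 1; k < nw; ++k) {
        double v = (k < nb ? b[k] * xt : 0.0) - (k < na ? a[k] * yt : 0.0);
        w[k - 1] = v + (k < nw - 1 ? w[k] : 0.0);
      }
      y(t, c) = yt;
    }
  }
  return y;
}

// Approximate entropy, Pincus convention: self-matches included, Chebyshev
// distance, ApEn = Phi^m(r) - Phi^{m+1}(r) with natural logs. Each
// unordered template pair is visited once in a sequential sweep (early
// exit on the first coordinate keeps the common non-matching case cheap).
// [[Rcpp::export(name = ".apenCpp")]]
double apenCpp(const NumericVector& x, const int m, const double r) {
  const int n = x.size();
  if (n <= m + 1) stop("series too short for the requested embedding");
  const int nm  = n - m + 1;   // number of m-templates
  const int nm1 = n - m;       // number of (m+1)-templates
  std::vector<double> cm(nm, 1.0), cm1(nm1, 1.0);  // self-matches
  const double* p = &x[0];
  for (int i = 0; i < nm; ++i) {
    const double xi0 = p[i];
    for (int j = i + 1; j < nm; ++j) {
      double d = std::abs(xi0 - p[j]);
      if (d > r) continue;
      bool ok = true;
      for (int k = 1; k < m; ++k) {
        if (std::abs(p[i + k] - p[j + k]) > r) { ok = false; break; }
      }
      if (!ok) continue;
      cm[i] += 1.0; cm[j] += 1.0;
      if (j < nm1 && i < nm1 && std::abs(p[i + m] - p[j + m]) <= r) {
        cm1[i] += 1.0; cm1[j] += 1.0;
      }
    }
  }
  double phim = 0.0, phim1 = 0.0;
  for (int t = 0; t < nm;  ++t) phim  += std::log(cm[t]  / nm);
  for (int t = 0; t < nm1; ++t) phim1 += std::log(cm1[t] / nm1);
  phim /= nm;
  phim1 /= nm1;
  return phim - phim1;
}
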