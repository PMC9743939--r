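#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy pair counts (Richman & Moorman convention): templates of
// length m+1 starting at i = 0..n-m-1; B counts pairs matching on the first
// m values, A pairs matching on all m+1, Chebyshev distance, self-matches
// excluded. Callers standardise the series and pass the tolerance r.
// [[Rcpp::export(name = ".sampen_counts")]]
NumericVector sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of (m+1)-length templates
  const double *p = REAL(x);
  long long A = 0, B = 0;
  if (m == 2) {
    // branchless specialisation of the common m = 2 case (vectorisable)
    for (int i = 0; i < nt - 1; ++i) {
      const double a0 = p[i], a1 = p[i + 1], a2 = p[i + 2];
      long long bi = 0, ai = 0;
      for (int j = i + 1; j < nt; ++j) {
        const int c1 = std::fabs(a0 - p[j]) <= r;
        const int c2 = std::fabs(a1 - p[j + 1]) <= r;
        const int c3 = std::fabs(a2 - p[j + 2]) <= r;
        bi += c1 & c2;
        ai += c1 & c2 & c3;
      }
      B += bi; A += ai;
    }
  } else {
    for (int i = 0; i < nt - 1; ++i) {
      for (int j = i + 1; j < nt; ++j) {
        bool ok = true;
        for (int k = 0; k < m; ++k) {
          if (std::fabs(p[i + k] - p[j + k]) > r) { ok = false; break; }
        }
        if (!ok) continue;
        ++B;
        if (std::fabs(p[i + m] - p[j + m]) <= r) ++A;
      }
    }
  }
  return NumericVector::create((double)A, (double)B);
}

// Lempel-Ziv 1976 phrase count by the Kaspar-Schuster scheme: scan the
// sequence, extending the current phrase while it reproduces (with at most
// one-symbol lookahead) a substring of everything seen so far.
// [[Rcpp::export(name = ".lz76_count")]]
int lz76_count(IntegerVector s) {
  const int n = s.size();
  if (n == 0) return 0;
  if (n == 1) return 1;
  int c = 1;   // first symbol is the first phrase
  int i = 0;   // start of parsed prefix considered for copying
  int k = 1;   // current extension length
  int l = 1;   // start of the phrase currently being built
  int kmax = 1;
  while (true) {
    if (s[i + k - 1] == s[l + k - 1]) {
      ++k;
      if (l + k > n) { ++c; break; }
    } else {
      if (k > kmax) kmax = k;
      ++i;
      if (i == l) {           // no earlier match: phrase complete
        ++c;
        l += kmax;
        if (l + 1 > n) break;
        i = 0; k = 1; kmax = 1;
      } else {
        k = 1;
      }
    }
  }
  return c;
}
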