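#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov chain sampler over the 4 DNA bases.
// States are 1..4 (A,C,G,T). Uses R's RNG so set.seed() governs output.
// [[Rcpp::export]]
IntegerVector cpp_markov_sample(int n, NumericVector p0, NumericMatrix P) {
  if (n <= 0) return IntegerVector(0);
  if (p0.size() != 4 || P.nrow() != 4 || P.ncol() != 4)
    stop("p0 must have length 4 and P must be 4x4");
  double c0[4];
  double cum[4][4];
  double acc = 0.0;
  for (int j = 0; j < 4; ++j) { acc += p0[j]; c0[j] = acc; }
  for (int i = 0; i < 4; ++i) {
    acc = 0.0;
    for (int j = 0; j < 4; ++j) { acc += P(i, j); cum[i][j] = acc; }
  }
  IntegerVector out(n);
  double u = unif_rand();
  int s = 0;
  while (s < 3 && u > c0[s]) ++s;
  out[0] = s + 1;
  for (int i = 1; i < n; ++i) {
    u = unif_rand();
    int j = 0;
    while (j < 3 && u > cum[s][j]) ++j;
    s = j;
    out[i] = s + 1;
  }
  return out;
}

// Exhaustive ungapped scan: report every offset where the pattern aligns to
// the subject with at most max_mm mismatches. Subject codes are 1..4 with 0
// for N; an N position always counts as a mismatch. Early abort makes the
// expected per-offset work O(max_mm) on background sequence.
// Returned starts are 0-based.
// [[Rcpp::export]]
List cpp_hamming_hits(IntegerVector subject, IntegerVector pattern, int max_mm) {
  const int n = subject.size(), m = pattern.size();
  if (m == 0) stop("empty pattern");
  std::vector<int> starts, mms;
  for (int i = 0; i + m <= n; ++i) {
    int mm = 0;
    for (int j = 0; j < m; ++j) {
      if (subject[i + j] != pattern[j] && ++mm > max_mm) break;
    }
    if (mm <= max_mm) { starts.push_back(i); mms.push_back(mm); }
  }
  return List::create(_["start"] = wrap(starts), _["mismatches"] = wrap(mms));
}
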