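#include <Rcpp.h>
using namespace Rcpp;

// Global Needleman-Wunsch alignment of a bisulfite clone read against its
// reference region. Scoring: match +1, mismatch -1, linear gap -2, with the
// bisulfite-specific asymmetry that reference C aligned to read T counts as
// a match (unmethylated cytosines read as T after conversion). Traceback
// prefers diagonal, then a gap in the read, then a gap in the reference,
// which makes the alignment deterministic.
//
// [[Rcpp::export]]
List nw_bisulfite_align(std::string ref, std::string read,
                        double match = 1.0, double mismatch = -1.0,
                        double gap = -2.0) {
  const int n = ref.size(), m = read.size();
  NumericMatrix S(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 0 diag, 1 up (gap in read), 2 left
  for (int i = 1; i <= n; ++i) { S(i, 0) = i * gap; P(i, 0) = 1; }
  for (int j = 1; j <= m; ++j) { S(0, j) = j * gap; P(0, j) = 2; }
  for (int i = 1; i <= n; ++i) {
    const char a = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char b = read[j - 1];
      const bool is_match = (a == b) || (a == 'C' && b == 'T');
      const double diag = S(i - 1, j - 1) + (is_match ? match : mismatch);
      const double up = S(i - 1, j) + gap;
      const double left = S(i, j - 1) + gap;
      double best = diag; int ptr = 0;
      if (up > best) { best = up; ptr = 1; }
      if (left > best) { best = left; ptr = 2; }
      S(i, j) = best; P(i, j) = ptr;
    }
  }
  std::string aref, aread;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int ptr = (i == 0) ? 2 : (j == 0) ? 1 : P(i, j);
    if (ptr == 0) { aref += ref[i - 1]; aread += read[j - 1]; --i; --j; }
    else if (ptr == 1) { aref += ref[i - 1]; aread += '-'; --i; }
    else { aref += '-'; aread += read[j - 1]; --j; }
  }
  std::reverse(aref.begin(), aref.end());
  std::reverse(aread.begin(), aread.end());
  int matches = 0;
  for (size_t k = 0; k < aref.size(); ++k) {
    const char a = aref[k], b = aread[k];
    if (a != '-' && b != '-' && ((a == b) || (a == 'C' && b == 'T'))) ++matches;
  }
  return List::create(_["aligned_ref"] = aref, _["aligned_read"] = aread,
                      _["score"] = S(n, m),
                      _["identity"] = (double)matches / (double)aref.size());
}
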