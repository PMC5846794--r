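#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Weighted running-sum enrichment score of a hit set inside a ranking of
// length P. Hits carry weight (P+1-r)^w at rank r (normalised over hits),
// misses decrement by 1/(P-s). The score is the running-sum value of
// largest magnitude, signed; ties in magnitude resolve to the positive
// extreme so that a set occupying the exact top of the ranking scores +1.
static double es_from_hits(std::vector<int> &hits, int P, double w) {
  const int s = (int)hits.size();
  std::sort(hits.begin(), hits.end());
  double V = 0.0;
  std::vector<double> v(s);
  for (int i = 0; i < s; ++i) {
    v[i] = (w == 0.0) ? 1.0 : std::pow((double)(P + 1 - hits[i]), w);
    V += v[i];
  }
  const double missdec = 1.0 / (double)(P - s);
  double cum = 0.0, maxpos = 0.0, minneg = 0.0;
  for (int i = 0; i < s; ++i) {
    const double miss = (double)(hits[i] - 1 - i) * missdec;
    const double before = cum - miss;        // running sum just before the hit
    if (before < minneg) minneg = before;
    cum += v[i] / V;
    const double at = cum - miss;            // running sum at the hit
    if (at > maxpos) maxpos = at;
    if (at < minneg) minneg = at;
  }
  // positive extreme preferred on (near-)ties, robust to summation noise
  return (maxpos + minneg >= -1e-12) ? maxpos : minneg;
}

// [[Rcpp::export(name = ".es_score_cpp")]]
double es_score_cpp(IntegerVector hit_ranks, int P, double w) {
  std::vector<int> hits(hit_ranks.begin(), hit_ranks.end());
  return es_from_hits(hits, P, w);
}

static double es_of_slice(const IntegerMatrix &ord, const IntegerMatrix &pos,
                          int a, int b, int from, int len, double w) {
  // ES of subject a's ranking slice [from, from+len) evaluated inside
  // subject b's ranking
  const int P = ord.ncol();
  std::vector<int> hits(len);
  for (int j = 0; j < len; ++j) hits[j] = pos(b, ord(a, from + j) - 1);
  return es_from_hits(hits, P, w);
}

// Pairwise signature distances between subject sets A and B.
// ord: subjects x P protein index (1-based) in descending-value rank order;
// pos: subjects x P rank of each protein (inverse permutation of ord).
// The similarity averages the defined terms of
//   [ ES(topA|B) - ES(botA|B) + ES(topB|A) - ES(botB|A) ] and maps to a
// distance via d = (1 - s) / 2.
// [[Rcpp::export(name = ".signature_distances_cpp")]]
NumericMatrix signature_distances_cpp(IntegerMatrix ord, IntegerMatrix pos,
                                      IntegerVector idxA, IntegerVector idxB,
                                      int n1, int n2, double w) {
  const int P = ord.ncol();
  const int nA = idxA.size(), nB = idxB.size();
  NumericMatrix out(nA, nB);
  const int nterms = 2 * ((n1 > 0) + (n2 > 0));
  if (nterms == 0) stop("signature is empty (n1 + n2 must be >= 1)");
  if (n1 >= P || n2 >= P || n1 + n2 > P)
    stop("signature lengths incompatible with the ranking length");
  for (int i = 0; i < nA; ++i) {
    const int a = idxA[i] - 1;
    for (int j = 0; j < nB; ++j) {
      const int b = idxB[j] - 1;
      double s = 0.0;
      if (n1 > 0) {
        s += es_of_slice(ord, pos, a, b, 0, n1, w);
        s += es_of_slice(ord, pos, b, a, 0, n1, w);
      }
      if (n2 > 0) {
        s -= es_of_slice(ord, pos, a, b, P - n2, n2, w);
        s -= es_of_slice(ord, pos, b, a, P - n2, n2, w);
      }
      double d = (1.0 - s / (double)nterms) / 2.0;
      if (d < 0.0) d = 0.0;
      if (d > 1.0) d = 1.0;
      out(i, j) = d;
    }
  }
  return out;
}
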