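#include <Rcpp.h>
using namespace Rcpp;

// Paths are passed as integer vectors of genotype codes (bit patterns over
// L <= 25 loci), so Hamming distance is a popcount of the XOR.

static inline int ham(int a, int b) {
  unsigned int x = (unsigned int)(a ^ b);
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0;
  while (x) { c += x & 1u; x >>= 1; }
  return c;
#endif
}

// Symmetrized mean of per-point minimum Hamming distances:
// d(p1,p2) = (sum_{x in p1} min_{y in p2} H(x,y) +
//             sum_{y in p2} min_{x in p1} H(x,y)) / (|p1| + |p2|),
// |p| counting points.
static double interpath(const std::vector<int>& a, const std::vector<int>& b) {
  double s = 0.0;
  for (size_t i = 0; i < a.size(); ++i) {
    int m = INT_MAX;
    for (size_t j = 0; j < b.size(); ++j) {
      int d = ham(a[i], b[j]);
      if (d < m) m = d;
    }
    s += m;
  }
  for (size_t j = 0; j < b.size(); ++j) {
    int m = INT_MAX;
    for (size_t i = 0; i < a.size(); ++i) {
      int d = ham(a[i], b[j]);
      if (d < m) m = d;
    }
    s += m;
  }
  return s / (double)(a.size() + b.size());
}

// [[Rcpp::export]]
double cpp_inter_path_distance(IntegerVector p1, IntegerVector p2) {
  std::vector<int> a(p1.begin(), p1.end()), b(p2.begin(), p2.end());
  return interpath(a, b);
}

// Probability-weighted pairwise divergence over an ensemble.
// Returns (sum_{i<j} Pi Pj d_ij, sum_{i<j} Pi Pj, max_{i<j} d_ij).
// [[Rcpp::export]]
NumericVector cpp_ensemble_divergence(List path_codes, NumericVector probs) {
  int m = path_codes.size();
  std::vector< std::vector<int> > pc(m);
  for (int i = 0; i < m; ++i) {
    IntegerVector v = path_codes[i];
    pc[i].assign(v.begin(), v.end());
  }
  double raw = 0.0, wsum = 0.0, maxd = 0.0;
  for (int i = 0; i < m; ++i) {
    for (int j = i + 1; j < m; ++j) {
      double d = interpath(pc[i], pc[j]);
      double w = probs[i] * probs[j];
      raw += w * d;
      wsum += w;
      if (d > maxd) maxd = d;
    }
  }
  return NumericVector::create(raw, wsum, maxd);
}
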