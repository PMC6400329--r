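#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Deterministic, platform-independent RNG (splitmix64 seeded xorshift64*),
// so that training is bit-reproducible given a seed, independently of R's RNG.
namespace {

struct XRng {
  uint64_t s;
  explicit XRng(uint64_t seed) {
    // splitmix64 scrambling of the seed
    uint64_t z = seed + 0x9e3779b97f4a7c15ULL;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    s = z ^ (z >> 31);
    if (s == 0) s = 0x1234567887654321ULL;
  }
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545f4914f6cdd1dULL;
  }
  double unif() { // in [0,1)
    return (next() >> 11) * (1.0 / 9007199254740992.0);
  }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// cumulative table over counts^0.75 for negative sampling
std::vector<double> neg_cumul(const NumericVector& counts) {
  std::vector<double> cum(counts.size());
  double acc = 0.0;
  for (int i = 0; i < counts.size(); ++i) {
    acc += std::pow(counts[i], 0.75);
    cum[i] = acc;
  }
  for (auto& v : cum) v /= acc;
  return cum;
}

int sample_neg(const std::vector<double>& cum, XRng& rng) {
  double u = rng.unif();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// one SGD pass over a token for a given document vector
inline void sgd_step(std::vector<double>& dvec, std::vector<double>& syn1,
                     int vocab, int dim, int target, int negative,
                     const std::vector<double>& cum, double alpha,
                     XRng& rng, std::vector<double>& grad, bool update_words) {
  std::fill(grad.begin(), grad.end(), 0.0);
  for (int n = 0; n <= negative; ++n) {
    int w; double label;
    if (n == 0) { w = target; label = 1.0; }
    else {
      w = sample_neg(cum, rng);
      if (w == target) continue;
      label = 0.0;
    }
    double* wv = &syn1[(size_t)w * dim];
    double f = 0.0;
    for (int k = 0; k < dim; ++k) f += dvec[k] * wv[k];
    double g = (label - sigmoid(f)) * alpha;
    for (int k = 0; k < dim; ++k) grad[k] += g * wv[k];
    if (update_words)
      for (int k = 0; k < dim; ++k) wv[k] += g * dvec[k];
  }
  for (int k = 0; k < dim; ++k) dvec[k] += grad[k];
}

// subsampling keep-probability, word2vec convention
inline double keep_prob(double count, double total, double t) {
  if (t <= 0.0) return 1.0;
  double f = count / total;
  if (f <= t) return 1.0;
  return (std::sqrt(f / t) + 1.0) * t / f;
}

} // namespace

// Train PV-DBOW document and word vectors.
// docs: list of 0-based integer vectors (word indices into the vocabulary);
// counts: corpus frequency of each vocabulary word.
// Returns list(doc_vectors, word_vectors).
// [[Rcpp::export(name = ".pvdbow_train_cpp")]]
List pvdbow_train_cpp(List docs, NumericVector counts, int dim, int epochs,
                      int negative, double subsample, double alpha,
                      double min_alpha, double seed) {
  const int ndoc = docs.size();
  const int vocab = counts.size();
  XRng rng((uint64_t)seed);

  double total = 0.0;
  for (int i = 0; i < vocab; ++i) total += counts[i];
  std::vector<double> cum = neg_cumul(counts);

  std::vector<std::vector<int>> dv(ndoc);
  size_t ntok = 0;
  for (int d = 0; d < ndoc; ++d) {
    IntegerVector v = docs[d];
    dv[d].assign(v.begin(), v.end());
    ntok += v.size();
  }

  // init: doc vectors small uniform, word output vectors zero
  std::vector<double> docm((size_t)ndoc * dim), syn1((size_t)vocab * dim, 0.0);
  for (auto& x : docm) x = (rng.unif() - 0.5) / dim;

  const double span = (double)epochs * (double)std::max<size_t>(ntok, 1);
  double seen = 0.0;
  std::vector<double> grad(dim), dvec(dim);

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < ndoc; ++d) {
      double* dp = &docm[(size_t)d * dim];
      std::copy(dp, dp + dim, dvec.begin());
      for (int target : dv[d]) {
        double a = alpha - (alpha - min_alpha) * (seen / span);
        seen += 1.0;
        if (subsample > 0.0 &&
            rng.unif() > keep_prob(counts[target], total, subsample))
          continue;
        sgd_step(dvec, syn1, vocab, dim, target, negative, cum, a, rng,
                 grad, true);
      }
      std::copy(dvec.begin(), dvec.end(), dp);
    }
  }

  NumericMatrix dm(ndoc, dim), wm(vocab, dim);
  for (int d = 0; d < ndoc; ++d)
    for (int k = 0; k < dim; ++k) dm(d, k) = docm[(size_t)d * dim + k];
  for (int w = 0; w < vocab; ++w)
    for (int k = 0; k < dim; ++k) wm(w, k) = syn1[(size_t)w * dim + k];
  return List::create(_["doc_vectors"] = dm, _["word_vectors"] = wm);
}

// Infer a vector for one document against frozen word vectors.
// The per-document seed must be supplied by the caller (derived from the
// inference seed and the token content) so identical documents map to
// identical vectors.
// [[Rcpp::export(name = ".pvdbow_infer_cpp")]]
NumericVector pvdbow_infer_cpp(IntegerVector doc, NumericMatrix word_vectors,
                               NumericVector counts, int epochs, int negative,
                               double alpha, double min_alpha, double seed) {
  const int dim = word_vectors.ncol();
  const int vocab = word_vectors.nrow();
  XRng rng((uint64_t)seed);
  std::vector<double> cum = neg_cumul(counts);
  std::vector<double> syn1((size_t)vocab * dim);
  for (int w = 0; w < vocab; ++w)
    for (int k = 0; k < dim; ++k) syn1[(size_t)w * dim + k] = word_vectors(w, k);

  std::vector<double> dvec(dim), grad(dim);
  for (auto& x : dvec) x = (rng.unif() - 0.5) / dim;

  const double span = (double)epochs * (double)std::max(doc.size(), R_xlen_t(1));
  double seen = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int t : doc) {
      double a = alpha - (alpha - min_alpha) * (seen / span);
      seen += 1.0;
      sgd_step(dvec, syn1, vocab, dim, t, negative, cum, a, rng, grad, false);
    }
  }
  return NumericVector(dvec.begin(), dvec.end());
}

// FNV-1a hash of an integer token sequence, folded into [0, 2^53)
// so it survives the round-trip through an R double.
// [[Rcpp::export(name = ".token_hash_cpp")]]
double token_hash_cpp(IntegerVector tokens) {
  uint64_t h = 1469598103934665603ULL;
  for (int t : tokens) {
    for (int b = 0; b < 4; ++b) {
      h ^= (uint64_t)((t >> (8 * b)) & 0xff);
      h *= 1099511628211ULL;
    }
  }
  return (double)(h >> 11);
}
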