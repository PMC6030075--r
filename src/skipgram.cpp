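// Skip-gram word embedding training with negative sampling.
// Single-threaded with an internal xorshift RNG so that a given seed
// always yields identical vectors.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s << 13;
    s ^= s >> 7;
    s ^= s << 17;
    return s;
  }
  // uniform in [0,1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t bounded(uint64_t n) { return next() % n; }
};

inline double sigmoid(double x) {
  if (x > 8.0) return 1.0;
  if (x < -8.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix sg_train_cpp(List sentences, int vocab_size,
                           NumericVector counts, int dim, int window,
                           int negative, int epochs, double alpha,
                           double min_alpha, double sample_power, int seed) {
  XorShift rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // unigram table for negative sampling, counts^sample_power
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  {
    double total = 0.0;
    std::vector<double> pw(vocab_size);
    for (int i = 0; i < vocab_size; ++i) {
      pw[i] = std::pow(counts[i], sample_power);
      total += pw[i];
    }
    int i = 0;
    double cum = pw[0] / total;
    for (int a = 0; a < table_size; ++a) {
      table[a] = i;
      if (static_cast<double>(a) / table_size > cum && i < vocab_size - 1) {
        ++i;
        cum += pw[i] / total;
      }
    }
  }

  std::vector<double> syn0(static_cast<size_t>(vocab_size) * dim);
  std::vector<double> syn1(static_cast<size_t>(vocab_size) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // pre-convert sentences
  std::vector<std::vector<int> > sents;
  sents.reserve(sentences.size());
  long long total_words = 0;
  for (int s = 0; s < sentences.size(); ++s) {
    IntegerVector iv = sentences[s];
    std::vector<int> v(iv.begin(), iv.end());
    total_words += static_cast<long long>(v.size());
    sents.push_back(v);
  }
  const long long train_total = total_words * static_cast<long long>(epochs);

  std::vector<double> neu1e(dim);
  long long processed = 0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (size_t s = 0; s < sents.size(); ++s) {
      const std::vector<int>& sen = sents[s];
      const int len = static_cast<int>(sen.size());
      for (int i = 0; i < len; ++i) {
        const double lr = std::max(
            min_alpha,
            alpha * (1.0 - static_cast<double>(processed) / (train_total + 1)));
        ++processed;
        const int center = sen[i];
        // dynamic window: effective half-width in [1, window]
        const int b = static_cast<int>(rng.bounded(static_cast<uint64_t>(window)));
        const int w = window - b;
        for (int j = i - w; j <= i + w; ++j) {
          if (j == i || j < 0 || j >= len) continue;
          const int context = sen[j];
          double* v_in = &syn0[static_cast<size_t>(context) * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int d = 0; d < negative + 1; ++d) {
            int target;
            double label;
            if (d == 0) {
              target = center;
              label = 1.0;
            } else {
              target = table[rng.bounded(table_size)];
              if (target == center) continue;
              label = 0.0;
            }
            double* v_out = &syn1[static_cast<size_t>(target) * dim];
            double f = 0.0;
            for (int k = 0; k < dim; ++k) f += v_in[k] * v_out[k];
            const double g = (label - sigmoid(f)) * lr;
            for (int k = 0; k < dim; ++k) neu1e[k] += g * v_out[k];
            for (int k = 0; k < dim; ++k) v_out[k] += g * v_in[k];
          }
          for (int k = 0; k < dim; ++k) v_in[k] += neu1e[k];
        }
      }
    }
  }

  NumericMatrix out(vocab_size, dim);
  for (int i = 0; i < vocab_size; ++i)
    for (int k = 0; k < dim; ++k)
      out(i, k) = syn0[static_cast<size_t>(i) * dim + k];
  return out;
}
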