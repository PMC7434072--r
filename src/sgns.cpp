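// Skip-gram with negative sampling, single-threaded and fully seeded.
// Follows the reference word2vec recipe: dynamic context window, unigram^0.75
// negative-sampling table, frequent-word subsampling, linear learning-rate
// decay over epochs * corpus size.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// word2vec's own 64-bit LCG keeps training deterministic across platforms
struct Lcg {
  uint64_t state;
  explicit Lcg(uint64_t seed) : state(seed) {}
  uint64_t next() {
    state = state * 6364136223846793005ULL + 1442695040888963407ULL;
    return state;
  }
  // uniform in [0, 1)
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform integer in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
};

inline double sigmoid(double x) {
  if (x > 6.0) return 1.0;
  if (x < -6.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

} // namespace

// [[Rcpp::export(name = ".cpp_train_sgns")]]
NumericMatrix cpp_train_sgns(List sequences, NumericVector vocab_counts,
                             int dim, int window, int negative, int epochs,
                             double alpha, double sample, int seed) {
  const int V = vocab_counts.size();
  Lcg rng(static_cast<uint64_t>(seed) * 2654435761ULL + 1ULL);

  // input (target) and output (context) weights
  std::vector<double> syn0(static_cast<size_t>(V) * dim);
  std::vector<double> syn1(static_cast<size_t>(V) * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  // unigram^0.75 table for negative sampling
  const int table_size = 1 << 20;
  std::vector<int> table(table_size);
  double norm = 0.0;
  for (int v = 0; v < V; ++v) norm += std::pow(vocab_counts[v], 0.75);
  {
    int v = 0;
    double cum = std::pow(vocab_counts[0], 0.75) / norm;
    for (int i = 0; i < table_size; ++i) {
      table[i] = v;
      if ((i + 1.0) / table_size > cum && v < V - 1) {
        ++v;
        cum += std::pow(vocab_counts[v], 0.75) / norm;
      }
    }
  }

  double total_count = 0.0;
  for (int v = 0; v < V; ++v) total_count += vocab_counts[v];
  // subsampling keep-probability per word (word2vec formula)
  std::vector<double> keep(V, 1.0);
  if (sample > 0) {
    for (int v = 0; v < V; ++v) {
      double f = vocab_counts[v] / total_count;
      double k = (std::sqrt(f / sample) + 1.0) * sample / f;
      keep[v] = k < 1.0 ? k : 1.0;
    }
  }

  double words_total = 0.0;
  for (int d = 0; d < sequences.size(); ++d)
    words_total += static_cast<IntegerVector>(sequences[d]).size();
  const double train_total = words_total * epochs + 1.0;
  const double min_alpha = alpha * 0.0001;

  std::vector<double> neu1e(dim);
  std::vector<int> sent;
  double words_done = 0.0;

  for (int ep = 0; ep < epochs; ++ep) {
    for (int d = 0; d < sequences.size(); ++d) {
      IntegerVector doc = sequences[d];
      sent.clear();
      for (int i = 0; i < doc.size(); ++i) {
        ++words_done;
        int w = doc[i];
        if (w < 0 || w >= V) continue;
        if (keep[w] < 1.0 && rng.unif() > keep[w]) continue;
        sent.push_back(w);
      }
      const int n = static_cast<int>(sent.size());
      for (int i = 0; i < n; ++i) {
        double lr = alpha * (1.0 - words_done / train_total);
        if (lr < min_alpha) lr = min_alpha;
        const int target = sent[i];
        const int b = static_cast<int>(rng.below(window)); // shrunk window
        for (int j = i - window + b; j <= i + window - b; ++j) {
          if (j == i || j < 0 || j >= n) continue;
          const int context = sent[j];
          double *v_in = &syn0[static_cast<size_t>(context) * dim];
          std::fill(neu1e.begin(), neu1e.end(), 0.0);
          for (int k = 0; k <= negative; ++k) {
            int label, out_word;
            if (k == 0) {
              out_word = target;
              label = 1;
            } else {
              out_word = table[rng.below(table_size)];
              if (out_word == target) continue;
              label = 0;
            }
            double *v_out = &syn1[static_cast<size_t>(out_word) * dim];
            double dot = 0.0;
            for (int c = 0; c < dim; ++c) dot += v_in[c] * v_out[c];
            const double g = (label - sigmoid(dot)) * lr;
            for (int c = 0; c < dim; ++c) neu1e[c] += g * v_out[c];
            for (int c = 0; c < dim; ++c) v_out[c] += g * v_in[c];
          }
          for (int c = 0; c < dim; ++c) v_in[c] += neu1e[c];
        }
      }
    }
    Rcpp::checkUserInterrupt();
  }

  NumericMatrix out(V, dim);
  for (int v = 0; v < V; ++v)
    for (int c = 0; c < dim; ++c)
      out(v, c) = syn0[static_cast<size_t>(v) * dim + c];
  return out;
}
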