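// Skip-gram with negative sampling, single-threaded and deterministic.
// Two entry points: a window-based trainer over tokenized sentences (n-gram
// embeddings) and a pair-based trainer over explicit (word, context) pairs
// (dependency embeddings). Negative contexts are drawn from the unigram^0.75
// distribution. All randomness comes from a private xorshift64* stream seeded
// from R, so results are bit-reproducible per seed.
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
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  // uniform in [0, n)
  uint64_t below(uint64_t n) { return next() % n; }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

inline double sigmoid(double x) {
  if (x > 30.0) return 1.0;
  if (x < -30.0) return 0.0;
  return 1.0 / (1.0 + std::exp(-x));
}

// cumulative unigram^0.75 table for negative sampling via binary search
std::vector<double> neg_cdf(const std::vector<double>& counts) {
  std::vector<double> cdf(counts.size());
  double acc = 0.0;
  for (size_t i = 0; i < counts.size(); ++i) {
    acc += std::pow(counts[i], 0.75);
    cdf[i] = acc;
  }
  return cdf;
}

int sample_cdf(const std::vector<double>& cdf, XorShift& rng) {
  double u = rng.unif() * cdf.back();
  int lo = 0, hi = (int)cdf.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cdf[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// one positive (w, c) update plus `negatives` sampled negatives; returns loss
double sgns_update(std::vector<double>& syn0, std::vector<double>& syn1,
                   int w, int c, int dim, double alpha, int negatives,
                   const std::vector<double>& cdf, int n_ctx, XorShift& rng,
                   std::vector<double>& work) {
  double* v = &syn0[(size_t)w * dim];
  std::fill(work.begin(), work.end(), 0.0);
  double loss = 0.0;
  for (int k = 0; k <= negatives; ++k) {
    int target;
    double label;
    if (k == 0) { target = c; label = 1.0; }
    else {
      target = sample_cdf(cdf, rng);
      if (target == c) continue;
      label = 0.0;
    }
    double* u = &syn1[(size_t)target * dim];
    double dot = 0.0;
    for (int d = 0; d < dim; ++d) dot += v[d] * u[d];
    double pred = sigmoid(dot);
    double g = (label - pred) * alpha;
    loss += label > 0.5 ? -std::log(std::max(pred, 1e-10))
                        : -std::log(std::max(1.0 - pred, 1e-10));
    for (int d = 0; d < dim; ++d) work[d] += g * u[d];
    for (int d = 0; d < dim; ++d) u[d] += g * v[d];
  }
  for (int d = 0; d < dim; ++d) v[d] += work[d];
  (void)n_ctx;
  return loss;
}

} // namespace

// [[Rcpp::export]]
List sgns_train_corpus_cpp(List sentences, NumericVector counts, int dim,
                           int window, int epochs, double lr, double subsample,
                           int negatives, int seed) {
  int vocab = counts.size();
  XorShift rng((uint64_t)seed * 2654435761ULL + 1ULL);
  std::vector<double> cnt(counts.begin(), counts.end());
  double total = 0.0;
  for (double x : cnt) total += x;
  std::vector<double> cdf = neg_cdf(cnt);

  // discard probability for frequent-word subsampling
  std::vector<double> keep(vocab, 1.0);
  if (subsample > 0) {
    for (int i = 0; i < vocab; ++i) {
      double f = cnt[i] / total;
      if (f > subsample) keep[i] = std::sqrt(subsample / f);
    }
  }

  std::vector<std::vector<int> > sents;
  sents.reserve(sentences.size());
  for (int i = 0; i < sentences.size(); ++i) {
    IntegerVector s = sentences[i];
    sents.push_back(std::vector<int>(s.begin(), s.end()));
  }

  std::vector<double> syn0((size_t)vocab * dim), syn1((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<double> work(dim);
  NumericVector epoch_loss(epochs);
  double words_total = total * epochs;
  double words_done = 0.0;
  std::vector<int> kept;
  for (int ep = 0; ep < epochs; ++ep) {
    double loss = 0.0; long npairs = 0;
    for (size_t si = 0; si < sents.size(); ++si) {
      kept.clear();
      for (int w : sents[si]) {
        words_done += 1.0;
        if (keep[w] >= 1.0 || rng.unif() < keep[w]) kept.push_back(w);
      }
      int n = (int)kept.size();
      for (int i = 0; i < n; ++i) {
        int b = 1 + (int)rng.below((uint64_t)window); // dynamic window
        double alpha = lr * std::max(1e-4, 1.0 - words_done / words_total);
        for (int j = i - b; j <= i + b; ++j) {
          if (j < 0 || j >= n || j == i) continue;
          loss += sgns_update(syn0, syn1, kept[i], kept[j], dim, alpha,
                              negatives, cdf, vocab, rng, work);
          ++npairs;
        }
      }
    }
    epoch_loss[ep] = npairs > 0 ? loss / npairs : 0.0;
  }

  NumericMatrix out(vocab, dim);
  for (int i = 0; i < vocab; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  return List::create(_["vectors"] = out, _["loss"] = epoch_loss);
}

// [[Rcpp::export]]
List sgns_train_pairs_cpp(IntegerVector words, IntegerVector ctxs,
                          int n_words, int n_ctx, NumericVector ctx_counts,
                          int dim, int epochs, double lr, int negatives,
                          int seed) {
  size_t npair = words.size();
  XorShift rng((uint64_t)seed * 2654435761ULL + 7ULL);
  std::vector<double> cnt(ctx_counts.begin(), ctx_counts.end());
  std::vector<double> cdf = neg_cdf(cnt);

  std::vector<double> syn0((size_t)n_words * dim), syn1((size_t)n_ctx * dim, 0.0);
  for (size_t i = 0; i < syn0.size(); ++i)
    syn0[i] = (rng.unif() - 0.5) / dim;

  std::vector<size_t> order(npair);
  for (size_t i = 0; i < npair; ++i) order[i] = i;

  std::vector<double> work(dim);
  NumericVector epoch_loss(epochs);
  double steps_total = (double)npair * epochs;
  double steps_done = 0.0;
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates with the private stream
    for (size_t i = npair; i > 1; --i) {
      size_t j = rng.below(i);
      std::swap(order[i - 1], order[j]);
    }
    double loss = 0.0;
    for (size_t k = 0; k < npair; ++k) {
      double alpha = lr * std::max(1e-4, 1.0 - steps_done / steps_total);
      steps_done += 1.0;
      size_t idx = order[k];
      loss += sgns_update(syn0, syn1, words[idx], ctxs[idx], dim, alpha,
                          negatives, cdf, n_ctx, rng, work);
    }
    epoch_loss[ep] = npair > 0 ? loss / npair : 0.0;
  }

  NumericMatrix out(n_words, dim);
  for (int i = 0; i < n_words; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = syn0[(size_t)i * dim + d];
  return List::create(_["vectors"] = out, _["loss"] = epoch_loss);
}
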