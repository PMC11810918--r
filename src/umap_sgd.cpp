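#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

static inline double clamp4(double x) {
  if (x > 4.0) return 4.0;
  if (x < -4.0) return -4.0;
  return x;
}

// Stochastic-gradient layout optimization of the fuzzy topological
// cross-entropy, following the reference UMAP optimizer: per-edge sampling
// schedule proportional to membership weight, negative sampling for the
// repulsive term, linearly decaying learning rate, clipped gradients.
// head/tail are 0-based edge endpoints; embedding is modified in place on a
// copy and returned.
// [[Rcpp::export(name = ".umap_layout_cpp")]]
NumericMatrix umap_layout_cpp(NumericMatrix embedding,
                              IntegerVector head,
                              IntegerVector tail,
                              NumericVector epochs_per_sample,
                              double a, double b, double gamma,
                              double initial_alpha,
                              int n_epochs,
                              double negative_sample_rate,
                              int seed) {
  NumericMatrix emb = clone(embedding);
  const int n = emb.nrow();
  const int d = emb.ncol();
  const int n_edges = head.size();

  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_int_distribution<int> pick(0, n - 1);

  std::vector<double> epoch_of_next_sample(epochs_per_sample.begin(),
                                           epochs_per_sample.end());
  std::vector<double> epochs_per_negative(n_edges);
  std::vector<double> epoch_of_next_negative(n_edges);
  for (int e = 0; e < n_edges; ++e) {
    epochs_per_negative[e] = epochs_per_sample[e] / negative_sample_rate;
    epoch_of_next_negative[e] = epochs_per_negative[e];
  }

  for (int epoch = 1; epoch <= n_epochs; ++epoch) {
    double alpha = initial_alpha * (1.0 - (double)(epoch - 1) / (double)n_epochs);
    for (int e = 0; e < n_edges; ++e) {
      if (epoch_of_next_sample[e] > epoch) continue;
      int i = head[e], j = tail[e];

      // attractive update
      double dist2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = emb(i, k) - emb(j, k);
        dist2 += diff * diff;
      }
      if (dist2 > 0.0) {
        double pd = a * std::pow(dist2, b);
        double grad_coeff = (-2.0 * a * b * std::pow(dist2, b - 1.0)) / (1.0 + pd);
        for (int k = 0; k < d; ++k) {
          double g = clamp4(grad_coeff * (emb(i, k) - emb(j, k)));
          emb(i, k) += alpha * g;
          emb(j, k) -= alpha * g;
        }
      }
      epoch_of_next_sample[e] += epochs_per_sample[e];

      // repulsive updates via negative sampling
      int n_neg = (int)((epoch - epoch_of_next_negative[e]) /
                        epochs_per_negative[e]);
      if (n_neg < 0) n_neg = 0;
      for (int s = 0; s < n_neg; ++s) {
        int t = pick(rng);
        if (t == i) continue;
        double nd2 = 0.0;
        for (int k = 0; k < d; ++k) {
          double diff = emb(i, k) - emb(t, k);
          nd2 += diff * diff;
        }
        if (nd2 > 0.0) {
          double grad_coeff = (2.0 * gamma * b) /
            ((0.001 + nd2) * (1.0 + a * std::pow(nd2, b)));
          for (int k = 0; k < d; ++k) {
            double g = clamp4(grad_coeff * (emb(i, k) - emb(t, k)));
            emb(i, k) += alpha * g;
          }
        } else {
          for (int k = 0; k < d; ++k) emb(i, k) += alpha * 4.0;
        }
      }
      epoch_of_next_negative[e] += n_neg * epochs_per_negative[e];
    }
  }
  return emb;
}
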