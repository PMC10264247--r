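#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// Self-contained RNG so fits are bit-reproducible for a given seed,
// independent of R's RNG state and of std::distribution implementations.
static inline double runif53(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0); // [0, 1)
}

// Collapsed Gibbs sampler for latent Dirichlet allocation on a sparse
// region x cell count matrix given as (region, cell, count) triplets
// (0-based indices). Token-level topic indicators are kept explicitly;
// region-topic and cell-topic count tables are updated in place.
//
// Returns final-sample count tables and, when average = true, tables
// accumulated over post-burn-in sweeps (for averaged point estimates).
// [[Rcpp::export]]
List lda_gibbs_cpp(IntegerVector region_idx, IntegerVector cell_idx,
                   IntegerVector count, int G, int n_cells, int K,
                   double alpha, double delta, int n_iter, int burn_in,
                   int seed, bool average) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2862933555777941757ULL
                      + 3037000493ULL);
  // expand tokens
  long n_tokens = 0;
  for (int i = 0; i < count.size(); ++i) n_tokens += count[i];
  std::vector<int> tok_g(n_tokens), tok_c(n_tokens), tok_z(n_tokens);
  {
    long t = 0;
    for (int i = 0; i < count.size(); ++i)
      for (int r = 0; r < count[i]; ++r) {
        tok_g[t] = region_idx[i];
        tok_c[t] = cell_idx[i];
        ++t;
      }
  }
  std::vector<double> n_gk((size_t)G * K, 0.0), n_kc((size_t)K * n_cells, 0.0),
      n_k(K, 0.0);
  // random initial assignment
  for (long t = 0; t < n_tokens; ++t) {
    int z = (int)(runif53(rng) * K);
    if (z >= K) z = K - 1;
    tok_z[t] = z;
    n_gk[(size_t)tok_g[t] * K + z] += 1.0;
    n_kc[(size_t)tok_c[t] * K + z] += 1.0;
    n_k[z] += 1.0;
  }
  std::vector<double> acc_gk, acc_kc, acc_k;
  int n_acc = 0;
  if (average) {
    acc_gk.assign((size_t)G * K, 0.0);
    acc_kc.assign((size_t)K * n_cells, 0.0);
    acc_k.assign(K, 0.0);
  }
  const double Gdelta = G * delta;
  std::vector<double> prob(K);
  for (int iter = 0; iter < n_iter; ++iter) {
    for (long t = 0; t < n_tokens; ++t) {
      const int g = tok_g[t], c = tok_c[t], z = tok_z[t];
      double *gk = &n_gk[(size_t)g * K];
      double *kc = &n_kc[(size_t)c * K];
      gk[z] -= 1.0; kc[z] -= 1.0; n_k[z] -= 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        tot += (kc[k] + alpha) * (gk[k] + delta) / (n_k[k] + Gdelta);
        prob[k] = tot;
      }
      const double u = runif53(rng) * tot;
      int znew = 0;
      while (znew < K - 1 && prob[znew] < u) ++znew;
      tok_z[t] = znew;
      gk[znew] += 1.0; kc[znew] += 1.0; n_k[znew] += 1.0;
    }
    if (average && iter >= burn_in) {
      for (size_t i = 0; i < n_gk.size(); ++i) acc_gk[i] += n_gk[i];
      for (size_t i = 0; i < n_kc.size(); ++i) acc_kc[i] += n_kc[i];
      for (int k = 0; k < K; ++k) acc_k[k] += n_k[k];
      ++n_acc;
    }
    if (iter % 20 == 0) Rcpp::checkUserInterrupt();
  }
  const std::vector<double> &out_gk = (average && n_acc > 0) ? acc_gk : n_gk;
  const std::vector<double> &out_kc = (average && n_acc > 0) ? acc_kc : n_kc;
  const std::vector<double> &out_k = (average && n_acc > 0) ? acc_k : n_k;
  const double denom = (average && n_acc > 0) ? (double)n_acc : 1.0;
  NumericMatrix R_gk(G, K);
  for (int g = 0; g < G; ++g)
    for (int k = 0; k < K; ++k) R_gk(g, k) = out_gk[(size_t)g * K + k] / denom;
  NumericMatrix R_kc(K, n_cells);
  for (int c = 0; c < n_cells; ++c)
    for (int k = 0; k < K; ++k) R_kc(k, c) = out_kc[(size_t)c * K + k] / denom;
  NumericVector R_k(K);
  for (int k = 0; k < K; ++k) R_k[k] = out_k[k] / denom;
  return List::create(_["n_gk"] = R_gk, _["n_kc"] = R_kc, _["n_k"] = R_k);
}

// Fold new cells into a fitted model: the region-topic matrix V is held
// fixed and only per-cell topic counts are Gibbs-sampled.
// [[Rcpp::export]]
NumericMatrix lda_fold_in_cpp(IntegerVector region_idx,
                              IntegerVector cell_idx, IntegerVector count,
                              NumericMatrix V, int n_cells, double alpha,
                              int n_iter, int burn_in, int seed) {
  const int K = V.ncol();
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL
                      + 1442695040888963407ULL);
  long n_tokens = 0;
  for (int i = 0; i < count.size(); ++i) n_tokens += count[i];
  std::vector<int> tok_g(n_tokens), tok_c(n_tokens), tok_z(n_tokens);
  {
    long t = 0;
    for (int i = 0; i < count.size(); ++i)
      for (int r = 0; r < count[i]; ++r) {
        tok_g[t] = region_idx[i];
        tok_c[t] = cell_idx[i];
        ++t;
      }
  }
  std::vector<double> n_kc((size_t)K * n_cells, 0.0);
  for (long t = 0; t < n_tokens; ++t) {
    int z = (int)(runif53(rng) * K);
    if (z >= K) z = K - 1;
    tok_z[t] = z;
    n_kc[(size_t)tok_c[t] * K + z] += 1.0;
  }
  // topic counts averaged over post-burn-in sweeps for stabler weights
  std::vector<double> acc((size_t)K * n_cells, 0.0);
  int n_acc = 0;
  std::vector<double> prob(K);
  for (int iter = 0; iter < n_iter; ++iter) {
    for (long t = 0; t < n_tokens; ++t) {
      const int g = tok_g[t], c = tok_c[t], z = tok_z[t];
      double *kc = &n_kc[(size_t)c * K];
      kc[z] -= 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        tot += (kc[k] + alpha) * V(g, k);
        prob[k] = tot;
      }
      const double u = runif53(rng) * tot;
      int znew = 0;
      while (znew < K - 1 && prob[znew] < u) ++znew;
      tok_z[t] = znew;
      kc[znew] += 1.0;
    }
    if (iter >= burn_in) {
      for (size_t i = 0; i < n_kc.size(); ++i) acc[i] += n_kc[i];
      ++n_acc;
    }
    if (iter % 50 == 0) Rcpp::checkUserInterrupt();
  }
  const double denom = n_acc > 0 ? (double)n_acc : 1.0;
  const std::vector<double> &src = n_acc > 0 ? acc : n_kc;
  NumericMatrix out(K, n_cells);
  for (int c = 0; c < n_cells; ++c)
    for (int k = 0; k < K; ++k) out(k, c) = src[(size_t)c * K + k] / denom;
  return out;
}
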