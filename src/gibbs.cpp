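#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sweeps for the grouped-LDA form of the author-topic model
// (one author per document). Tokens are visited in the order supplied, which
// the R side fixes to document order, then token order within document.
//
// Conditional for token i with author a and word w:
//   P(z_i = k | z_-i, w) ∝ (n_ak^{-i} + alpha_k) * (n_kw^{-i} + beta) / (n_k^{-i} + V*beta)
//
// All randomness comes from R's RNG so set.seed() on the R side makes runs
// bit-reproducible.
// [[Rcpp::export]]
List cpp_gibbs_sweeps(IntegerVector z_in,
                      IntegerVector token_author,
                      IntegerVector token_word,
                      IntegerMatrix n_ak_in,
                      IntegerMatrix n_kw_in,
                      IntegerVector n_k_in,
                      NumericVector alpha,
                      double beta,
                      int nsweeps) {
  IntegerVector z = clone(z_in);
  IntegerMatrix n_ak = clone(n_ak_in);
  IntegerMatrix n_kw = clone(n_kw_in);
  IntegerVector n_k = clone(n_k_in);

  const int N = z.size();
  const int K = alpha.size();
  const int V = n_kw.ncol();
  const double Vbeta = V * beta;
  std::vector<double> prob(K);

  RNGScope scope;

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int i = 0; i < N; ++i) {
      const int a = token_author[i];
      const int w = token_word[i];
      const int k_old = z[i];

      n_ak(a, k_old)--;
      n_kw(k_old, w)--;
      n_k[k_old]--;

      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        const double p = (n_ak(a, k) + alpha[k]) *
                         (n_kw(k, w) + beta) / (n_k[k] + Vbeta);
        total += p;
        prob[k] = total;
      }

      const double u = unif_rand() * total;
      int k_new = 0;
      while (k_new < K - 1 && prob[k_new] < u) ++k_new;

      z[i] = k_new;
      n_ak(a, k_new)++;
      n_kw(k_new, w)++;
      n_k[k_new]++;
    }
  }

  return List::create(_["z"] = z, _["n_ak"] = n_ak,
                      _["n_kw"] = n_kw, _["n_k"] = n_k);
}

// Sweeps that additionally accumulate per-token topic frequencies after each
// sweep; used for long Monte-Carlo runs checked against exhaustive
// enumeration of the collapsed posterior. Returns the running counts of
// z_i = k over sweeps plus per-batch means for batch-means standard errors.
// [[Rcpp::export]]
List cpp_gibbs_sweeps_traced(IntegerVector z_in,
                             IntegerVector token_author,
                             IntegerVector token_word,
                             IntegerMatrix n_ak_in,
                             IntegerMatrix n_kw_in,
                             IntegerVector n_k_in,
                             NumericVector alpha,
                             double beta,
                             int nsweeps,
                             int nbatches) {
  IntegerVector z = clone(z_in);
  IntegerMatrix n_ak = clone(n_ak_in);
  IntegerMatrix n_kw = clone(n_kw_in);
  IntegerVector n_k = clone(n_k_in);

  const int N = z.size();
  const int K = alpha.size();
  const int V = n_kw.ncol();
  const double Vbeta = V * beta;
  std::vector<double> prob(K);

  NumericMatrix freq(N, K);           // overall occupancy counts
  const int batch_len = nsweeps / nbatches;
  // batch means of the indicator z_i == k, laid out (batch) x (N*K)
  NumericMatrix batch_mean(nbatches, N * K);

  RNGScope scope;

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int i = 0; i < N; ++i) {
      const int a = token_author[i];
      const int w = token_word[i];
      const int k_old = z[i];

      n_ak(a, k_old)--;
      n_kw(k_old, w)--;
      n_k[k_old]--;

      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        const double p = (n_ak(a, k) + alpha[k]) *
                         (n_kw(k, w) + beta) / (n_k[k] + Vbeta);
        total += p;
        prob[k] = total;
      }

      const double u = unif_rand() * total;
      int k_new = 0;
      while (k_new < K - 1 && prob[k_new] < u) ++k_new;

      z[i] = k_new;
      n_ak(a, k_new)++;
      n_kw(k_new, w)++;
      n_k[k_new]++;
    }
    const int b = std::min(sweep / batch_len, nbatches - 1);
    for (int i = 0; i < N; ++i) {
      freq(i, z[i]) += 1.0;
      batch_mean(b, i * K + z[i]) += 1.0;
    }
  }

  for (int b = 0; b < nbatches; ++b) {
    const int len = (b == nbatches - 1) ? (nsweeps - batch_len * (nbatches - 1))
                                        : batch_len;
    for (int j = 0; j < N * K; ++j) batch_mean(b, j) /= len;
  }

  return List::create(_["freq"] = freq, _["batch_mean"] = batch_mean,
                      _["z"] = z, _["n_ak"] = n_ak,
                      _["n_kw"] = n_kw, _["n_k"] = n_k);
}

// Fold-in Gibbs for held-out documents: the topic-gene distribution phi is
// frozen; only per-document topic counts are resampled.
//   P(z_i = k | rest) ∝ (n_dk^{-i} + alpha_k) * phi(k, w)
// [[Rcpp::export]]
List cpp_fold_in(IntegerVector z_in,
                 IntegerVector token_doc,
                 IntegerVector token_word,
                 IntegerMatrix n_dk_in,
                 NumericMatrix phi,
                 NumericVector alpha,
                 int nsweeps) {
  IntegerVector z = clone(z_in);
  IntegerMatrix n_dk = clone(n_dk_in);

  const int N = z.size();
  const int K = alpha.size();
  std::vector<double> prob(K);

  RNGScope scope;

  for (int sweep = 0; sweep < nsweeps; ++sweep) {
    for (int i = 0; i < N; ++i) {
      const int d = token_doc[i];
      const int w = token_word[i];
      const int k_old = z[i];
      n_dk(d, k_old)--;

      double total = 0.0;
      for (int k = 0; k < K; ++k) {
        const double p = (n_dk(d, k) + alpha[k]) * phi(k, w);
        total += p;
        prob[k] = total;
      }

      const double u = unif_rand() * total;
      int k_new = 0;
      while (k_new < K - 1 && prob[k_new] < u) ++k_new;

      z[i] = k_new;
      n_dk(d, k_new)++;
    }
  }

  return List::create(_["z"] = z, _["n_dk"] = n_dk);
}
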