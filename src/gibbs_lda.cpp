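#include <Rcpp.h>
using namespace Rcpp;

// Collapsed Gibbs sampler for LDA. Uses R's RNG, so results are
// reproducible under set.seed() on the R side. doc_id/word_id are 0-based
// token streams; returns final count matrices.
// [[Rcpp::export]]
List gibbs_lda_cpp(IntegerVector doc_id, IntegerVector word_id,
                   int n_docs, int n_vocab, int n_topics,
                   double alpha, double beta, int n_iter) {
  int n_tok = doc_id.size();
  IntegerMatrix ndk(n_docs, n_topics);
  IntegerMatrix nkw(n_topics, n_vocab);
  IntegerVector nk(n_topics);
  IntegerVector z(n_tok);
  NumericVector p(n_topics);

  for (int i = 0; i < n_tok; ++i) {
    int k = (int)(unif_rand() * n_topics);
    if (k == n_topics) k = n_topics - 1;
    z[i] = k;
    ndk(doc_id[i], k)++;
    nkw(k, word_id[i])++;
    nk[k]++;
  }
  double vbeta = n_vocab * beta;
  for (int it = 0; it < n_iter; ++it) {
    for (int i = 0; i < n_tok; ++i) {
      int d = doc_id[i], w = word_id[i], k = z[i];
      ndk(d, k)--; nkw(k, w)--; nk[k]--;
      double tot = 0.0;
      for (int t = 0; t < n_topics; ++t) {
        p[t] = (ndk(d, t) + alpha) * (nkw(t, w) + beta) / (nk[t] + vbeta);
        tot += p[t];
      }
      double u = unif_rand() * tot, cum = 0.0;
      int knew = n_topics - 1;
      for (int t = 0; t < n_topics; ++t) {
        cum += p[t];
        if (u <= cum) { knew = t; break; }
      }
      z[i] = knew;
      ndk(d, knew)++; nkw(knew, w)++; nk[knew]++;
    }
  }
  return List::create(_["ndk"] = ndk, _["nkw"] = nkw, _["nk"] = nk);
}
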