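#include <Rcpp.h>
using namespace Rcpp;

// Sample base codes (A=0, C=1, G=2, T=3) from an order-k Markov chain.
//
// trans: 4^k x 4 row-stochastic matrix, contexts in lexicographic order over
// the code alphabet. init_context indexes the starting context (0-based).
// u holds n uniforms pre-drawn from R's RNG so every source of randomness
// stays under set.seed() on the R side.
// [[Rcpp::export]]
IntegerVector markov_sample_codes(int n, int k, NumericMatrix trans,
                                  int init_context, NumericVector u) {
  if (n < 0) stop("n must be non-negative");
  if (trans.ncol() != 4) stop("transition matrix must have 4 columns");
  if (u.size() < n) stop("need one uniform draw per sampled base");
  int n_ctx = 1;
  for (int i = 0; i < k; ++i) n_ctx *= 4;
  if (trans.nrow() != n_ctx) stop("transition matrix must have 4^k rows");
  if (init_context < 0 || init_context >= n_ctx) stop("bad initial context");

  int mask = n_ctx / 4;  // 4^(k-1)
  IntegerVector out(n);
  int ctx = init_context;
  for (int i = 0; i < n; ++i) {
    double x = u[i];
    double acc = 0.0;
    int b = 3;
    for (int j = 0; j < 4; ++j) {
      acc += trans(ctx, j);
      if (x < acc) { b = j; break; }
    }
    out[i] = b;
    ctx = (ctx % mask) * 4 + b;
  }
  return out;
}
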