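#include <Rcpp.h>
using namespace Rcpp;

// Sample an order-m Markov nucleotide sequence.
//
// cum: (4^m) x 4 matrix of cumulative transition probabilities, rows indexed
// by the base-4 encoding of the length-m context (A=0, C=1, G=2, T=3), each
// row ending at 1. u: uniform(0,1) draws, one per base, generated on the R
// side so determinism follows R's RNG. The first m bases are drawn uniformly
// from the first m entries of u.
// [[Rcpp::export(name = ".sample_markov_cpp")]]
std::string sample_markov_cpp(NumericMatrix cum, int m, NumericVector u) {
  static const char bases[] = {'A', 'C', 'G', 'T'};
  const int n = u.size();
  if (n < m) stop("length must be at least the model order");
  std::string out(n, 'A');
  int ctx = 0;
  const int mask = (int)cum.nrow() - 1;  // 4^m - 1
  for (int i = 0; i < m; ++i) {
    int b = (int)(u[i] * 4.0);
    if (b > 3) b = 3;
    out[i] = bases[b];
    ctx = ((ctx << 2) | b) & mask;
  }
  for (int i = m; i < n; ++i) {
    const double x = u[i];
    int b = 0;
    while (b < 3 && x >= cum(ctx, b)) ++b;
    out[i] = bases[b];
    ctx = ((ctx << 2) | b) & mask;
  }
  return out;
}
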