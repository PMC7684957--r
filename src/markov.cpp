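#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov chain over {A,C,G,T}.
// cum_trans: 4x4 matrix of row-wise cumulative transition probabilities
// (row = current base, col = next base, last column == 1).
// cum_init: length-4 cumulative initial distribution.
// Draws from R's RNG so set.seed() governs reproducibility.
// [[Rcpp::export]]
std::string markov_sim_cpp(NumericMatrix cum_trans, NumericVector cum_init, int n) {
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  if (n < 1) stop("sequence length must be >= 1");
  std::string out(n, 'A');
  double u = unif_rand();
  int s = 0;
  while (s < 3 && cum_init[s] < u) ++s;
  out[0] = bases[s];
  for (int i = 1; i < n; ++i) {
    u = unif_rand();
    int t = 0;
    while (t < 3 && cum_trans(s, t) < u) ++t;
    s = t;
    out[i] = bases[s];
  }
  return out;
}
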