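#include <Rcpp.h>
using namespace Rcpp;

// First-order Markov-chain nucleotide sequence. `trans` is a 4x4 row-
// stochastic matrix over (A,C,G,T); the initial state is drawn from the
// stationary-ish uniform start unless `init` is given. Uses R's RNG so
// set.seed() governs reproducibility.
// [[Rcpp::export(name = ".markov_sequence")]]
String markov_sequence(int n, NumericMatrix trans, NumericVector init) {
  static const char bases[] = {'A', 'C', 'G', 'T'};
  if (trans.nrow() != 4 || trans.ncol() != 4)
    stop("transition matrix must be 4x4");
  // row-wise cumulative probabilities
  double cum[4][4];
  for (int i = 0; i < 4; ++i) {
    double s = 0.0;
    for (int j = 0; j < 4; ++j) {
      s += trans(i, j);
      cum[i][j] = s;
    }
    if (s < 1.0 - 1e-9 || s > 1.0 + 1e-9)
      stop("transition matrix rows must sum to 1");
  }
  double cinit[4];
  double s = 0.0;
  for (int j = 0; j < 4; ++j) { s += init[j]; cinit[j] = s; }
  if (s < 1.0 - 1e-9 || s > 1.0 + 1e-9)
    stop("initial distribution must sum to 1");

  std::string out(n, 'A');
  double u = unif_rand();
  int state = 0;
  while (state < 3 && u > cinit[state]) ++state;
  if (n > 0) out[0] = bases[state];
  for (int t = 1; t < n; ++t) {
    u = unif_rand();
    int nxt = 0;
    while (nxt < 3 && u > cum[state][nxt]) ++nxt;
    state = nxt;
    out[t] = bases[state];
  }
  return String(out);
}
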