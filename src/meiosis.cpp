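#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Form gametes for one chromosome by recombining parental haplotypes.
//
// haps:   2N x L integer matrix; rows 2p and 2p+1 (0-based) hold the two
//         haplotypes of parent p+1 (1-based).
// parent: 1-based parent index per gamete (length = number of gametes).
// pos:    locus positions in Morgans, non-decreasing.
//
// Crossovers are a Poisson process at 1 per Morgan (Haldane, no
// interference); the starting haplotype is chosen at random.  Uses R's
// RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix meiosis_cpp(IntegerMatrix haps, IntegerVector parent,
                          NumericVector pos) {
  const int L = haps.ncol();
  const int G = parent.size();
  IntegerMatrix out(G, L);
  const double lo = pos[0];
  const double len = pos[L - 1] - pos[0];
  std::vector<double> xo;
  for (int g = 0; g < G; ++g) {
    const int p = parent[g] - 1;
    int cur = (unif_rand() < 0.5) ? 0 : 1;
    const int nco = (len > 0.0) ? (int) R::rpois(len) : 0;
    if (nco == 0) {
      for (int l = 0; l < L; ++l) out(g, l) = haps(2 * p + cur, l);
      continue;
    }
    xo.resize(nco);
    for (int k = 0; k < nco; ++k) xo[k] = lo + unif_rand() * len;
    std::sort(xo.begin(), xo.end());
    int k = 0;
    for (int l = 0; l < L; ++l) {
      while (k < nco && xo[k] <= pos[l]) { cur = 1 - cur; ++k; }
      out(g, l) = haps(2 * p + cur, l);
    }
  }
  return out;
}
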