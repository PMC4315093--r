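#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Forward Wright-Fisher evolution of haplotypes at L biallelic markers on
// one chromosome.  H holds 2N founder haplotypes (rows) x L markers (0/1).
// gpos gives each marker's genetic position in Morgans on [0, total_morgans].
// ne[g] is the diploid population size of generation g; each offspring draws
// two parents uniformly (selfing allowed) and receives one recombinant
// gamete from each.  Crossover counts are Poisson(total_morgans) with
// breakpoints uniform in genetic distance; no interference.  Uses R's RNG,
// so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix wf_evolve_cpp(IntegerMatrix H, NumericVector gpos,
                            double total_morgans, IntegerVector ne) {
  const int L = H.ncol();
  int ncur = H.nrow() / 2;
  if (2 * ncur != H.nrow()) stop("haplotype count must be even");

  std::vector<unsigned char> cur((size_t)2 * ncur * L), nxt;
  for (int r = 0; r < 2 * ncur; ++r)
    for (int l = 0; l < L; ++l)
      cur[(size_t)r * L + l] = (unsigned char)H(r, l);

  std::vector<double> xs;
  for (int g = 0; g < ne.size(); ++g) {
    const int nn = ne[g];
    if (nn < 1) stop("population size must be positive");
    nxt.assign((size_t)2 * nn * L, 0);
    for (int i = 0; i < nn; ++i) {
      for (int par = 0; par < 2; ++par) {
        int p = (int)(unif_rand() * ncur);
        if (p == ncur) p = ncur - 1;
        const unsigned char *h0 = &cur[(size_t)(2 * p) * L];
        const unsigned char *h1 = &cur[(size_t)(2 * p + 1) * L];
        unsigned char *out = &nxt[(size_t)(2 * i + par) * L];
        int k = (int)R::rpois(total_morgans);
        int hap = unif_rand() < 0.5 ? 0 : 1;
        if (k == 0) {
          std::copy(hap ? h1 : h0, (hap ? h1 : h0) + L, out);
        } else {
          xs.resize(k);
          for (int c = 0; c < k; ++c) xs[c] = unif_rand() * total_morgans;
          std::sort(xs.begin(), xs.end());
          int ci = 0;
          for (int l = 0; l < L; ++l) {
            while (ci < k && xs[ci] <= gpos[l]) { hap ^= 1; ++ci; }
            out[l] = hap ? h1[l] : h0[l];
          }
        }
      }
    }
    cur.swap(nxt);
    ncur = nn;
  }

  IntegerMatrix out(2 * ncur, L);
  for (int r = 0; r < 2 * ncur; ++r)
    for (int l = 0; l < L; ++l)
      out(r, l) = cur[(size_t)r * L + l];
  return out;
}
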