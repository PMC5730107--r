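#include <Rcpp.h>
using namespace Rcpp;

// Gamete formation for an individual-based Wright-Fisher simulator.
//
// H1, H2: parental haplotype matrices (individuals x sites, 0/1), H1 the
// maternally inherited copy. parent_idx: 1-based row index of the parent
// producing each gamete. switch_prob: per-site probability of switching
// the source haplotype between site s-1 and s (0.5 at the first site of
// each chromosome = free recombination across chromosomes). x_site: 1 for
// X-linked sites. parent_male: per-gamete flag; a male parent is
// hemizygous, so his gametes always carry H1 at X-linked sites.
// [[Rcpp::export(name = ".make_gametes")]]
IntegerMatrix make_gametes(const IntegerMatrix& H1, const IntegerMatrix& H2,
                           const IntegerVector& parent_idx,
                           const NumericVector& switch_prob,
                           const LogicalVector& x_site,
                           const LogicalVector& parent_male) {
  const int n_off = parent_idx.size();
  const int S = H1.ncol();
  IntegerMatrix out(n_off, S);

  // Free recombination (every interior switch probability 1/2) makes the
  // source haplotype iid per site; serve 16 random bits per unif_rand()
  // call instead of one, which dominates runtime at genome scale.
  bool free_recomb = true;
  for (int s = 1; s < S; ++s)
    if (switch_prob[s] != 0.5) { free_recomb = false; break; }
  if (free_recomb) {
    unsigned int cache = 0;
    int nbits = 0;
    for (int i = 0; i < n_off; ++i) {
      const int p = parent_idx[i] - 1;
      const bool male = parent_male[i];
      for (int s = 0; s < S; ++s) {
        if (male && x_site[s]) { out(i, s) = H1(p, s); continue; }
        if (nbits == 0) {
          cache = (unsigned int)(unif_rand() * 65536.0) & 0xFFFFu;
          nbits = 16;
        }
        const int b = cache & 1u;
        cache >>= 1;
        --nbits;
        out(i, s) = b ? H2(p, s) : H1(p, s);
      }
    }
    return out;
  }

  for (int i = 0; i < n_off; ++i) {
    const int p = parent_idx[i] - 1;
    const bool male = parent_male[i];
    int state = (unif_rand() < 0.5) ? 0 : 1;
    for (int s = 0; s < S; ++s) {
      if (s > 0 && unif_rand() < switch_prob[s]) state = 1 - state;
      if (male && x_site[s]) {
        out(i, s) = H1(p, s);
      } else {
        out(i, s) = state == 0 ? H1(p, s) : H2(p, s);
      }
    }
  }
  return out;
}
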