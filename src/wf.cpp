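#include <Rcpp.h>
using namespace Rcpp;

// Gamete formation with Haldane crossovers (Poisson, no interference).
// hap1/hap2: parental haplotypes over all SNPs; chrom: 0-based chromosome
// index per SNP (consecutive blocks); pos_m: position in Morgans within
// the chromosome; chrom_len_m: chromosome lengths in Morgans;
// chrom_off: first SNP index of each chromosome (with a final sentinel =
// number of SNPs). Uses R's RNG so results follow set.seed().
static void make_gamete(const int *hap1, const int *hap2,
                        const NumericVector &pos_m,
                        const NumericVector &chrom_len_m,
                        const IntegerVector &chrom_off,
                        double mutation_rate, int *out) {
  int n_chrom = chrom_len_m.size();
  for (int c = 0; c < n_chrom; ++c) {
    int lo = chrom_off[c], hi = chrom_off[c + 1];
    int ncross = (int) R::rpois(chrom_len_m[c]);
    int phase = (unif_rand() < 0.5) ? 0 : 1;
    if (ncross == 0) {
      const int *src = phase ? hap2 : hap1;
      for (int j = lo; j < hi; ++j) out[j] = src[j];
    } else {
      std::vector<double> cx(ncross);
      for (int k = 0; k < ncross; ++k) cx[k] = unif_rand() * chrom_len_m[c];
      std::sort(cx.begin(), cx.end());
      int k = 0;
      for (int j = lo; j < hi; ++j) {
        while (k < ncross && cx[k] <= pos_m[j]) { phase ^= 1; ++k; }
        out[j] = phase ? hap2[j] : hap1[j];
      }
    }
    if (mutation_rate > 0) {
      for (int j = lo; j < hi; ++j)
        if (unif_rand() < mutation_rate) out[j] = 1 - out[j];
    }
  }
}

// [[Rcpp::export]]
IntegerVector gamete_cpp(IntegerVector hap1, IntegerVector hap2,
                         NumericVector pos_m, NumericVector chrom_len_m,
                         IntegerVector chrom_off, double mutation_rate) {
  IntegerVector out(hap1.size());
  make_gamete(hap1.begin(), hap2.begin(), pos_m, chrom_len_m, chrom_off,
              mutation_rate, out.begin());
  return out;
}

// Discrete-generation Wright-Fisher evolution of a haplotype pool.
// haps: 2N x m matrix, rows 2i and 2i+1 (0-based) are individual i.
// ne_per_gen: population size of each offspring generation.
// Returns the final generation's haplotypes (2 * last Ne rows).
// Parents are drawn uniformly with selfing excluded.
// [[Rcpp::export]]
IntegerMatrix wf_evolve_cpp(IntegerMatrix haps, NumericVector pos_m,
                            NumericVector chrom_len_m,
                            IntegerVector chrom_off,
                            IntegerVector ne_per_gen,
                            double mutation_rate) {
  int m = haps.ncol();
  int n_cur = haps.nrow() / 2;
  // copy into row-major buffers for cache-friendly gamete formation
  std::vector<std::vector<int> > cur(2 * n_cur, std::vector<int>(m));
  for (int i = 0; i < 2 * n_cur; ++i)
    for (int j = 0; j < m; ++j) cur[i][j] = haps(i, j);

  for (int g = 0; g < ne_per_gen.size(); ++g) {
    int n_next = ne_per_gen[g];
    if (n_next < 2) stop("population size must be at least 2");
    std::vector<std::vector<int> > nxt(2 * n_next, std::vector<int>(m));
    for (int i = 0; i < n_next; ++i) {
      int mother = (int) (unif_rand() * n_cur);
      if (mother >= n_cur) mother = n_cur - 1;
      int father = (int) (unif_rand() * (n_cur - 1));
      if (father >= n_cur - 1) father = n_cur - 2;
      if (father >= mother) ++father;          // exclude selfing
      make_gamete(cur[2 * mother].data(), cur[2 * mother + 1].data(),
                  pos_m, chrom_len_m, chrom_off, mutation_rate,
                  nxt[2 * i].data());
      make_gamete(cur[2 * father].data(), cur[2 * father + 1].data(),
                  pos_m, chrom_len_m, chrom_off, mutation_rate,
                  nxt[2 * i + 1].data());
    }
    cur.swap(nxt);
    n_cur = n_next;
  }
  IntegerMatrix out(2 * n_cur, m);
  for (int i = 0; i < 2 * n_cur; ++i)
    for (int j = 0; j < m; ++j) out(i, j) = cur[i][j];
  return out;
}
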