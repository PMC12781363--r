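# genodiv

Genomic-diversity analysis of SNP-array genotypes for livestock
populations, built around the workflow used in pig breeding-program
studies: per-population quality control, heterozygosity summaries,
population structure, runs of homozygosity (ROH) and ROH islands, ten
genomic inbreeding coefficients, linkage-disequilibrium decay with
effective-population-size estimation, and windowed F_ST selection
scans.  A forward-in-time Wright–Fisher simulator with planted ground
truth makes every stage verifiable by parameter recovery.

## What it computes

For diploid biallelic genotypes (VCF or PLINK PED/MAP text, dosages of
a counted allele), per population:

* **QC** — the six sequential removal rules (call rate 0.95, MAF 0.05,
  joint call rate 0.90 for SNPs then individuals, exact
  Hardy–Weinberg p < 1e-6, unknown/duplicated positions,
  non-autosomal SNPs), with a per-rule report.
* **Diversity** — mean MAF, observed and expected heterozygosity
  (`He = 2pq`), with a homozygosity-scale option.
* **Structure** — VanRaden and variance-standardised genomic
  relationship matrices, PCA, identity-by-state distances.
* **ROH** — the sliding-window detector (50-SNP windows, ≤ 1
  heterozygote and ≤ 5 missing per window, 5% hit threshold, ≥ 15
  SNPs, ≥ 500 kb, ≤ 75 kb/SNP, 500-kb gap split), five length
  classes, per-SNP incidence, dual-threshold ROH islands (top-1%
  quantile *and* ≥ 35% incidence, < 100 kb merge), and shared islands
  across population groups.
* **Inbreeding** — F_GRM (`G_ii − 1`), F_HOM1
  (`(E_het − O_het)/E_het`), F_HOM2 (mean of
  `1 − x(2−x)/2pq`), F_UNI (uniting gametes), F_ROH
  (`Σ L_ROH / L_auto`) plus its five length-stratified variants, and
  their Pearson correlation matrix.
* **Ne** — pairwise r² by EM haplotype-frequency estimation
  (`r² = (p_ab − p_a p_b)² / p_a(1−p_a)p_b(1−p_b)`), 100-kb LD-decay
  bins to 2 Mb, and the Sved estimator
  `Ne(t) = (1/(4c_t)) (1/E[r²_adj] − α)` for t = 25…100 generations.
* **Selection** — per-SNP Weir–Cockerham variance components, 100-kb
  windows sliding in 10-kb steps with the weighted `Σa/Σ(a+b+c)`
  statistic, top-1% outlier windows, and shared outlier regions.

`run_full_analysis()` drives all of it from one (YAML-able) config;
`inst/cli/genodiv.R` is a thin command-line wrapper with `run` and
`simulate` subcommands.

## Worked example

Simulate a Duroc-like population (60 pigs, 6,000 SNPs on six 100-Mb
autosomes, Ne = 80 for 100 generations) and run the main stages:

```r
library(genodiv)

cfg  <- sim_config(n_snps = 6000, n_chromosomes = 6, chrom_length_mb = 100,
                   ne = 80, n_generations = 100, seed = 11)
pool <- simulate_founders(cfg)
set.seed(11)
gm <- simulate_wright_fisher(pool, n_sample = 60,
                             population = "DurocSim")$gm

qc <- apply_qc(gm, qc_profile("default", autosomes = as.character(1:6)))
qc$report
#> QC report (profile 'default'): 60 x 6000 -> 60 x 3234 (samples x SNPs)
#>  rule                          description snps_removed samples_removed
#>     1                        SNP call rate            0               0
#>     2               minor allele frequency         2766               0
#>     3 joint call rate (SNPs, then samples)            0               0
#>     4            Hardy-Weinberg exact test            0               0
#>     5       unknown or duplicated position            0               0
#>     6             non-autosomal chromosome            0               0
```

After 100 generations of drift at Ne = 80, almost half the array is
below the 5% MAF floor — rule 2 removes 2,766 SNPs.  Diversity of the
survivors:

```r
diversity_summary(qc$gm)
#>   population n_samples n_snps mean_maf mean_ho mean_he           mode
#> 1   DurocSim        60   3234   0.2746  0.3701  0.3645 heterozygosity
```

ROH are detected on the unfiltered-MAF track and summarised by length
class; the inbreeding coefficients use both tracks:

```r
roh_qc <- apply_qc(gm, qc_profile("roh", autosomes = as.character(1:6)))
segs   <- detect_roh(roh_qc$gm)
roh_summary(segs)
#>   population n_roh mean_length_mb sd_length_mb min_length_mb max_length_mb
#> 1        all    34         3.2698       1.2240        0.9653        5.1433
#>   n_lt2 n_2to4 n_4to8 n_8to16 n_gt16
#> 1     7     19      8       0      0

recs <- inbreeding_records(qc$gm, segs, roh_gm = roh_qc$gm,
                           autosomes = as.character(1:6))
round(colMeans(recs[, -1]), 4)
#>  f_hom1   f_grm  f_hom2   f_uni   f_roh ...
#> -0.0155 -0.0155 -0.0162 -0.0155  0.0031 ...
```

The marker-based estimators agree closely with one another and sit near
zero, as they should for a closed population analysed with its own
allele frequencies; F_ROH is small because only 34 runs exceed the
500-kb detection floor.  The LD-based Ne trajectory recovers the
simulated size:

```r
estimate_ne(qc$gm, t_range = c(25, 50, 75, 100))
#>     t    c_t mean_r2_adj n_pairs      ne
#> 1  25 0.0200      0.1124    1394   98.74
#> 2  50 0.0100      0.1986     352  100.86
#> 3  75 0.0067      0.2535     186  110.46
#> 4 100 0.0050      0.2861      95  124.76
```

Estimates of 99–125 against a true Ne of 80 reflect the deeper,
effectively larger founder history — the expected behaviour of the Sved
estimator on a recently founded line.

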