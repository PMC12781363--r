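---
title: "Methods and design of genodiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of genodiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

genodiv characterises genomic diversity in SNP-array genotypes of
livestock populations: quality control, heterozygosity summaries,
population structure (GRM/PCA, identity-by-state distances), runs of
homozygosity (ROH) and ROH islands, ten genomic inbreeding coefficients,
linkage-disequilibrium decay with effective-population-size estimation,
and windowed F_ST selection scans.  This vignette explains the models
and the design decisions behind each stage; the README shows a worked
example.

## Data model

Genotypes are diploid biallelic dosages in `{0, 1, 2, NA}` counting a
designated *counted allele* per SNP (ALT for VCF input; the minor allele,
with a lexicographic tie-break, for PLINK text input).  All statistics
below are invariant to which allele is counted except for the sign of
the dosage, which input harmonisation handles.  Coordinates are 1-based
closed intervals internally; BED export converts to 0-based half-open at
the I/O boundary.  Chromosome labels are opaque strings; autosome status
comes from a configurable list (default `"1"`–`"18"`, the pig
karyotype), so other species remain usable.

## Quality control

Six removal rules run sequentially, with call rates and allele
frequencies recomputed on the surviving data before each rule: (1) SNP
call rate < 0.95; (2) MAF < 0.05; (3) SNPs, then individuals, with call
rate < 0.90; (4) exact Hardy–Weinberg p < 1e-6; (5) unknown or
duplicated positions; (6) non-autosomal SNPs.  Sequential recomputation
is the standard (PLINK-style `--geno` then `--mind`) behaviour and makes
the report reproducible.  Two consequences of this ordering are worth
stating plainly: a SNP that fails rule 3's 0.90 threshold has always
already failed rule 1's 0.95, so rule 3 removes only individuals in
practice; and the exact HWE test cannot reach p < 1e-6 with fewer than
roughly 30 individuals per homozygote class, so very small populations
are effectively never filtered by rule 4.

The HWE test is the plain two-sided exact test (no mid-p): conditional
on the observed allele counts, all heterozygote counts of the same
parity are enumerated and configurations no more probable than the
observed one are summed.  Probabilities are computed on the log scale
and renormalised, which is exact to floating-point rounding for any
sample size used on arrays.

Two named profiles ship: `default` (all six rules) and `roh`, which
disables the MAF filter because low-MAF and monomorphic SNPs carry
information about run length and removing them fragments ROH.

## Diversity summaries

Per SNP, observed heterozygosity is the fraction of non-missing
genotypes that are heterozygous and expected heterozygosity is
`2p(1-p)`; population values are unweighted means over SNPs.  Published
tables in this literature sometimes report the homozygosity complement
under the same column names, so the `mode` argument exposes both scales
and records which was used; the default is the heterozygosity scale
(the `He = 2pq` convention).

## Relationship matrices and PCA

Two constructions from centred dosages `Z = X - 2p`: the VanRaden ratio
form `G = ZZ'/(2 Σ p_j(1-p_j))`, whose diagonal defines
`F_GRM = G_ii - 1`, and the variance-standardised form
`G = WW'/m`, `W_ij = Z_ij/sqrt(2p_j(1-p_j))`, used for PCA.  Missing
dosages are mean-imputed to `2p_j` (standard VanRaden practice);
monomorphic SNPs are excluded with a warning.  PCA is a symmetric
eigendecomposition; variance explained is each eigenvalue over the sum
of positive eigenvalues, scores are `U√λ`, and each component's sign is
fixed so its largest-magnitude loading is positive (a deterministic
convention; eigenvector signs are otherwise arbitrary).

## Runs of homozygosity

The detector follows the standard SNP-array windowed algorithm: a
50-SNP window slides one SNP at a time; a window is homozygous if it
contains at most 1 heterozygous and 5 missing calls; a SNP is *in-run*
if at least 5% of the windows covering it are homozygous; maximal
in-run stretches are split at inter-SNP gaps > 500 kb, trimmed to
homozygous non-missing endpoints, and emitted if they have ≥ 15 SNPs,
length ≥ 500 kb, and average spacing ≤ 75 kb per SNP.  The 5% hit
threshold is not always reported alongside the other six criteria in
application papers; it is the long-standing default of the tool that
defined the algorithm, and it is exposed as a parameter.

Two edge behaviours follow from the rules rather than from
implementation choices, and the test suite pins both: the outermost SNP
of a homozygous stretch flanked by heterozygotes is covered by only two
homozygous windows (hit fraction 0.04 < 0.05), so recovered boundaries
sit exactly one SNP inside an abruptly bounded tract; and a tract
shorter than the window cannot produce any homozygous window against a
heterozygous flank, so runs need roughly `window_snps` SNPs to be
detectable regardless of the 15-SNP emission floor.  Length classes are
lower-inclusive (`[0.5,2)`, `[2,4)`, `[4,8)`, `[8,16)`, `[16,∞)` Mb);
`length_bp = end - start + 1` on the 1-based closed interval.

ROH islands use the dual threshold: candidate SNPs must reach the
population's empirical 99th-percentile incidence (nearest-rank quantile,
which is deterministic) *and* an absolute floor of 35%; candidates
closer than 100 kb merge into islands whose bounds are candidate SNP
positions.  Shared islands across a group of populations are the
genomic intersection (intervals covered by at least one island in
*every* member), computed with IRanges; intersection is the strictest
reading of "shared" and is the documented default.  Group membership is
always configuration, never inferred.

## Genomic inbreeding coefficients

Ten per-individual coefficients, all using within-population allele
frequencies:

* `F_GRM = G_ii - 1` (VanRaden diagonal).
* `F_HOM1 = (E_het - O_het)/E_het`, a ratio of sums over the
  individual's non-missing SNPs.  This heterozygosity form is
  algebraically identical to the `(O_hom - E_hom)/(N - E_hom)`
  excess-homozygosity form and is positive for inbred individuals; a
  literal "homozygous counts" reading would flip the sign and contradict
  the sign conventions of published tables.
* `F_HOM2`: mean over SNPs of `1 - x(2-x)/(2p(1-p))` (mean of ratios).
* `F_UNI`: ratio of sums of `x² - (1+2p)x + 2p²` over `2p(1-p)`.
* `F_ROH` and five length-stratified variants: ROH length over
  `L_auto`, the SNP-spanned autosome length (sum over autosomes of last
  minus first SNP position + 1); the five class values sum exactly to
  the total.

The aggregation choices (ratio-of-sums for F_HOM1 and F_UNI,
mean-of-ratios for F_HOM2) follow the conventions of the tools these
estimators originate from and reproduce the empirical pattern that
F_HOM1 and F_HOM2 are near-identical but not equal.  Under
Hardy–Weinberg equilibrium all four marker-based estimators are
calibrated near zero (validated at n = 300, m = 10,000), and on
full-sib pedigrees they recover the pedigree expectation (0.25 after
one generation).  Correlations among all ten are Pearson, with
zero-variance metrics yielding flagged `NA`, never silent zeros.

## LD and effective population size

Pairwise r² on unphased genotypes uses maximum-likelihood haplotype
frequencies from the two-locus genotype table via EM (only the double
heterozygote is phase-ambiguous; convergence tolerance 1e-10 on the
coupling probability, cap 1000 iterations, fallback to the squared
dosage correlation with a warning).  The squared dosage correlation is
also available directly as the fast composite estimator.  LD decay is
the unweighted mean r² in contiguous 100-kb distance bins up to 2 Mb.

Effective population size uses the Sved relationship: for generation
`t`, pairs whose map distance lies in `(1/(2(t+0.5)), 1/(2(t-0.5))]`
Morgans estimate `Ne(t) = (1/(4c_t))(1/E[r²_adj] - α)` with
`c_t = 1/(2t)`.  Design choices, each exposed as configuration:
a linear 1 cM/Mb map (the conventional assumption, which maps
t ∈ [25, 100] exactly onto the 0.5–2 Mb distances the LD analysis
covers); `α = 1` (the classical drift-only form; 2.2 is the common
mutation-adjusted variant); and the finite-sample correction
`r²_adj = r² - 1/n` (default on, since raw r² is inflated by sampling).
Parameter recovery on constant-Ne Wright–Fisher simulations (Ne = 100,
50 samples, ~15,300 SNPs on 18 × 100 Mb, 200 generations of history, 10
replicates) returns median estimates within [86, 142] across
t ∈ {25, 50, 75, 100} with a flat trajectory.

## F_ST scans

Per-SNP differentiation uses the Weir–Cockerham (1984) two-population
variance components `a`, `b`, `c`; negative estimates are kept (they are
legitimate finite-sample behaviour).  Windows of 100 kb slide in 10-kb
steps anchored at position 1; the window statistic is the ratio of sums
`Σa/Σ(a+b+c)` (the "weighted" definition of the tool that popularised
windowed F_ST).  Outliers are the top 1% of windows genome-wide per
scan: the cutoff is the k-th largest value with
`k = max(1, floor(0.01 · n_windows))`, ties kept — so 100 distinct
windows yield exactly one outlier.  Shared outliers between two scans
are the genomic intersection of merged outlier windows.  On
drift-only divergence (Ne = 100, t = 20), the genome-wide weighted
theta matches the drift expectation `1 - (1 - 1/(2Ne))^t ≈ 0.095`
within 10%.

## The synthetic-data generator

A forward-in-time Wright–Fisher simulator provides ground truth for
every stage; forward simulation (rather than a coalescent) directly
produces the recent-generation LD regime the Ne estimator probes and
makes planting inbreeding, tracts and sweeps trivial.

* **Founders**: `2·Ne` haplotypes in linkage equilibrium, SNP positions
  uniform per chromosome (even allocation), allele frequencies uniform
  on `[0.05, 0.95]` — an array-like ascertained spectrum, matching the
  MAF floor of the arrays being emulated.
* **Evolution**: non-overlapping generations; two distinct parents per
  offspring (no selfing — these are pigs); gametes recombine as a
  Poisson process on a linear 1 cM/Mb map (Haldane, no interference);
  optional per-site mutation.  The generation loop is compiled (Rcpp)
  and uses R's RNG, so `set.seed()` governs everything.
* **Inbred lines**: repeated full-sib mating with the pedigree-expected
  F recorded per individual (0.25, 0.375, 0.5, 0.594 for 1–4
  generations).
* **Planted truth**: `plant_autozygosity` copies one haplotype over the
  other inside an interval (an IBD tract with known bounds);
  `plant_sweep` copies a reference haplotype onto both chromosomes of a
  carrier fraction (an ROH-island footprint); `diverge_populations`
  splits one founder pool into two drifting replicates with the
  closed-form expected F_ST recorded.
* **Detector-validation background**: `simulate_max_het_population`
  produces individuals heterozygous at every SNP (an F1 between
  oppositely fixed inbred lines).  Planted-tract boundary recovery is
  only well-posed on this background: on an outbred background, chance
  runs of homozygous flanking SNPs (each ~63% homozygous) legitimately
  extend the *observed* IBS run beyond the planted IBD tract, so exact
  boundary truth does not exist.  Boundary-recovery tests therefore use
  the heterozygous background, and tracts are placed in regions with no
  internal map gap above the detector's 500-kb split rule.

What the generator does **not** emulate: realistic pig demography,
ascertainment bias beyond the MAF floor, genotyping error, variable
recombination maps, or selection other than the haplotype-copy sweep.
Passing parameter-recovery tests therefore demonstrates correctness of
the estimators under their own model assumptions, not robustness to
array artefacts or demographic misspecification.

## Problem sizes and runtime

The validation suite runs, on one CPU in a few minutes: 200
random-genome ROH oracle comparisons (≤ 300 SNPs each); 50 planted
tracts on a 30,000-SNP map; HWE calibration at n = 300, m = 10,000; a
300-individual inbreeding gradient at 20,000 SNPs; 10 Wright–Fisher
replicates of ~15,300 SNPs for Ne recovery; 10 divergence replicates of
5,000 SNPs for F_ST; and a sweep recovery on a 6,000-SNP map.  These
sizes sit at the lower end of the array densities the package targets
(18,000–52,000 SNPs per population) and were chosen so the full suite
re-runs quickly on a laptop.

## Known limitations

* PED/MAP parsing covers the common PLINK text dialect (ACGT/0 codes);
  binary PLINK, phasing, imputation and liftover are out of scope.
* Merging multi-array datasets (strand flips, shared-SNP intersection
  across platforms) is not provided beyond subsetting utilities.
* The Ne estimator assumes the linear map and the Sved form; no
  confidence intervals are reported.
* ROH boundary precision is inherently ±1 SNP at abrupt
  heterozygosity boundaries and worse on outbred backgrounds (see
  above); island bounds inherit candidate-SNP granularity.
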