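# Rule-by-rule QC fixture: 60 samples x 20 SNPs with exactly one
# engineered violation of each applicable rule.  Note on sizing: with the
# exact HWE test, a heterozygote-free SNP needs ~30 samples per genotype
# class before its p-value can fall below 1e-6, so the fixture uses 60
# samples.
#
# Construction (rules in application order):
#   rule 1: snp_cr     missing in 4/60 samples  -> call rate 0.933 < 0.95
#   rule 2: snp_maf    3 het, 57 ref-hom        -> MAF 0.025 < 0.05
#   rule 3: sample S60 missing at 2 surviving SNPs -> call rate 16/18 < 0.90
#           (no SNP can fail rule 3's 0.90 after surviving rule 1's 0.95,
#            so the SNP count for rule 3 is structurally 0)
#   rule 4: snp_hwe    30 AA / 0 Aa / 29 aa among the remaining 59
#   rule 5: snp_pos0   position 0 (unknown)
#   rule 6: snp_x      on chromosome X
# Expected: removals (1, 1, 0 SNPs + 1 sample, 1, 1, 1); 15 SNPs and 59
# samples survive.
make_qc_fixture <- function() {
  n <- 60
  base_pattern <- function(shift) {
    g <- rep(c(0L, 1L, 1L, 2L), length.out = n)
    g[((seq_len(n) + shift) %% n) + 1L]
  }
  cols <- list()
  ids <- character()
  add <- function(id, g) {
    cols[[length(cols) + 1L]] <<- g
    ids[length(ids) + 1L] <<- id
  }
  add("snp_pos0", base_pattern(1))              # rule 5 (position 0)
  for (k in 1:6) add(paste0("snp_ok_a", k), base_pattern(k + 1))
  add("snp_cr", {                               # rule 1
    g <- base_pattern(8); g[1:4] <- NA; g
  })
  add("snp_maf", c(rep(1L, 3), rep(0L, n - 3))) # rule 2
  add("snp_hwe", c(rep(2L, 30), rep(0L, 30)))   # rule 4 (59 after S60 drop)
  for (k in 1:7) add(paste0("snp_ok_b", k), base_pattern(k + 9))
  add("snp_mis1", { g <- base_pattern(17); g[n] <- NA; g })  # S60 missing
  add("snp_mis2", { g <- base_pattern(18); g[n] <- NA; g })  # S60 missing
  add("snp_x", base_pattern(19))                # rule 6
  dosage <- do.call(cbind, cols)
  chrom <- c(rep("1", 10), rep("2", 9), "X")
  pos <- c(0L, seq(1e6, 9e6, by = 1e6),         # chrom 1
           seq(1e6, 9e6, by = 1e6),             # chrom 2
           5e6)                                 # X
  variants <- data.frame(snp_id = ids, chromosome = chrom,
                         position_bp = as.integer(pos),
                         allele_a = "A", allele_b = "G",
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("S%02d", seq_len(n)),
                        population = "fix", group = NA_character_,
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(dosage, samples, variants)
  list(gm = gm,
       expected = list(snps_removed = c(1L, 1L, 0L, 1L, 1L, 1L),
                       samples_removed = c(0L, 0L, 1L, 0L, 0L, 0L),
                       output_snps = 15L, output_samples = 59L))
}

# small deterministic dosage matrix (with optional missingness) for
# oracle-equality tests
random_dosage_gm <- function(n, m, miss_rate = 0, seed = 1,
                             n_chrom = 1) {
  set.seed(seed)
  dosage <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss_rate > 0)
    dosage[runif(n * m) < miss_rate] <- NA
  per <- ceiling(m / n_chrom)
  chrom <- as.character(rep(seq_len(n_chrom), each = per)[seq_len(m)])
  pos <- unlist(lapply(rle(chrom)$lengths, function(k)
    sort(sample.int(1e8, k))))
  variants <- data.frame(snp_id = paste0("s", seq_len(m)),
                         chromosome = chrom,
                         position_bp = pos, allele_a = "A",
                         allele_b = "C", stringsAsFactors = FALSE)
  genotype_matrix(dosage, data.frame(sample_id = paste0("i", seq_len(n)),
                                     population = "p1"),
                  variants)
}
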