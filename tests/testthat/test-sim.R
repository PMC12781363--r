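test_that("simulate_founders allocates SNPs evenly with truncated spectra
           and is seed-deterministic", {
  cfg <- sim_config(n_snps = 1800, n_chromosomes = 18, ne = 30, seed = 41)
  pool <- simulate_founders(cfg)
  expect_equal(unname(table(pool$variants$chromosome)[as.character(1:18)]),
               rep(100L, 18), ignore_attr = TRUE)
  expect_true(all(pool$founder_freq >= 0.05 &
                    pool$founder_freq <= 0.95))
  pool2 <- simulate_founders(cfg)
  expect_identical(pool$haplotypes, pool2$haplotypes)
  expect_identical(pool$variants, pool2$variants)
  expect_error(sim_config(n_snps = 5, n_chromosomes = 18, seed = 1),
               "at least")
})

test_that("Wright-Fisher heterozygosity decays at the drift rate", {
  cfg <- sim_config(n_snps = 3000, n_chromosomes = 6, ne = 100,
                    n_generations = 60, seed = 42)
  pool <- simulate_founders(cfg)
  founder_gm <- simulate_wright_fisher(pool, n_sample = 100,
                                       generations = 0)$gm
  h0 <- mean(founder_gm$dosage == 1L)
  gm <- simulate_wright_fisher(pool, n_sample = 100)$gm
  h1 <- mean(gm$dosage == 1L)
  expect_lt(abs(h1 / h0 - (1 - 1 / 200)^60), 0.05)
})

test_that("zero generations returns paired founder haplotypes; seeds fix
           the whole trajectory", {
  cfg <- sim_config(n_snps = 300, n_chromosomes = 2, ne = 20,
                    n_generations = 5, seed = 43)
  pool <- simulate_founders(cfg)
  set.seed(1)
  s0 <- simulate_wright_fisher(pool, n_sample = 20, generations = 0)
  expect_equal(unname(s0$gm$dosage),
               unname(pool$haplotypes[seq(1, 40, 2), ] +
                        pool$haplotypes[seq(2, 40, 2), ]))
  set.seed(99); a <- simulate_wright_fisher(pool, n_sample = 10)
  set.seed(99); b <- simulate_wright_fisher(pool, n_sample = 10)
  expect_identical(a$gm$dosage, b$gm$dosage)
})

test_that("full-sib lines carry the pedigree-expected inbreeding", {
  expect_equal(genodiv:::sib_expected_f(0), 0)
  expect_equal(genodiv:::sib_expected_f(1), 0.25)
  expect_equal(genodiv:::sib_expected_f(2), 0.375)
  expect_equal(genodiv:::sib_expected_f(3), 0.5)
  expect_equal(genodiv:::sib_expected_f(4), 0.59375)
  cfg <- sim_config(n_snps = 4000, n_chromosomes = 4, ne = 300, seed = 44)
  pool <- simulate_founders(cfg)
  set.seed(2)
  sim <- simulate_inbred_lines(pool, generations = rep(1L, 100))
  expect_equal(unname(sim$truth$expected_f), rep(0.25, 100))
  f <- f_hom1(sim$gm)
  expect_gt(mean(f), 0.17)
  expect_lt(mean(f), 0.33)
  sim0 <- simulate_inbred_lines(pool, generations = 0L, n_per_line = 5)
  expect_equal(unname(sim0$truth$expected_f), rep(0, 5))
})

test_that("plant_autozygosity forces homozygosity and books the truth", {
  cfg <- sim_config(n_snps = 2000, n_chromosomes = 2, chrom_length_mb = 50,
                    ne = 30, seed = 45)
  pool <- simulate_founders(cfg)
  set.seed(3)
  sim <- simulate_wright_fisher(pool, n_sample = 10, generations = 0)
  sid <- sim$gm$samples$sample_id[4]
  sim <- plant_autozygosity(sim, sid, "1", 10e6, 11e6)
  idx <- sim$variants$chromosome == "1" &
    sim$variants$position_bp >= 10e6 & sim$variants$position_bp <= 11e6
  expect_true(all(sim$gm$dosage[4, idx] %in% c(0L, 2L)))
  span <- genodiv:::snp_span_bp(sim$variants)
  expect_equal(unname(sim$truth$autozygosity_fraction[sid]),
               (11e6 - 10e6 + 1) / span)
  # overlapping plants are not double-counted
  sim <- plant_autozygosity(sim, sid, "1", 10.5e6, 11.5e6)
  expect_equal(unname(sim$truth$autozygosity_fraction[sid]),
               (11.5e6 - 10e6 + 1) / span)
  expect_equal(nrow(sim$truth$tracts), 2L)
})

test_that("plant_sweep makes carriers homozygous for one haplotype", {
  cfg <- sim_config(n_snps = 3000, n_chromosomes = 3, chrom_length_mb = 30,
                    ne = 60, seed = 46)
  pool <- simulate_founders(cfg)
  set.seed(4)
  sim <- simulate_wright_fisher(pool, n_sample = 50, generations = 0)
  sim <- plant_sweep(sim, "2", 5e6, 6e6, carrier_fraction = 0.6)
  idx <- which(sim$variants$chromosome == "2" &
                 sim$variants$position_bp >= 5e6 &
                 sim$variants$position_bp <= 6e6)
  hom_ref <- apply(sim$gm$dosage[, idx], 1, function(x)
    all(x == 2L * sim$haplotypes[1L, idx]))
  expect_equal(sum(hom_ref), 30L)
  expect_equal(sim$truth$sweeps$carrier_fraction, 0.6)
})

test_that("diverged populations report the drift-expected F_ST", {
  cfg <- sim_config(n_snps = 500, n_chromosomes = 2, ne = 100, seed = 47)
  pool <- simulate_founders(cfg)
  set.seed(5)
  div <- diverge_populations(pool, t_div = 20, n_sample = 20)
  expect_equal(div$expected_fst, 1 - (1 - 1 / 200)^20)
  expect_equal(div$pop1$truth$divergence_time_generations, 20)
  set.seed(5)
  div2 <- diverge_populations(pool, t_div = 20, n_sample = 20)
  expect_identical(div$pop1$gm$dosage, div2$pop1$gm$dosage)
})

test_that("simulated output validates and round-trips through writers", {
  cfg <- sim_config(n_snps = 400, n_chromosomes = 2, ne = 25, seed = 48)
  pool <- simulate_founders(cfg)
  set.seed(6)
  sim <- simulate_wright_fisher(pool, n_sample = 12, generations = 10)
  expect_silent(validate_genotype_matrix(sim$gm))
  prefix <- file.path(withr::local_tempdir(), "fix")
  write_sim_fixture(sim, prefix)
  expect_true(file.exists(paste0(prefix, ".ped")))
  expect_true(file.exists(paste0(prefix, ".truth.json")))
  back <- read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  # compare dosages of the simulation's counted allele, whatever allele
  # the PLINK reader chose to count (monomorphic SNPs come back with an
  # unseen counted allele "0" and all-zero dosage)
  for (j in seq_len(ncol(back$dosage))) {
    want <- unname(sim$gm$dosage[, j])
    aa <- sim$gm$variants$allele_a[j]
    if (back$variants$allele_a[j] == aa) {
      expect_equal(unname(back$dosage[, j]), want)
    } else if (back$variants$allele_b[j] == aa) {
      expect_equal(2L - unname(back$dosage[, j]), want)
    } else {
      expect_true(all(want == 0L))   # counted allele absent from the file
      expect_true(all(back$dosage[, j] == 0L))
    }
  }
  vback <- read_vcf(paste0(prefix, ".vcf"))
  expect_equal(unname(vback$dosage), unname(sim$gm$dosage))
})

test_that("max-het background is heterozygous everywhere until planted", {
  cfg <- sim_config(n_snps = 1000, n_chromosomes = 2, chrom_length_mb = 40,
                    ne = 20, seed = 49)
  pool <- simulate_founders(cfg)
  set.seed(7)
  sim <- simulate_max_het_population(pool, n_sample = 5)
  expect_true(all(sim$gm$dosage == 1L))
  sim <- plant_autozygosity(sim, sim$gm$samples$sample_id[1], "1",
                            5e6, 9e6)
  idx <- sim$variants$chromosome == "1" &
    sim$variants$position_bp >= 5e6 & sim$variants$position_bp <= 9e6
  expect_true(all(sim$gm$dosage[1, idx] %in% c(0L, 2L)))
  expect_true(all(sim$gm$dosage[1, !idx] == 1L))
})
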