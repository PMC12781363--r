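write_mini_vcf <- function(path, records,
                           samples = c("ind1", "ind2")) {
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", samples),
                     collapse = "\t"),
               records), path)
  path
}

test_that("read_vcf counts ALT alleles and maps missing/half calls to NA", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(f, c(
    paste(c("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
            "0/1", "1/1"), collapse = "\t"),
    paste(c("1", "200", "rs2", "T", "C", ".", "PASS", ".", "GT",
            "./.", "0|0"), collapse = "\t"),
    paste(c("1", "300", "rs3", "G", "A", ".", "PASS", ".", "GT",
            "./1", "1/1"), collapse = "\t")))
  gm <- read_vcf(f)
  expect_equal(dim(gm), c(2L, 3L))
  expect_equal(unname(gm$dosage[, 1]), c(1L, 2L))           # 0/1, 1/1
  expect_equal(unname(gm$dosage[, 2]), c(NA_integer_, 0L))  # ./., 0|0
  expect_equal(unname(gm$dosage[, 3]), c(NA_integer_, 2L))  # half call
  expect_equal(gm$variants$allele_a, c("G", "C", "A"))      # ALT counted
})

test_that("read_vcf keeps only biallelic SNP records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(f, c(
    paste(c("1", "100", "a", "A", "G", ".", ".", ".", "GT", "0/0", "0/1"),
          collapse = "\t"),
    paste(c("1", "200", "b", "A", "G,T", ".", ".", ".", "GT", "0/1", "1/2"),
          collapse = "\t"),
    paste(c("1", "300", "c", "AT", "A", ".", ".", ".", "GT", "0/1", "0/0"),
          collapse = "\t"),
    paste(c("1", "400", "d", "C", "T", ".", ".", ".", "GT", "1/1", "0/1"),
          collapse = "\t")))
  gm <- read_vcf(f)
  expect_equal(gm$variants$snp_id, c("a", "d"))
})

test_that("read_vcf rejects duplicate sample IDs and missing files", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_mini_vcf(f, paste(c("1", "100", "a", "A", "G", ".", ".", ".",
                            "GT", "0/0", "0/1"), collapse = "\t"),
                 samples = c("dup", "dup"))
  expect_error(read_vcf(f), "duplicate sample")
  expect_error(read_vcf(tempfile()), "not found")
})

test_that("read_plink_text determines the counted (minor) allele", {
  dir <- withr::local_tempdir()
  writeLines(c("1 s1 0 100", "1 s2 0 200"), file.path(dir, "t.map"))
  # s1: freq(A) = 3/8 -> A minor, counted; s2: 0 0 missing for i1
  writeLines(c("fam1 i1 0 0 0 -9 A A 0 0",
               "fam1 i2 0 0 0 -9 A G G G",
               "fam1 i3 0 0 0 -9 G G G G",
               "fam1 i4 0 0 0 -9 G G A G"),
             file.path(dir, "t.ped"))
  gm <- read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  expect_equal(gm$variants$allele_a[1], "A")
  expect_equal(unname(gm$dosage[, 1]), c(2L, 1L, 0L, 0L))
  expect_equal(unname(gm$dosage[, 2]), c(NA_integer_, 0L, 0L, 1L))
  expect_equal(gm$samples$population, rep("fam1", 4))
})

test_that("read_plink_text validates column counts and allele codes", {
  dir <- withr::local_tempdir()
  writeLines(c("1 s1 0 100", "1 s2 0 200"), file.path(dir, "t.map"))
  writeLines("fam i1 0 0 0 -9 A A", file.path(dir, "t.ped"))
  expect_error(read_plink_text(file.path(dir, "t.ped"),
                               file.path(dir, "t.map")),
               "column count")
  writeLines("fam i1 0 0 0 -9 A A N N", file.path(dir, "t.ped"))
  expect_error(read_plink_text(file.path(dir, "t.ped"),
                               file.path(dir, "t.map")),
               "non-ACGT0")
})

test_that("subset_genotypes slices consistently and rejects empty selections", {
  gm <- random_dosage_gm(10, 30, seed = 3, n_chrom = 2)
  gm$samples$population <- rep(c("Duroc1", "Duroc2"), each = 5)
  sub <- subset_genotypes(gm, sample_filter = function(s)
    s$population == "Duroc1")
  expect_equal(nrow(sub$dosage), 5L)
  expect_equal(sub$samples$population, rep("Duroc1", 5))
  sub2 <- subset_genotypes(gm, variant_filter = function(v)
    v$chromosome == "1")
  expect_true(all(sub2$variants$chromosome == "1"))
  expect_equal(sub2$dosage,
               gm$dosage[, gm$variants$chromosome == "1"])
  ident <- subset_genotypes(gm, sample_filter = function(s) rep(TRUE, nrow(s)),
                            variant_filter = function(v) rep(TRUE, nrow(v)))
  expect_equal(ident$dosage, gm$dosage)
  expect_error(subset_genotypes(gm, sample_filter = function(s)
    s$population == "nope"), "empty sample selection")
})

test_that("PLINK text round-trips dosages up to counted-allele flips", {
  gm <- random_dosage_gm(12, 40, miss_rate = 0.05, seed = 11, n_chrom = 2)
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_plink_text(gm, prefix)
  back <- read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_equal(back$variants$position_bp, gm$variants$position_bp)
  for (j in seq_len(ncol(gm$dosage))) {
    a <- gm$dosage[, j]; b <- back$dosage[, j]
    flip <- back$variants$allele_a[j] != gm$variants$allele_a[j]
    expect_equal(b, if (flip) 2L - a else a,
                 info = paste("snp", j))
  }
})

test_that("VCF writer round-trips through read_vcf exactly", {
  gm <- random_dosage_gm(8, 25, miss_rate = 0.1, seed = 5, n_chrom = 2)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, f)
  back <- read_vcf(f)
  expect_equal(unname(back$dosage), unname(gm$dosage))
  expect_equal(back$variants$position_bp, gm$variants$position_bp)
  expect_equal(back$variants$allele_a, gm$variants$allele_a)
})

test_that("VCF and PLINK text of the same cohort agree after harmonization", {
  gm <- sim_example_population(n = 15, n_snps = 60, seed = 9)
  dir <- withr::local_tempdir()
  write_vcf(gm, file.path(dir, "c.vcf"))
  write_plink_text(gm, file.path(dir, "c"))
  g1 <- read_vcf(file.path(dir, "c.vcf"))
  g2 <- read_plink_text(file.path(dir, "c.ped"), file.path(dir, "c.map"))
  expect_equal(g1$variants$snp_id, g2$variants$snp_id)
  # compare dosages of the VCF's counted (ALT) allele; monomorphic SNPs
  # come back from PLINK text with an unseen counted allele and dosage 0
  for (j in seq_len(ncol(g1$dosage))) {
    want <- unname(g1$dosage[, j])
    aa <- g1$variants$allele_a[j]
    if (g2$variants$allele_a[j] == aa) {
      expect_equal(unname(g2$dosage[, j]), want)
    } else if (g2$variants$allele_b[j] == aa) {
      expect_equal(2L - unname(g2$dosage[, j]), want)
    } else {
      expect_true(all(want == 0L))
    }
  }
})

test_that("BED export converts 1-based closed to 0-based half-open", {
  seg <- data.frame(chromosome = "3", start_bp = 1001L, end_bp = 2000L,
                    sample_id = "s1")
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(seg, f, name_col = "sample_id")
  out <- read.table(f, sep = "\t")
  expect_equal(out$V2, 1000L)
  expect_equal(out$V3, 2000L)
})

test_that("write_tsv emits a header-only file for empty tables and the
           11-column inbreeding schema", {
  f <- withr::local_tempfile(fileext = ".tsv")
  empty <- data.frame(chromosome = character(), start_bp = integer(),
                      end_bp = integer())
  write_tsv(empty, f)
  expect_equal(readLines(f), "chromosome\tstart_bp\tend_bp")
  gm <- sim_example_population(n = 6, n_snps = 50, seed = 2)
  recs <- suppressWarnings(inbreeding_records(gm, detect_roh(gm)))
  write_tsv(recs, f)
  header <- strsplit(readLines(f, n = 1), "\t")[[1]]
  expect_length(header, 11L)   # sample + 10 coefficients
  expect_equal(header[1], "sample_id")
})
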