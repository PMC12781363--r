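# build a one-sample, one-chromosome genotype matrix from a genotype
# vector and positions
roh_gm <- function(g, pos) {
  variants <- data.frame(snp_id = paste0("s", seq_along(g)),
                         chromosome = "1", position_bp = as.integer(pos),
                         allele_a = "A", allele_b = "G",
                         stringsAsFactors = FALSE)
  genotype_matrix(matrix(as.integer(g), nrow = 1),
                  data.frame(sample_id = "ind1", population = "p"),
                  variants)
}

test_that("a planted homozygous run flanked by dense heterozygotes is
           recovered at the planted boundaries", {
  # 60 homozygous SNPs spanning 900 kb (one per ~15 kb), het flanks
  pos <- c(seq(1e5, 1e6, length.out = 60),            # left het flank
           seq(2e6, 2.9e6, length.out = 60),          # planted run
           seq(4e6, 4.9e6, length.out = 60))          # right het flank
  g <- c(rep(1L, 60), rep(c(0L, 2L), 30), rep(1L, 60))
  gm <- roh_gm(g, round(pos))
  segs <- detect_roh(gm)
  expect_equal(nrow(segs), 1L)
  # the hit-fraction rule trims exactly the outermost run SNP on each
  # side (covered by only 2/50 homozygous windows, below the 5%
  # threshold), so the recovered bounds sit one SNP inside the plant
  expect_equal(segs$start_bp, round(pos[62]))
  expect_equal(segs$end_bp, round(pos[119]))
  expect_equal(segs$n_snps, 58L)
  # and the brute-force oracle agrees
  orc <- oracle_roh_scan(g, round(pos), roh_params())
  expect_equal(segs$start_bp, orc$start_bp)
  expect_equal(segs$end_bp, orc$end_bp)
})

test_that("runs shorter than 500 kb are rejected", {
  pos <- c(seq(1e5, 1.5e6, length.out = 60),
           seq(2e6, 2.4e6, length.out = 30),          # 400 kb homozygous
           seq(3e6, 4.5e6, length.out = 60))
  g <- c(rep(1L, 60), rep(2L, 30), rep(1L, 60))
  segs <- detect_roh(roh_gm(g, round(pos)))
  expect_equal(nrow(segs), 0L)
})

test_that("a large inter-SNP gap splits a candidate run (oracle agreement)", {
  # 1.4 Mb homozygous stretch with a 600 kb gap in the middle
  pos <- c(seq(1e5, 1e6, length.out = 50),
           seq(2e6, 2.4e6, length.out = 12),
           seq(3e6, 3.4e6, length.out = 12),          # gap 2.4 -> 3.0 Mb
           seq(4e6, 5e6, length.out = 50))
  g <- c(rep(1L, 50), rep(0L, 24), rep(1L, 50))
  params <- roh_params()
  segs <- detect_roh(roh_gm(g, round(pos)), params)
  orc <- oracle_roh_scan(g, round(pos), params)
  expect_equal(nrow(segs), nrow(orc))
  if (nrow(segs)) {
    expect_equal(segs$start_bp, orc$start_bp)
    expect_equal(segs$end_bp, orc$end_bp)
  }
})

test_that("detector equals the brute-force oracle on random genomes", {
  set.seed(101)
  params <- roh_params()
  for (rep in 1:60) {
    m <- sample(30:300, 1)
    span <- sample(c(3e6, 1e7, 5e7), 1)
    pos <- sort(sample.int(span, m))
    # blocky genotypes: alternate homozygous-rich and het-rich patches
    g <- integer(m)
    i <- 1
    while (i <= m) {
      len <- min(m - i + 1, sample(5:80, 1))
      kind <- sample(1:3, 1)
      g[i:(i + len - 1)] <- switch(kind,
        sample(c(0L, 2L), len, replace = TRUE),
        sample(c(0L, 1L, 2L), len, replace = TRUE),
        sample(c(0L, 1L, 2L, NA), len, replace = TRUE))
      i <- i + len
    }
    segs <- detect_roh(roh_gm(g, pos), params)
    orc <- oracle_roh_scan(g, pos, params)
    expect_equal(nrow(segs), nrow(orc), info = paste("rep", rep))
    if (nrow(orc)) {
      expect_equal(segs$start_bp, orc$start_bp, info = paste("rep", rep))
      expect_equal(segs$end_bp, orc$end_bp, info = paste("rep", rep))
      expect_equal(segs$n_snps, as.integer(orc$n_snps),
                   info = paste("rep", rep))
    }
  }
})

test_that("emitted segments always satisfy the declared constraints", {
  gm <- sim_example_population(n = 20, n_snps = 1500, seed = 31,
                               generations = 60)
  params <- roh_params()
  segs <- detect_roh(gm, params)
  if (nrow(segs)) {
    expect_true(all(segs$length_bp >= params$min_length_kb * 1000))
    expect_true(all(segs$n_snps >= params$min_snps))
    expect_true(all(segs$length_bp / segs$n_snps <=
                      params$max_kb_per_snp * 1000))
    expect_equal(segs$length_bp, segs$end_bp - segs$start_bp + 1)
  }
  # fully heterozygous individual: no segments
  het <- roh_gm(rep(1L, 200), sort(sample.int(5e7, 200)))
  expect_equal(nrow(detect_roh(het)), 0L)
  # fully homozygous individual on a dense map: near-complete coverage
  set.seed(8)
  pos <- sort(sample.int(3e7, 1000))
  hom <- roh_gm(rep(2L, 1000), pos)
  segs2 <- detect_roh(hom)
  expect_gte(sum(segs2$length_bp), 0.95 * (max(pos) - min(pos) + 1))
})

test_that("length classes use lower-inclusive boundaries", {
  segs <- data.frame(sample_id = "s", chromosome = "1",
                     start_bp = 1L,
                     end_bp = c(19e5, 2e6, 16e6),
                     n_snps = 100L,
                     length_bp = c(1.9e6, 2.0e6, 16.0e6))
  segs$length_class <- genodiv:::roh_length_class(segs$length_bp)
  expect_equal(as.character(segs$length_class), c("lt2", "2to4", "gt16"))
  summ <- roh_summary(segs)
  expect_equal(summ$n_lt2, 1L)
  expect_equal(summ$n_2to4, 1L)
  expect_equal(summ$n_gt16, 1L)
})

test_that("roh_summary matches a loop-based oracle on random segments", {
  set.seed(5)
  lens <- runif(100, 0.5e6, 40e6)
  segs <- data.frame(sample_id = sample(c("a", "b"), 100, TRUE),
                     chromosome = "1", start_bp = 1L,
                     end_bp = as.integer(lens), n_snps = 50L,
                     length_bp = lens)
  segs$length_class <- genodiv:::roh_length_class(lens)
  summ <- roh_summary(segs)
  expect_equal(summ$n_roh, 100L)
  expect_equal(summ$mean_length_mb, mean(lens) / 1e6)
  expect_equal(summ$sd_length_mb, sd(lens) / 1e6)
  counts <- c(sum(lens < 2e6), sum(lens >= 2e6 & lens < 4e6),
              sum(lens >= 4e6 & lens < 8e6),
              sum(lens >= 8e6 & lens < 16e6), sum(lens >= 16e6))
  expect_equal(unlist(summ[, c("n_lt2", "n_2to4", "n_4to8", "n_8to16",
                               "n_gt16")], use.names = FALSE), counts)
  # single 3 Mb segment: mean 3, sd 0
  s1 <- segs[1, ]; s1$length_bp <- 3e6
  s1$length_class <- genodiv:::roh_length_class(3e6)
  summ1 <- roh_summary(s1)
  expect_equal(summ1$mean_length_mb, 3)
  expect_equal(summ1$sd_length_mb, 0)
})

test_that("roh_incidence equals the interval-containment oracle", {
  gm <- random_dosage_gm(10, 50, seed = 6, n_chrom = 2)
  set.seed(6)
  v <- gm$variants
  segs <- do.call(rbind, lapply(1:7, function(i) {
    ch <- sample(c("1", "2"), 1)
    p <- sort(sample(v$position_bp[v$chromosome == ch], 2))
    data.frame(sample_id = sample(gm$samples$sample_id, 1),
               chromosome = ch, start_bp = p[1], end_bp = p[2])
  }))
  inc <- roh_incidence(segs, gm)
  # loop oracle
  for (j in seq_len(nrow(v))) {
    cnt <- 0
    for (s in gm$samples$sample_id) {
      ss <- segs[segs$sample_id == s, ]
      hit <- FALSE
      for (q in seq_len(nrow(ss)))
        if (ss$chromosome[q] == v$chromosome[j] &&
            ss$start_bp[q] <= v$position_bp[j] &&
            v$position_bp[j] <= ss$end_bp[q]) hit <- TRUE
      cnt <- cnt + hit
    }
    expect_equal(unname(inc[j]), cnt / 10)
  }
  # simple known case: 5 of 10 individuals covering one SNP
  segs5 <- data.frame(sample_id = gm$samples$sample_id[1:5],
                      chromosome = v$chromosome[3],
                      start_bp = v$position_bp[3], end_bp = v$position_bp[3])
  expect_equal(unname(roh_incidence(segs5, gm)[3]), 0.5)
})

test_that("detect_islands applies the dual threshold and the merge rule", {
  # 1000 SNPs; 8 consecutive SNPs at 0.6 within 50 kb; rest at 0.05
  pos <- seq(1e5, by = 6e4, length.out = 1000)
  pos[500:507] <- seq(pos[500], by = 40e3, length.out = 8)
  pos <- as.integer(sort(pos))
  variants <- data.frame(snp_id = paste0("s", 1:1000), chromosome = "1",
                         position_bp = pos, allele_a = "A", allele_b = "G")
  inc <- rep(0.05, 1000)
  inc[500:507] <- 0.6
  isl <- detect_islands(inc, variants)
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$start_bp, pos[500])
  expect_equal(isl$end_bp, pos[507])
  expect_equal(isl$n_snps, 8L)
  expect_equal(isl$peak_incidence, 0.6)
  # all incidences below the 35% floor: no islands
  expect_equal(nrow(detect_islands(rep(0.10, 1000), variants)), 0L)
  # two candidates 150 kb apart stay separate islands
  inc2 <- rep(0.05, 1000)
  inc2[c(200, 300)] <- 0.9
  variants2 <- variants
  variants2$position_bp[300] <- variants2$position_bp[200] + 150e3
  variants2$position_bp <- as.integer(sort(variants2$position_bp))
  isl2 <- detect_islands(inc2, variants2)
  expect_equal(nrow(isl2), 2L)
})

test_that("shared_islands intersects across all member populations", {
  a <- data.frame(chromosome = "1", start_bp = 1000000L, end_bp = 2000000L)
  b <- data.frame(chromosome = "1", start_bp = 1500000L, end_bp = 2500000L)
  sh <- shared_islands(list(A = a, B = b))
  expect_equal(sh$start_bp, 1500000L)
  expect_equal(sh$end_bp, 2000000L)
  disj <- data.frame(chromosome = "1", start_bp = 5e6, end_bp = 6e6)
  expect_equal(nrow(shared_islands(list(A = a, B = disj))), 0L)
  expect_error(shared_islands(list(A = a)), "at least two")
  # three random island sets versus a per-bp grid oracle
  set.seed(9)
  mk <- function() {
    s <- sort(sample.int(500, 8))
    data.frame(chromosome = "1", start_bp = s[c(1, 3, 5, 7)] * 1000L,
               end_bp = (s[c(2, 4, 6, 8)] + 1) * 1000L)
  }
  sets <- list(mk(), mk(), mk())
  sh3 <- shared_islands(sets)
  grid <- seq(1, 510000)
  covered <- lapply(sets, function(df) {
    x <- logical(length(grid))
    for (i in seq_len(nrow(df)))
      x[df$start_bp[i]:df$end_bp[i]] <- TRUE
    x
  })
  all_cov <- Reduce(`&`, covered)
  oracle_total <- sum(all_cov)
  got_total <- if (nrow(sh3)) sum(sh3$end_bp - sh3$start_bp + 1) else 0
  expect_equal(got_total, oracle_total)
  # every reported interval is fully covered in all sets
  if (nrow(sh3))
    for (i in seq_len(nrow(sh3)))
      expect_true(all(all_cov[sh3$start_bp[i]:sh3$end_bp[i]]))
})
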