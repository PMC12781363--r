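# Independent brute-force oracles used across the test suite.  These are
# deliberately written as plain loops, separate from the package's
# vectorized implementations.

# exact HWE p-value by direct enumeration with the recurrence
# P(k+2)/P(k) = ... (normalised at the end); independent of the
# log-factorial route used by the package.
oracle_hwe <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  n_a <- 2 * n_aa + n_ab
  n_b <- 2 * n_bb + n_ab
  if (n_a == 0 || n_b == 0) return(1)
  ks <- seq(n_a %% 2, min(n_a, n_b), by = 2)
  probs <- numeric(length(ks))
  probs[1] <- 1
  if (length(ks) > 1) {
    for (i in seq_len(length(ks) - 1)) {
      k <- ks[i]
      # ratio P(k+2)/P(k) from the conditional distribution
      probs[i + 1] <- probs[i] * 4 * ((n_a - k) / 2) * ((n_b - k) / 2) /
        ((k + 2) * (k + 1))
    }
  }
  probs <- probs / sum(probs)
  obs <- probs[which(ks == n_ab)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# per-SNP counted-allele frequency by explicit loops
oracle_allele_freq <- function(dosage) {
  m <- ncol(dosage)
  out <- numeric(m)
  for (j in seq_len(m)) {
    tot <- 0; cnt <- 0
    for (i in seq_len(nrow(dosage))) {
      if (!is.na(dosage[i, j])) {
        tot <- tot + dosage[i, j]
        cnt <- cnt + 1
      }
    }
    out[j] <- if (cnt == 0) NaN else tot / (2 * cnt)
  }
  out
}

# VanRaden / variance-standardized GRM by double loop
oracle_grm <- function(dosage, method) {
  p <- oracle_allele_freq(dosage)
  use <- which(!is.na(p) & p > 0 & p < 1)
  n <- nrow(dosage)
  g <- matrix(0, n, n)
  denom <- 2 * sum(p[use] * (1 - p[use]))
  for (i in seq_len(n)) for (k in seq_len(n)) {
    acc <- 0
    for (j in use) {
      zi <- if (is.na(dosage[i, j])) 0 else dosage[i, j] - 2 * p[j]
      zk <- if (is.na(dosage[k, j])) 0 else dosage[k, j] - 2 * p[j]
      if (method == "vanraden") {
        acc <- acc + zi * zk
      } else {
        acc <- acc + zi * zk / (2 * p[j] * (1 - p[j]))
      }
    }
    g[i, k] <- if (method == "vanraden") acc / denom else acc / length(use)
  }
  g
}

# IBS distance by per-pair loop
oracle_ibs_distance <- function(dosage) {
  n <- nrow(dosage)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (k in seq_len(n)) {
    if (i == k) next
    s <- 0; m <- 0
    for (j in seq_len(ncol(dosage))) {
      a <- dosage[i, j]; b <- dosage[k, j]
      if (!is.na(a) && !is.na(b)) {
        s <- s + (2 - abs(a - b))
        m <- m + 1
      }
    }
    d[i, k] <- 1 - s / (2 * m)
  }
  d
}

# brute-force ROH scanner: explicit loops over windows, SNPs and
# stretches, following the published criteria
oracle_roh_scan <- function(g, pos, params) {
  m <- length(g)
  segs <- list()
  if (m >= params$min_snps) {
    w <- min(params$window_snps, m)
    nw <- m - w + 1
    hom_win <- logical(nw)
    for (s in seq_len(nw)) {
      win <- g[s:(s + w - 1)]
      hom_win[s] <- sum(win == 1, na.rm = TRUE) <= params$window_max_het &&
        sum(is.na(win)) <= params$window_max_missing
    }
    in_run <- logical(m)
    for (j in seq_len(m)) {
      hits <- 0; tot <- 0
      for (s in seq_len(nw)) {
        if (s <= j && j <= s + w - 1) {
          tot <- tot + 1
          if (hom_win[s]) hits <- hits + 1
        }
      }
      in_run[j] <- hits / tot >= params$window_hit_threshold
    }
    # maximal consecutive stretches
    j <- 1
    while (j <= m) {
      if (!in_run[j]) { j <- j + 1; next }
      k <- j
      while (k < m && in_run[k + 1]) k <- k + 1
      # split at gaps
      pieces <- list(); a <- j
      for (q in j:k) {
        if (q < k && pos[q + 1] - pos[q] > params$max_gap_kb * 1000) {
          pieces[[length(pieces) + 1]] <- c(a, q)
          a <- q + 1
        }
      }
      pieces[[length(pieces) + 1]] <- c(a, k)
      for (pc in pieces) {
        a2 <- pc[1]; b2 <- pc[2]
        while (a2 <= b2 && (is.na(g[a2]) || g[a2] == 1)) a2 <- a2 + 1
        while (b2 >= a2 && (is.na(g[b2]) || g[b2] == 1)) b2 <- b2 - 1
        if (b2 < a2) next
        nn <- b2 - a2 + 1
        len <- pos[b2] - pos[a2] + 1
        if (nn >= params$min_snps && len >= params$min_length_kb * 1000 &&
            len / nn <= params$max_kb_per_snp * 1000) {
          segs[[length(segs) + 1]] <- c(pos[a2], pos[b2], nn)
        }
      }
      j <- k + 1
    }
  }
  if (!length(segs))
    return(data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      n_snps = numeric(0)))
  out <- as.data.frame(do.call(rbind, segs))
  names(out) <- c("start_bp", "end_bp", "n_snps")
  out
}

# Weir & Cockerham (1984) two-population single-locus estimator, written
# from the published equations with explicit intermediates
oracle_wc_theta <- function(counts1, counts2) {
  r <- 2
  ni <- c(sum(counts1), sum(counts2))
  pi <- c((2 * counts1[1] + counts1[2]) / (2 * ni[1]),
          (2 * counts2[1] + counts2[2]) / (2 * ni[2]))
  hi <- c(counts1[2] / ni[1], counts2[2] / ni[2])
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  a <- nbar / nc * (s2 - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# r^2 of two phased binary haplotype vectors: squared Pearson correlation,
# an algebraically independent route to the haplotype-frequency formula
oracle_hap_r2 <- function(h1, h2) cor(h1, h2)^2

# combine two sim populations into one genotype matrix
combine_populations <- function(gm1, gm2) {
  genotype_matrix(rbind(gm1$dosage, gm2$dosage),
                  rbind(gm1$samples, gm2$samples),
                  gm1$variants)
}
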