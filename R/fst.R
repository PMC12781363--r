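#' Weir-Cockerham F_ST variance components for one SNP
#'
#' Two-population Weir & Cockerham (1984) estimator from genotype counts:
#' returns the among-population (`a`), among-individual-within-population
#' (`b`) and within-individual (`c`) variance components and the per-SNP
#' ratio `theta = a / (a + b + c)`.  Negative theta is legitimate
#' finite-sample behaviour and is not clamped; a locus monomorphic across
#' both populations yields all-zero components and `NA` theta.
#'
#' @param counts1,counts2 length-3 integer vectors
#'   `(n_AA, n_Aa, n_aa)` of genotype counts in each population, where
#'   `A` is the counted allele.
#' @return list with `a`, `b`, `c`, `theta`.
#' @export
wc_fst_snp <- function(counts1, counts2) {
  stopifnot(length(counts1) == 3L, length(counts2) == 3L)
  comp <- wc_components(matrix(counts1, nrow = 1),
                        matrix(counts2, nrow = 1))
  list(a = comp$a[1L], b = comp$b[1L], c = comp$c[1L],
       theta = comp$theta[1L])
}

# vectorized W&C components over SNPs.
# cnt1, cnt2: m x 3 matrices of genotype counts (AA, Aa, aa).
wc_components <- function(cnt1, cnt2) {
  n1 <- rowSums(cnt1); n2 <- rowSums(cnt2)
  r <- 2
  p1 <- (2 * cnt1[, 1L] + cnt1[, 2L]) / (2 * n1)
  p2 <- (2 * cnt2[, 1L] + cnt2[, 2L]) / (2 * n2)
  h1 <- cnt1[, 2L] / n1
  h2 <- cnt2[, 2L] / n2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  mono <- pbar <= 0 | pbar >= 1
  a[mono] <- 0; b[mono] <- 0; cc[mono] <- 0
  tot <- a + b + cc
  theta <- ifelse(tot != 0, a / tot, NA_real_)
  theta[mono] <- NA_real_
  list(a = a, b = b, c = cc, theta = theta)
}

genotype_count_matrix <- function(gm) {
  d <- gm$dosage
  cbind(AA = colSums(d == 2L, na.rm = TRUE),
        Aa = colSums(d == 1L, na.rm = TRUE),
        aa = colSums(d == 0L, na.rm = TRUE))
}

#' Sliding-window Weir-Cockerham F_ST between two populations
#'
#' Windows of `window_kb` anchored at positions 1, 1 + step, ... tile each
#' chromosome in `step_kb` steps; a SNP belongs to every window whose
#' closed interval contains its position.  The window statistic is the
#' ratio-of-sums ("weighted") estimator `sum(a) / sum(a + b + c)` over the
#' usable (overall-polymorphic, both populations genotyped) SNPs in the
#' window; windows with no usable SNP are omitted.
#'
#' @param gm1,gm2 [genotype_matrix()] objects for the two populations,
#'   sharing the same variant list.
#' @param window_kb window width (default 100 kb).
#' @param step_kb step size (default 10 kb).
#' @return data.frame of windows: chromosome, start_bp, end_bp, n_snps,
#'   fst_weighted, is_outlier (initialised `FALSE`; see
#'   [outlier_windows()]).
#' @export
windowed_fst <- function(gm1, gm2, window_kb = 100, step_kb = 10) {
  v1 <- gm1$variants; v2 <- gm2$variants
  if (nrow(v1) == 0L) stop("no variants")
  if (!identical(v1$snp_id, v2$snp_id) ||
      !identical(v1$position_bp, v2$position_bp))
    stop("the two populations must share the same variant list")
  comp <- wc_components(genotype_count_matrix(gm1),
                        genotype_count_matrix(gm2))
  usable <- !is.na(comp$theta) &
    rowSums(genotype_count_matrix(gm1)) > 0 &
    rowSums(genotype_count_matrix(gm2)) > 0
  if (!any(usable)) stop("no usable polymorphic SNPs shared by the scan")
  win_bp <- window_kb * 1000
  step_bp <- step_kb * 1000
  rows <- list()
  for (ch in unique(v1$chromosome)) {
    idx <- which(v1$chromosome == ch & usable)
    if (!length(idx)) next
    pos <- v1$position_bp[idx]
    # window k has start 1 + k*step; SNP at p lies in windows with
    # start in [p - win + 1, p]
    k_lo <- ceiling((pos - win_bp + 1 - 1) / step_bp)
    k_lo <- pmax(k_lo, 0L)
    k_hi <- floor((pos - 1) / step_bp)
    reps <- k_hi - k_lo + 1L
    ks <- unlist(lapply(seq_along(idx), function(q) seq(k_lo[q], k_hi[q])))
    snp <- rep(idx, reps)
    agg_a <- tapply(comp$a[snp], ks, sum)
    agg_t <- tapply(comp$a[snp] + comp$b[snp] + comp$c[snp], ks, sum)
    agg_n <- tapply(snp, ks, length)
    k <- as.integer(names(agg_a))
    rows[[ch]] <- data.frame(
      chromosome = ch, start_bp = 1L + k * step_bp,
      end_bp = k * step_bp + win_bp, n_snps = as.integer(agg_n),
      fst_weighted = as.numeric(agg_a) / as.numeric(agg_t),
      is_outlier = FALSE, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$chromosome, out$start_bp), , drop = FALSE]
}

#' Flag top-fraction F_ST outlier windows
#'
#' Windows whose weighted F_ST reaches the k-th largest value, where
#' `k = max(1, floor(top_fraction * n_windows))`, are flagged as putative
#' selection sweeps; ties at the cutoff are kept.
#'
#' @param windows output of [windowed_fst()].
#' @param top_fraction outlier fraction (default 0.01, the top 1%).
#' @return `windows` with `is_outlier` updated.
#' @export
outlier_windows <- function(windows, top_fraction = 0.01) {
  stopifnot(nrow(windows) >= 1L)
  vals <- windows$fst_weighted
  k <- max(1L, floor(top_fraction * sum(!is.na(vals))))
  cutoff <- sort(vals, decreasing = TRUE)[k]
  windows$is_outlier <- !is.na(vals) & vals >= cutoff
  windows
}

#' Genomic regions outlying in two F_ST scans
#'
#' Merges each scan's outlier windows into maximal intervals and returns
#' their genomic intersection — regions flagged as candidate sweeps in
#' both comparisons.
#'
#' @param scan1,scan2 [outlier_windows()] outputs on the same coordinate
#'   system.
#' @return data.frame with chromosome, start_bp, end_bp (possibly empty).
#' @export
shared_outliers <- function(scan1, scan2) {
  o1 <- scan1[scan1$is_outlier, c("chromosome", "start_bp", "end_bp")]
  o2 <- scan2[scan2$is_outlier, c("chromosome", "start_bp", "end_bp")]
  intersect_intervals(o1, o2)
}
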