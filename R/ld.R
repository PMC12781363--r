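#' Pairwise linkage disequilibrium r-squared
#'
#' Two estimators on unphased dosage vectors:
#' \describe{
#'   \item{`em`}{maximum-likelihood haplotype frequencies from the
#'     two-locus genotype table via expectation-maximization (the only
#'     ambiguous configuration is the double heterozygote), then
#'     `r^2 = (p_ab - p_a p_b)^2 / (p_a (1 - p_a) p_b (1 - p_b))`.}
#'   \item{`genotype_corr`}{squared Pearson correlation of the dosage
#'     vectors (the fast composite-LD approximation).}
#' }
#'
#' @param g1,g2 dosage vectors (0/1/2/NA) over the same samples.
#' @param method `"em"` (default) or `"genotype_corr"`.
#' @param max_iter,tol EM iteration cap and convergence tolerance on the
#'   haplotype frequency.  Non-convergence falls back to
#'   `genotype_corr` with a warning.
#' @return r-squared in `[0, 1]`.
#' @export
r2_pair <- function(g1, g2, method = c("em", "genotype_corr"),
                    max_iter = 1000L, tol = 1e-10) {
  method <- match.arg(method)
  keep <- !is.na(g1) & !is.na(g2)
  if (sum(keep) < 2L) stop("fewer than two jointly non-missing samples")
  g1 <- g1[keep]; g2 <- g2[keep]
  if (length(unique(g1)) == 1L || length(unique(g2)) == 1L)
    stop("monomorphic locus in the jointly typed set: r^2 undefined")
  if (method == "genotype_corr") return(cor(g1, g2)^2)
  cnt <- pair_category_counts(matrix(g1, ncol = 1), matrix(g2, ncol = 1))
  res <- em_r2_batch(cnt, max_iter = max_iter, tol = tol)
  if (!res$converged[1L]) {
    warning("EM did not converge; falling back to genotype correlation")
    return(cor(g1, g2)^2)
  }
  res$r2[1L]
}

#' r-squared from phased haplotype frequencies
#'
#' The two-locus LD statistic evaluated directly on haplotype
#' frequencies: `r^2 = (p_ab - p_a p_b)^2 / (p_a (1-p_a) p_b (1-p_b))`.
#' This is the quantity the EM estimator of [r2_pair()] targets; it is
#' exposed separately so phase-known data (e.g. simulated haplotypes) can
#' bypass phasing.
#'
#' @param p_a,p_b allele frequencies at the two loci (in (0,1)).
#' @param p_ab frequency of the haplotype carrying both alleles.
#' @return r-squared.
#' @export
r2_from_hap_freqs <- function(p_a, p_b, p_ab) {
  if (any(p_a <= 0 | p_a >= 1 | p_b <= 0 | p_b >= 1))
    stop("allele frequencies must lie strictly between 0 and 1")
  (p_ab - p_a * p_b)^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

# 9-category genotype-pair counts for P pairs.
# G1, G2: n x P dosage matrices (columns are pairs), NAs allowed.
# Returns a list of vectors n00, n01, ..., n22 (first index = locus 1).
pair_category_counts <- function(G1, G2) {
  ok <- !is.na(G1) & !is.na(G2)
  cnt <- list()
  for (i in 0:2) for (j in 0:2) {
    cnt[[paste0("n", i, j)]] <-
      colSums(ok & !is.na(G1) & G1 == i & !is.na(G2) & G2 == j, na.rm = TRUE)
  }
  cnt$n_joint <- colSums(ok)
  cnt
}

# vectorized EM over P pairs given 9-category counts.
# Returns list(r2, d, p_a, p_b, p_ab, converged).
em_r2_batch <- function(cnt, max_iter = 1000L, tol = 1e-10) {
  n <- cnt$n_joint
  # fixed (phase-known) haplotype contributions
  base_ab <- 2 * cnt$n22 + cnt$n21 + cnt$n12    # A-B
  base_aB <- 2 * cnt$n20 + cnt$n21 + cnt$n10    # A-b
  base_Ab <- 2 * cnt$n02 + cnt$n01 + cnt$n12    # a-B
  base_AB <- 2 * cnt$n00 + cnt$n01 + cnt$n10    # a-b
  dh <- cnt$n11                                  # double heterozygotes
  tot <- 2 * n
  pc <- rep(0.5, length(n))                      # P(coupling | double het)
  converged <- dh == 0
  act <- which(!converged)                       # active (unconverged) pairs
  for (it in seq_len(max_iter)) {
    if (!length(act)) break
    f1 <- (base_ab[act] + dh[act] * pc[act]) / tot[act]
    f2 <- (base_aB[act] + dh[act] * (1 - pc[act])) / tot[act]
    f3 <- (base_Ab[act] + dh[act] * (1 - pc[act])) / tot[act]
    f4 <- (base_AB[act] + dh[act] * pc[act]) / tot[act]
    num <- f1 * f4
    den <- num + f2 * f3
    pc_new <- ifelse(den > 0, num / den, 0.5)
    done <- abs(pc_new - pc[act]) < tol
    pc[act] <- pc_new
    converged[act[done]] <- TRUE
    act <- act[!done]
  }
  # final frequencies from the last responsibilities
  f_ab <- (base_ab + dh * pc) / tot
  f_aB <- (base_aB + dh * (1 - pc)) / tot
  f_Ab <- (base_Ab + dh * (1 - pc)) / tot
  f_AB <- (base_AB + dh * pc) / tot
  p_a <- f_ab + f_aB
  p_b <- f_ab + f_Ab
  d <- f_ab - p_a * p_b
  denom <- p_a * (1 - p_a) * p_b * (1 - p_b)
  r2 <- ifelse(denom > 0, d * d / denom, NA_real_)
  list(r2 = r2, d = d, p_a = p_a, p_b = p_b, p_ab = f_ab,
       converged = converged)
}

# all intra-chromosome SNP pairs with bp distance in (min_bp, max_bp];
# returns data.frame(i, j, dist_bp, r2) using global variant indices.
ld_pairs <- function(gm, min_bp = 0, max_bp, method = "em") {
  v <- gm$variants
  d <- gm$dosage
  p <- allele_frequencies(gm)
  poly <- !is.na(p) & p > 0 & p < 1
  out <- list()
  for (ch in unique(v$chromosome)) {
    idx <- which(v$chromosome == ch & poly)
    if (length(idx) < 2L) next
    pos <- v$position_bp[idx]
    hi <- findInterval(pos + max_bp, pos)
    lo <- pmax(findInterval(pos + min_bp, pos) + 1L,
               seq_along(idx) + 1L)
    cnt_a <- pmax(hi - lo + 1L, 0L)
    ii <- rep.int(seq_along(idx), cnt_a)
    jj <- sequence(cnt_a, from = lo)
    if (!length(ii)) next
    G1 <- d[, idx[ii], drop = FALSE]
    G2 <- d[, idx[jj], drop = FALSE]
    if (method == "em") {
      cnt <- pair_category_counts(G1, G2)
      r2 <- em_r2_batch(cnt)$r2
    } else {
      r2 <- numeric(length(ii))
      for (k in seq_along(ii)) {
        ok <- !is.na(G1[, k]) & !is.na(G2[, k])
        r2[k] <- suppressWarnings(cor(G1[ok, k], G2[ok, k])^2)
      }
    }
    out[[ch]] <- data.frame(i = idx[ii], j = idx[jj],
                            dist_bp = v$position_bp[idx[jj]] -
                              v$position_bp[idx[ii]],
                            r2 = r2)
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), dist_bp = numeric(),
                      r2 = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[!is.na(res$r2), , drop = FALSE]
}

#' Linkage disequilibrium decay by physical distance
#'
#' Mean r-squared of all intra-chromosome SNP pairs, binned by physical
#' distance in contiguous lower-inclusive bins of `bin_kb` up to
#' `max_dist_kb`.
#'
#' @param gm a [genotype_matrix()] (one population, sorted positions).
#' @param max_dist_kb maximum pair distance (default 2000 kb).
#' @param bin_kb bin width (default 100 kb).
#' @param method LD estimator, `"em"` or `"genotype_corr"`.
#' @return data.frame of bins: distance_lo_kb, distance_hi_kb, mean_r2,
#'   n_pairs.  Bins without pairs are retained with `n_pairs = 0` and
#'   `NA` mean; an entirely empty result triggers a warning.
#' @export
ld_decay <- function(gm, max_dist_kb = 2000, bin_kb = 100,
                     method = c("em", "genotype_corr")) {
  method <- match.arg(method)
  pairs <- ld_pairs(gm, min_bp = 0, max_bp = max_dist_kb * 1000,
                    method = method)
  lo <- seq(0, max_dist_kb - bin_kb, by = bin_kb)
  out <- data.frame(distance_lo_kb = lo, distance_hi_kb = lo + bin_kb,
                    mean_r2 = NA_real_, n_pairs = 0L)
  if (!nrow(pairs)) {
    warning("no SNP pairs within ", max_dist_kb, " kb")
    return(out)
  }
  bin <- findInterval(pairs$dist_bp / 1000, c(lo, max_dist_kb),
                      left.open = FALSE, rightmost.closed = TRUE)
  means <- tapply(pairs$r2, bin, mean)
  counts <- tapply(pairs$r2, bin, length)
  k <- as.integer(names(means))
  out$mean_r2[k] <- as.numeric(means)
  out$n_pairs[k] <- as.integer(counts)
  out
}

#' Effective population size from LD decay (Sved equation)
#'
#' For each number of generations `t` in `t_range`, pairs whose genetic
#' map distance `c` (from physical distance via a linear `cm_per_mb` map)
#' lies in `(1/(2(t+0.5)), 1/(2(t-0.5))]` Morgans estimate the LD a
#' population of size `Ne(t)` generated `t = 1/(2c)` generations ago:
#' `Ne(t) = (1 / (4 c_t)) * (1 / mean(r2_adj) - alpha)` with
#' `c_t = 1/(2t)`.  With `sample_size_correction = "one_over_n"` (the
#' default) `r2_adj = r2 - 1/n` removes the finite-sample inflation of
#' r-squared.
#'
#' @param gm a [genotype_matrix()] (one population; a warning is issued
#'   below 10 samples).
#' @param t_range integer generations ago (default `25:100`).
#' @param alpha mutation-adjustment constant of the Sved equation
#'   (1 = drift only; 2.2 is the common mutation-adjusted variant).
#' @param cm_per_mb linear map rate converting bp to Morgans (default 1).
#' @param sample_size_correction `"one_over_n"` or `"none"`.
#' @param method LD estimator (see [r2_pair()]).
#' @return data.frame: t, c_t (Morgans), mean_r2_adj, n_pairs, ne.  Rows
#'   whose distance bin is empty or whose adjusted LD gives a non-positive
#'   Ne carry `NA` in `ne` and are flagged in `valid`.
#' @export
estimate_ne <- function(gm, t_range = 25:100, alpha = 1, cm_per_mb = 1,
                        sample_size_correction = c("one_over_n", "none"),
                        method = c("em", "genotype_corr")) {
  sample_size_correction <- match.arg(sample_size_correction)
  method <- match.arg(method)
  n <- nrow(gm$dosage)
  if (n < 10L) warning("fewer than 10 samples: Ne estimates are unstable")
  t_range <- sort(unique(as.integer(t_range)))
  # Morgans -> bp under the linear map
  bp_per_morgan <- 1e6 * 100 / cm_per_mb
  c_lo_all <- 1 / (2 * (max(t_range) + 0.5))
  c_hi_all <- 1 / (2 * (min(t_range) - 0.5))
  pairs <- ld_pairs(gm, min_bp = c_lo_all * bp_per_morgan,
                    max_bp = c_hi_all * bp_per_morgan, method = method)
  adj <- if (sample_size_correction == "one_over_n") 1 / n else 0
  rows <- lapply(t_range, function(t) {
    c_t <- 1 / (2 * t)
    lo <- 1 / (2 * (t + 0.5)) * bp_per_morgan
    hi <- 1 / (2 * (t - 0.5)) * bp_per_morgan
    sel <- pairs$dist_bp > lo & pairs$dist_bp <= hi
    if (!any(sel))
      return(data.frame(t = t, c_t = c_t, mean_r2_adj = NA_real_,
                        n_pairs = 0L, ne = NA_real_, valid = FALSE))
    r2a <- mean(pairs$r2[sel]) - adj
    ne <- if (r2a > 0) (1 / (4 * c_t)) * (1 / r2a - alpha) else NA_real_
    data.frame(t = t, c_t = c_t, mean_r2_adj = r2a, n_pairs = sum(sel),
               ne = if (!is.na(ne) && ne > 0) ne else NA_real_,
               valid = !is.na(ne) && ne > 0)
  })
  do.call(rbind, rows)
}
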