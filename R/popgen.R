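#' Counted-allele frequencies
#'
#' Per-SNP frequency of the counted allele over non-missing genotypes.
#' SNPs with no non-missing calls get `NaN` and must be excluded
#' downstream.
#'
#' @param gm a [genotype_matrix()].
#' @return Numeric vector of length `n_snps`, named by `snp_id`.
#' @export
allele_frequencies <- function(gm) {
  d <- gm$dosage
  n_called <- colSums(!is.na(d))
  f <- colSums(d, na.rm = TRUE) / (2 * n_called)
  f[n_called == 0L] <- NaN
  setNames(f, gm$variants$snp_id)
}

#' Per-population diversity summary
#'
#' Per SNP, observed heterozygosity is the fraction of non-missing
#' genotypes that are heterozygous and expected heterozygosity is
#' `2 p (1 - p)`; population values are unweighted means over SNPs.
#' Summary tables in the livestock literature sometimes report these on
#' the homozygosity scale (`1 - Ho`, `1 - He`); `mode = "homozygosity"`
#' produces that complement, with the mode recorded in the output.
#'
#' @param gm a [genotype_matrix()] (one population, post QC).
#' @param mode `"heterozygosity"` (default) or `"homozygosity"`.
#' @return One-row data.frame: population, n_samples, n_snps, mean_maf,
#'   mean_ho, mean_he, mode.
#' @export
diversity_summary <- function(gm, mode = c("heterozygosity", "homozygosity")) {
  mode <- match.arg(mode)
  d <- gm$dosage
  if (ncol(d) == 0L || nrow(d) == 0L) stop("empty genotype matrix")
  p <- allele_frequencies(gm)
  usable <- !is.na(p)
  ho <- colMeans(d == 1L, na.rm = TRUE)[usable]
  he <- (2 * p * (1 - p))[usable]
  maf <- pmin(p, 1 - p)[usable]
  if (mode == "homozygosity") {
    ho <- 1 - ho
    he <- 1 - he
  }
  data.frame(population = gm$samples$population[1L],
             n_samples = nrow(d), n_snps = sum(usable),
             mean_maf = mean(maf), mean_ho = mean(ho), mean_he = mean(he),
             mode = mode, stringsAsFactors = FALSE)
}

#' Genomic relationship matrix
#'
#' Two standard constructions from centred dosages `Z = X - 2p`:
#' \describe{
#'   \item{`vanraden`}{`G = Z Z' / (2 sum_j p_j (1 - p_j))` — the classic
#'     ratio form whose diagonal feeds the F_GRM inbreeding coefficient.}
#'   \item{`variance_standardized`}{`G = W W' / m` with
#'     `W_ij = Z_ij / sqrt(2 p_j (1 - p_j))` — the matrix conventionally
#'     used for PCA of population structure.}
#' }
#' Missing dosages are mean-imputed to `2p_j`; monomorphic SNPs are
#' excluded with a warning.
#'
#' @param gm a [genotype_matrix()].
#' @param method `"vanraden"` or `"variance_standardized"`.
#' @return A `relationship_matrix`: list with `values` (n x n symmetric),
#'   `sample_ids`, `method`, `n_snps_used`.
#' @export
compute_grm <- function(gm, method = c("vanraden", "variance_standardized")) {
  method <- match.arg(method)
  p <- allele_frequencies(gm)
  usable <- !is.na(p) & p > 0 & p < 1
  if (!any(usable)) stop("no polymorphic SNPs available for the GRM")
  if (any(!usable))
    warning(sum(!usable), " monomorphic or all-missing SNPs excluded from GRM")
  d <- gm$dosage[, usable, drop = FALSE]
  p <- p[usable]
  z <- sweep(d, 2L, 2 * p)
  z[is.na(z)] <- 0              # mean imputation: dosage 2p => z = 0
  if (method == "vanraden") {
    g <- tcrossprod(z) / (2 * sum(p * (1 - p)))
  } else {
    w <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
    g <- tcrossprod(w) / ncol(w)
  }
  structure(list(values = g, sample_ids = gm$samples$sample_id,
                 method = method, n_snps_used = ncol(d)),
            class = "relationship_matrix")
}

#' Principal component analysis of a relationship matrix
#'
#' Eigendecomposition of the (variance-standardized) genomic relationship
#' matrix.  Components are ordered by decreasing eigenvalue; the fraction
#' of variance explained is each eigenvalue over the sum of positive
#' eigenvalues; scores are `U sqrt(lambda)`.  The sign of each component
#' is fixed so that its largest-magnitude loading is positive.
#'
#' @param grm a `relationship_matrix`, typically
#'   `compute_grm(gm, "variance_standardized")`.
#' @param k number of components, `k <= n - 1`.
#' @return list with `scores` (n x k), `varexp` (length k) and
#'   `eigenvalues` (all n).
#' @export
grm_pca <- function(grm, k = 10L) {
  stopifnot(inherits(grm, "relationship_matrix"))
  n <- length(grm$sample_ids)
  if (k >= n) stop("k must be smaller than the number of samples")
  e <- eigen(grm$values, symmetric = TRUE)
  pos <- sum(pmax(e$values, 0))
  vecs <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- sweep(vecs, 2L, sqrt(pmax(e$values[seq_len(k)], 0)), "*")
  rownames(scores) <- grm$sample_ids
  colnames(scores) <- paste0("PC", seq_len(k))
  list(scores = scores, varexp = pmax(e$values[seq_len(k)], 0) / pos,
       eigenvalues = e$values)
}

#' Identity-by-state genetic distance matrix
#'
#' `D_kl = 1 - IBS_kl` with the allele-sharing score
#' `IBS_kl = sum_j (2 - |x_kj - x_lj|) / (2 m_kl)` over SNPs non-missing
#' in both samples.
#'
#' @param gm a [genotype_matrix()] with at least two samples.
#' @return Symmetric n x n matrix of distances in `[0, 1]`, with sample IDs
#'   as dimnames.  A pair with no jointly typed SNPs is an error.
#' @export
ibs_distance <- function(gm) {
  d <- gm$dosage
  n <- nrow(d)
  if (n < 2L) stop("need at least two samples")
  ok <- !is.na(d)
  x <- d; x[!ok] <- 0L
  x <- matrix(as.numeric(x), nrow = n)
  okn <- matrix(as.numeric(ok), nrow = n)
  # |x_k - x_l| over joint-called SNPs, decomposed by genotype value:
  # sum |a-b| = sum over pairs of products of genotype-class indicators
  i0 <- okn * (x == 0); i1 <- okn * (x == 1); i2 <- okn * (x == 2)
  m_joint <- tcrossprod(okn)
  if (any(m_joint[upper.tri(m_joint)] == 0))
    stop("sample pair(s) with zero jointly typed SNPs")
  absdiff <- tcrossprod(i0, i1) + tcrossprod(i1, i0) +
    tcrossprod(i1, i2) + tcrossprod(i2, i1) +
    2 * (tcrossprod(i0, i2) + tcrossprod(i2, i0))
  dist <- absdiff / (2 * m_joint)
  dimnames(dist) <- list(gm$samples$sample_id, gm$samples$sample_id)
  diag(dist) <- 0
  dist
}
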