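#' F_GRM: inbreeding from the genomic relationship matrix diagonal
#'
#' `F_GRM_i = G_ii - 1` on the classic (VanRaden) relationship matrix.
#'
#' @param grm a `relationship_matrix` with `method = "vanraden"`.
#' @return Named numeric vector, one value per sample.
#' @export
f_grm <- function(grm) {
  stopifnot(inherits(grm, "relationship_matrix"))
  if (grm$method != "vanraden")
    stop("f_grm expects a vanraden relationship matrix")
  setNames(diag(grm$values) - 1, grm$sample_ids)
}

#' F_HOM1: inbreeding from the heterozygote deficit (ratio of sums)
#'
#' Per sample, over its non-missing SNPs:
#' `F_HOM1 = (E_het - O_het) / E_het` with `E_het = sum_j 2 p_j (1 - p_j)`
#' and `O_het` the observed heterozygote count.  Algebraically identical
#' to the excess-homozygosity form `(O_hom - E_hom) / (N - E_hom)` used by
#' standard GWAS tooling, and positive for inbred individuals.  Allele
#' frequencies are computed within the population being analysed.
#'
#' @param gm a [genotype_matrix()] (one population).
#' @param freqs optional precomputed [allele_frequencies()].
#' @return Named numeric vector, one value per sample.
#' @export
f_hom1 <- function(gm, freqs = NULL) {
  d <- gm$dosage
  p <- freqs %||% allele_frequencies(gm)
  twopq <- 2 * p * (1 - p)
  called <- !is.na(d)
  e_het <- called %*% ifelse(is.na(twopq), 0, twopq)
  o_het <- rowSums(d == 1L, na.rm = TRUE)
  if (any(e_het == 0))
    stop("sample(s) with zero expected heterozygosity (no polymorphic SNPs)")
  setNames(as.numeric((e_het - o_het) / e_het), gm$samples$sample_id)
}

#' F_HOM2: per-SNP homozygosity-based inbreeding (mean of ratios)
#'
#' Per sample, the mean over its non-missing SNPs (polymorphic in the
#' population) of `1 - x (2 - x) / (2 p (1 - p))`, where `x` is the
#' counted-allele dosage and `p` the within-population counted-allele
#' frequency.
#'
#' @inheritParams f_hom1
#' @return Named numeric vector, one value per sample.
#' @export
f_hom2 <- function(gm, freqs = NULL) {
  d <- gm$dosage
  p <- freqs %||% allele_frequencies(gm)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs usable for f_hom2")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  ratio <- sweep(d * (2 - d), 2L, 2 * p * (1 - p), "/")
  val <- 1 - ratio                     # NA propagates through missing dosage
  setNames(rowMeans(val, na.rm = TRUE), gm$samples$sample_id)
}

#' F_UNI: inbreeding from the correlation of uniting gametes
#'
#' Ratio-of-sums aggregation of the per-SNP uniting-gametes statistic:
#' `F_UNI = sum_j [x_j^2 - (1 + 2 p_j) x_j + 2 p_j^2] / sum_j 2 p_j (1 - p_j)`
#' over the sample's non-missing SNPs polymorphic in the population.
#'
#' @inheritParams f_hom1
#' @return Named numeric vector, one value per sample.
#' @export
f_uni <- function(gm, freqs = NULL) {
  d <- gm$dosage
  p <- freqs %||% allele_frequencies(gm)
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs usable for f_uni")
  d <- d[, poly, drop = FALSE]
  p <- p[poly]
  num <- d * d - sweep(d, 2L, 1 + 2 * p, "*") +
    matrix(2 * p * p, nrow(d), ncol(d), byrow = TRUE)
  num[is.na(d)] <- NA
  den <- (!is.na(d)) %*% (2 * p * (1 - p))
  setNames(as.numeric(rowSums(num, na.rm = TRUE) / den),
           gm$samples$sample_id)
}

#' F_ROH: genomic inbreeding from runs of homozygosity
#'
#' The fraction of the SNP-covered autosomal genome lying inside ROH:
#' `F_ROH = sum_i L_ROH_i / L_auto`, where `L_auto` sums, over the
#' autosomes present in the matrix, the span from the first to the last
#' SNP position.  Length-stratified variants restrict the numerator to
#' segments of one length class; the five class values sum exactly to the
#' total.
#'
#' @param segments [detect_roh()] output for this population.
#' @param gm the matching post-QC [genotype_matrix()].
#' @param autosomes chromosome labels included in `L_auto` (default pig).
#' @return data.frame: sample_id, f_roh and the five class columns.
#' @export
f_roh <- function(segments, gm, autosomes = pig_autosomes()) {
  v <- gm$variants
  chroms <- intersect(unique(v$chromosome), autosomes)
  if (!length(chroms)) chroms <- unique(v$chromosome)
  l_auto <- sum(vapply(chroms, function(ch) {
    p <- v$position_bp[v$chromosome == ch]
    max(p) - min(p) + 1
  }, numeric(1)))
  if (l_auto <= 0) stop("L_auto is zero: no SNP-covered autosome span")
  ids <- gm$samples$sample_id
  out <- data.frame(sample_id = ids, f_roh = 0, f_roh_lt2 = 0,
                    f_roh_2to4 = 0, f_roh_4to8 = 0, f_roh_8to16 = 0,
                    f_roh_gt16 = 0, stringsAsFactors = FALSE)
  if (nrow(segments)) {
    segments <- segments[segments$chromosome %in% chroms, , drop = FALSE]
    tot <- tapply(segments$length_bp, segments$sample_id, sum)
    out$f_roh <- as.numeric(tot[ids]) / l_auto
    cls_cols <- paste0("f_roh_", .roh_class_labels)
    names(cls_cols) <- .roh_class_labels
    for (cl in .roh_class_labels) {
      s <- segments[segments$length_class == cl, ]
      if (nrow(s)) {
        t2 <- tapply(s$length_bp, s$sample_id, sum)
        out[[cls_cols[cl]]] <- as.numeric(t2[ids]) / l_auto
      }
    }
    out[is.na(out)] <- 0
  }
  names(out) <- c("sample_id", "f_roh", "f_roh_lt2", "f_roh_2_4",
                  "f_roh_4_8", "f_roh_8_16", "f_roh_gt16")
  out
}

#' All ten genomic inbreeding coefficients per individual
#'
#' Computes F_HOM1, F_GRM, F_HOM2, F_UNI, F_ROH and the five
#' length-stratified F_ROH variants for one population, using
#' within-population allele frequencies throughout.
#'
#' @param gm post-QC [genotype_matrix()] for the F_GRM/F_HOM/F_UNI track
#'   (MAF-filtered).
#' @param segments ROH segments from [detect_roh()] on the ROH-profile
#'   matrix; pass the matching `roh_gm` when it differs from `gm`.
#' @param roh_gm matrix used for the ROH track (defaults to `gm`).
#' @param autosomes chromosome labels for `L_auto`.
#' @return data.frame with sample_id and the ten coefficients.
#' @export
inbreeding_records <- function(gm, segments, roh_gm = gm,
                               autosomes = pig_autosomes()) {
  p <- allele_frequencies(gm)
  grm <- compute_grm(gm, "vanraden")
  rec <- data.frame(sample_id = gm$samples$sample_id,
                    f_hom1 = as.numeric(f_hom1(gm, p)),
                    f_grm = as.numeric(f_grm(grm)),
                    f_hom2 = as.numeric(f_hom2(gm, p)),
                    f_uni = as.numeric(f_uni(gm, p)),
                    stringsAsFactors = FALSE)
  froh <- f_roh(segments, roh_gm, autosomes)
  merge(rec, froh, by = "sample_id", sort = FALSE)
}

#' Pearson correlations among inbreeding coefficients
#'
#' Pairwise Pearson correlation across individuals for every pair of the
#' ten coefficients.  Zero-variance metrics yield `NA` entries (flagged
#' with a warning) rather than silent zeros.
#'
#' @param records output of [inbreeding_records()] (>= 3 samples).
#' @return 10 x 10 symmetric correlation matrix with unit diagonal.
#' @export
inbreeding_correlations <- function(records) {
  metrics <- setdiff(names(records), "sample_id")
  x <- as.matrix(records[, metrics])
  if (nrow(x) < 3L) stop("need at least three samples for correlations")
  sds <- apply(x, 2L, sd)
  if (any(sds == 0))
    warning("zero-variance metric(s): ",
            paste(metrics[sds == 0], collapse = ", "),
            " - correlations set to NA")
  suppressWarnings(cc <- cor(x))
  diag(cc) <- 1
  cc
}
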