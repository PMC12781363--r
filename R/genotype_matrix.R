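#' Construct a genotype matrix object
#'
#' The central data container of the package: an `n_samples x n_snps`
#' dosage matrix counting copies of the counted allele (`allele_a`) with
#' entries 0, 1, 2 or `NA` (missing), plus per-sample and per-variant
#' metadata.  All coordinates are 1-based physical positions; within each
#' chromosome variants must be sorted by non-decreasing position (strictly
#' increasing once duplicate positions have been removed by QC).
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param samples data.frame with columns `sample_id` (unique), `population`
#'   and optionally `group`.
#' @param variants data.frame with columns `snp_id`, `chromosome` (character
#'   label), `position_bp` (integer >= 0; 0 flags an unknown position),
#'   `allele_a` (counted allele) and `allele_b`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, samples, variants) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  if (is.null(samples$group)) samples$group <- NA_character_
  variants$chromosome <- as.character(variants$chromosome)
  variants$position_bp <- as.integer(variants$position_bp)
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- variants$snp_id
  gm <- structure(list(dosage = dosage, samples = samples,
                       variants = variants),
                  class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

#' Validate a genotype matrix
#'
#' Checks dimensional consistency, legal dosage values, unique sample IDs
#' and per-chromosome position sorting.  Called by all constructors; also
#' usable directly on externally assembled objects.
#'
#' @param gm a [genotype_matrix()].
#' @return `gm`, invisibly; stops on violation.
#' @export
validate_genotype_matrix <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  d <- gm$dosage
  if (nrow(d) != nrow(gm$samples))
    stop("dosage rows (", nrow(d), ") != samples (", nrow(gm$samples), ")")
  if (ncol(d) != nrow(gm$variants))
    stop("dosage columns (", ncol(d), ") != variants (", nrow(gm$variants), ")")
  bad <- d[!is.na(d)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosage entries must be 0, 1, 2 or NA")
  if (anyDuplicated(gm$samples$sample_id))
    stop("duplicate sample_id in sample metadata")
  need_v <- c("snp_id", "chromosome", "position_bp", "allele_a", "allele_b")
  miss <- setdiff(need_v, names(gm$variants))
  if (length(miss)) stop("variants lack column(s): ", paste(miss, collapse = ", "))
  if (any(gm$variants$position_bp < 0L, na.rm = TRUE))
    stop("position_bp must be >= 0")
  for (ch in unique(gm$variants$chromosome)) {
    p <- gm$variants$position_bp[gm$variants$chromosome == ch]
    if (is.unsorted(p, na.rm = TRUE))
      stop("variants on chromosome ", ch, " are not sorted by position")
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "samples x", ncol(x$dosage),
      "SNPs\n")
  pops <- table(x$samples$population)
  cat("populations:", paste(names(pops), pops, sep = "=", collapse = ", "),
      "\n")
  cat("chromosomes:", paste(unique(x$variants$chromosome), collapse = ", "),
      "\n")
  mr <- mean(is.na(x$dosage))
  cat(sprintf("missing rate: %.4f\n", mr))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or variants
#'
#' Each analysis stage operates on one population at a time, so
#' per-population (and per-chromosome) slicing is the basic composition
#' step of the pipeline.  Filters may be given as predicate functions on
#' the metadata data.frames, or as logical/integer index vectors.  Order is
#' preserved and the input is never modified.
#'
#' @param gm a [genotype_matrix()].
#' @param sample_filter `NULL` (keep all), a function mapping the sample
#'   data.frame to a logical vector, or a logical/integer index vector.
#' @param variant_filter same conventions, applied to the variant table.
#' @return A new `genotype_matrix`.  An empty selection is an error.
#' @examples
#' gm <- sim_example_population(n = 6, n_snps = 40, seed = 1)
#' subset_genotypes(gm, variant_filter = function(v) v$chromosome == "1")
#' @export
subset_genotypes <- function(gm, sample_filter = NULL, variant_filter = NULL) {
  validate_genotype_matrix(gm)
  resolve <- function(filter, meta, what) {
    if (is.null(filter)) return(seq_len(nrow(meta)))
    idx <- if (is.function(filter)) which(filter(meta)) else which_idx(filter, nrow(meta))
    if (length(idx) == 0L) stop("empty ", what, " selection")
    idx
  }
  si <- resolve(sample_filter, gm$samples, "sample")
  vi <- resolve(variant_filter, gm$variants, "variant")
  genotype_matrix(gm$dosage[si, vi, drop = FALSE],
                  gm$samples[si, , drop = FALSE],
                  gm$variants[vi, , drop = FALSE])
}

which_idx <- function(filter, n) {
  if (is.logical(filter)) {
    stopifnot(length(filter) == n)
    which(filter)
  } else {
    as.integer(filter)
  }
}

#' Split a genotype matrix by population
#'
#' @param gm a [genotype_matrix()].
#' @return Named list of `genotype_matrix` objects, one per population.
#' @export
split_by_population <- function(gm, populations = NULL) {
  pops <- populations %||% unique(gm$samples$population)
  setNames(lapply(pops, function(p) {
    subset_genotypes(gm, sample_filter = function(s) s$population == p)
  }), pops)
}

#' Default autosome labels
#'
#' The pig (Sscrofa 11.1) karyotype has 18 autosomes; other species are
#' supported by passing a different label set wherever an `autosomes`
#' argument appears.
#'
#' @param n number of autosomes.
#' @return Character vector of chromosome labels `"1" ... "n"`.
#' @export
pig_autosomes <- function(n = 18L) as.character(seq_len(n))
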