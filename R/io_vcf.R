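#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzip-compressed) via
#' \pkg{vcfR} and returns the biallelic SNP records as a
#' [genotype_matrix()].  Dosage counts the ALT allele, i.e.
#' `allele_a = ALT`, `allele_b = REF`.  Missing calls (`./.`) and half
#' calls (e.g. `./1`) become `NA`; phased separators (`|`) are treated as
#' unphased.  Variants are sorted per chromosome by position.
#'
#' Records with more than one ALT allele, symbolic or multi-base alleles,
#' or a missing ALT are dropped.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param population optional single population label, or a data.frame
#'   mapping (columns `sample_id`, `population`, optionally `group`) as
#'   read by [read_sample_map()].
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, population = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- t(fx)     # single-record VCF: bare vector
  fx <- as.data.frame(fx, stringsAsFactors = FALSE)
  if (nrow(fx) == 0L) stop("VCF contains no variant records: ", path)
  ref <- toupper(fx$REF)
  alt <- toupper(ifelse(is.na(fx$ALT), "", fx$ALT))
  keep <- nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  fx <- fx[keep, , drop = FALSE]
  sample_ids <- colnames(gt)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs in VCF header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  # GT string -> ALT-allele count; any missing half-call -> NA
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dos <- matrix(NA_integer_, nrow = length(sample_ids), ncol = nrow(fx))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  flat <- known[t(gt)]   # samples vary fastest after transpose
  dos[] <- flat
  ids <- fx$ID
  ids[is.na(ids) | ids == "."] <-
    paste0(fx$CHROM, "_", fx$POS)[is.na(ids) | ids == "."]
  variants <- data.frame(snp_id = ids, chromosome = as.character(fx$CHROM),
                         position_bp = as.integer(fx$POS),
                         allele_a = alt[keep], allele_b = ref[keep],
                         stringsAsFactors = FALSE)
  ord <- order(variants$chromosome, variants$position_bp)
  variants <- variants[ord, , drop = FALSE]
  dos <- dos[, ord, drop = FALSE]
  samples <- make_sample_table(sample_ids, population)
  genotype_matrix(dos, samples, variants)
}

make_sample_table <- function(sample_ids, population) {
  if (is.data.frame(population)) {
    m <- match(sample_ids, population$sample_id)
    if (anyNA(m))
      stop("samples absent from population map: ",
           paste(sample_ids[is.na(m)], collapse = ", "))
    data.frame(sample_id = sample_ids,
               population = population$population[m],
               group = (population$group %||% rep(NA_character_,
                                                  nrow(population)))[m],
               stringsAsFactors = FALSE)
  } else {
    data.frame(sample_id = sample_ids,
               population = if (is.null(population)) "pop1" else population,
               group = NA_character_, stringsAsFactors = FALSE)
  }
}

#' Write a genotype matrix as VCF
#'
#' Minimal VCF 4.2 output with unphased GT fields; `allele_a` is written as
#' ALT and `allele_b` as REF so that [read_vcf()] round-trips the dosage
#' matrix exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  validate_genotype_matrix(gm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=genodiv",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", gm$samples$sample_id),
                   collapse = "\t"), con)
  gt_code <- c("0/0", "0/1", "1/1")
  d <- gm$dosage
  for (j in seq_len(ncol(d))) {
    g <- d[, j]
    gs <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    v <- gm$variants[j, ]
    writeLines(paste(c(v$chromosome, v$position_bp, v$snp_id, v$allele_b,
                       v$allele_a, ".", "PASS", ".", "GT", gs),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a sample-to-population mapping file
#'
#' Tab-separated text with columns `sample_id`, `population` and optionally
#' `group` (the analysis subgroup a population belongs to).
#'
#' @param path TSV path with a header line.
#' @return data.frame with the three columns (group filled with `NA` when
#'   absent).
#' @export
read_sample_map <- function(path) {
  sm <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sample_id", "population")
  miss <- setdiff(need, names(sm))
  if (length(miss)) stop("sample map lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (is.null(sm$group)) sm$group <- NA_character_
  if (anyDuplicated(sm$sample_id)) stop("duplicate sample_id in sample map")
  sm[, c("sample_id", "population", "group")]
}
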