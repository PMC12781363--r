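#' Read genotypes from PLINK text files (PED/MAP)
#'
#' The counted allele at each SNP is the minor allele as determined from
#' the file itself (lexicographically smaller allele on a frequency tie);
#' `0 0` encodes a missing genotype.  The PED family ID column is ingested
#' as the population label unless an explicit mapping is supplied.
#'
#' @param ped_path path to the `.ped` file (FID, IID, father, mother, sex,
#'   phenotype, then two allele columns per SNP).
#' @param map_path path to the `.map` file (chromosome, snp_id, cM,
#'   position_bp).
#' @param population optional label or sample-map data.frame overriding the
#'   family ID column (see [read_vcf()]).
#' @return A [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path, population = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)
  map <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(map) < 4L) stop("MAP file must have 4 columns: ", map_path)
  m <- nrow(map)
  ped <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                           data.table = FALSE)
  if (ncol(ped) != 6L + 2L * m)
    stop("PED genotype column count (", ncol(ped) - 6L,
         ") does not equal 2 x MAP rows (", 2L * m, ")")
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  ok <- al %in% c("A", "C", "G", "T", "0")
  if (!all(ok))
    stop("non-ACGT0 allele codes in PED: ",
         paste(unique(al[!ok]), collapse = ", "))
  n <- nrow(ped)
  a1 <- al[, seq(1L, 2L * m, by = 2L), drop = FALSE]
  a2 <- al[, seq(2L, 2L * m, by = 2L), drop = FALSE]
  if (any((a1 == "0") != (a2 == "0")))
    stop("half-missing genotypes ('0 X') are not legal PLINK text")
  dos <- matrix(NA_integer_, n, m)
  allele_a <- allele_b <- character(m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    seen <- setdiff(sort(unique(c(x1, x2))), "0")
    if (length(seen) > 2L)
      stop("more than two alleles at MAP row ", j, ": ",
           paste(seen, collapse = ", "))
    if (length(seen) == 0L) {            # all missing
      allele_a[j] <- "0"; allele_b[j] <- "0"
      next
    }
    if (length(seen) == 1L) {            # monomorphic: counted allele unseen
      allele_a[j] <- "0"; allele_b[j] <- seen
      dos[, j] <- ifelse(x1 == "0", NA_integer_, 0L)
      next
    }
    cnt1 <- sum(x1 == seen[1L]) + sum(x2 == seen[1L])
    cnt2 <- sum(x1 == seen[2L]) + sum(x2 == seen[2L])
    # minor allele counted; lexicographic tie-break (seen is sorted)
    minor <- if (cnt1 <= cnt2) seen[1L] else seen[2L]
    major <- setdiff(seen, minor)
    allele_a[j] <- minor; allele_b[j] <- major
    dos[, j] <- ifelse(x1 == "0", NA_integer_,
                       (x1 == minor) + (x2 == minor))
  }
  sample_ids <- make.unique(ped[, 2L])
  samples <- if (is.null(population)) {
    data.frame(sample_id = sample_ids, population = ped[, 1L],
               group = NA_character_, stringsAsFactors = FALSE)
  } else {
    make_sample_table(sample_ids, population)
  }
  variants <- data.frame(snp_id = map[, 2L], chromosome = map[, 1L],
                         position_bp = as.integer(map[, 4L]),
                         allele_a = allele_a, allele_b = allele_b,
                         stringsAsFactors = FALSE)
  ord <- order(variants$chromosome, variants$position_bp)
  genotype_matrix(dos[, ord, drop = FALSE], samples,
                  variants[ord, , drop = FALSE])
}

#' Write a genotype matrix as PLINK text (PED/MAP)
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return The prefix, invisibly.
#' @export
write_plink_text <- function(gm, prefix) {
  validate_genotype_matrix(gm)
  v <- gm$variants
  map <- data.frame(v$chromosome, v$snp_id, 0, v$position_bp)
  utils::write.table(map, paste0(prefix, ".map"), quote = FALSE,
                     sep = "\t", row.names = FALSE, col.names = FALSE)
  d <- gm$dosage
  n <- nrow(d); m <- ncol(d)
  a_cols <- matrix("0", n, 2L * m)
  for (j in seq_len(m)) {
    g <- d[, j]
    aa <- v$allele_a[j]; ab <- v$allele_b[j]
    # dosage -> allele pair; counted allele first where heterozygous
    c1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, aa, ab))
    c2 <- ifelse(is.na(g), "0", ifelse(g == 2L, aa, ab))
    a_cols[, 2L * j - 1L] <- c1
    a_cols[, 2L * j] <- c2
  }
  ped <- cbind(gm$samples$population, gm$samples$sample_id,
               "0", "0", "0", "-9", a_cols)
  data.table::fwrite(as.data.frame(ped), paste0(prefix, ".ped"),
                     quote = FALSE, sep = " ", col.names = FALSE)
  invisible(prefix)
}
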