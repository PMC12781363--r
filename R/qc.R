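#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided exact test on one biallelic SNP: conditional on the observed
#' allele counts, the probability of every heterozygote count with the same
#' parity is evaluated and all configurations no more probable than the
#' observed one are summed.  This is the plain (non mid-p) exact test used
#' by standard GWAS QC tooling; SNPs with extreme departure are treated as
#' likely genotyping errors.
#'
#' @param n_aa count of counted-allele homozygotes.
#' @param n_ab heterozygote count.
#' @param n_bb other-homozygote count.
#' @return Two-sided exact p-value in (0, 1].
#' @examples
#' hwe_exact_test(25, 50, 25)   # perfect HWE proportions -> 1
#' hwe_exact_test(50, 0, 50)    # extreme heterozygote deficit -> ~0
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("all genotype counts are zero")
  n_a <- 2L * n_aa + n_ab          # counted-allele copies
  n_b <- 2L * n_bb + n_ab
  if (n_a == 0L || n_b == 0L) return(1)  # monomorphic: single configuration
  # possible het counts share the parity of n_a
  k <- seq.int(n_a %% 2L, min(n_a, n_b), by = 2L)
  # log P(n_ab = k | n, n_a) up to a constant: multinomial x 2^k
  logp <- k * log(2) - lfactorial((n_a - k) / 2) - lfactorial(k) -
    lfactorial((n_b - k) / 2)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- p[match(n_ab, k)]
  sum(p[p <= obs * (1 + 1e-12)])
}

#' Quality-control profile
#'
#' Thresholds for the six sequential removal rules of [apply_qc()]:
#' (1) SNP call rate, (2) minor allele frequency, (3) joint call rate for
#' SNPs then individuals, (4) exact Hardy-Weinberg p-value, (5) unknown or
#' duplicated genomic positions, (6) non-autosomal SNPs.
#'
#' Two named profiles cover the two analysis tracks: `"default"` applies
#' all six rules; `"roh"` disables the MAF filter because ROH detection
#' must keep low-MAF (including monomorphic) SNPs — homozygosity at such
#' sites is informative for run length.
#'
#' @param name `"default"` or `"roh"`, or build a custom profile via the
#'   other arguments.
#' @param snp_call_rate_min rule-1 threshold (default 0.95).
#' @param maf_min rule-2 threshold (default 0.05).
#' @param apply_maf_filter logical; `FALSE` skips rule 2.
#' @param joint_call_rate_min rule-3 threshold applied to SNPs then samples
#'   (default 0.90).
#' @param hwe_p_min rule-4 p-value floor (default 1e-6).
#' @param drop_unknown_or_duplicate_pos rule 5 on/off.
#' @param autosomes_only rule 6 on/off.
#' @param autosomes chromosome labels counted as autosomes (default pig,
#'   `"1"`..`"18"`).
#' @return A `qc_profile` list.
#' @export
qc_profile <- function(name = "default",
                       snp_call_rate_min = 0.95,
                       maf_min = 0.05,
                       apply_maf_filter = NULL,
                       joint_call_rate_min = 0.90,
                       hwe_p_min = 1e-6,
                       drop_unknown_or_duplicate_pos = TRUE,
                       autosomes_only = TRUE,
                       autosomes = pig_autosomes()) {
  name <- match.arg(name, c("default", "roh"))
  if (is.null(apply_maf_filter)) apply_maf_filter <- (name == "default")
  p <- list(name = name,
            snp_call_rate_min = snp_call_rate_min,
            maf_min = maf_min,
            apply_maf_filter = apply_maf_filter,
            joint_call_rate_min = joint_call_rate_min,
            hwe_p_min = hwe_p_min,
            drop_unknown_or_duplicate_pos = drop_unknown_or_duplicate_pos,
            autosomes_only = autosomes_only,
            autosomes = autosomes)
  for (th in c("snp_call_rate_min", "maf_min", "joint_call_rate_min",
               "hwe_p_min"))
    if (p[[th]] < 0 || p[[th]] > 1) stop(th, " must lie in [0, 1]")
  structure(p, class = "qc_profile")
}

#' Apply the six-rule quality-control procedure
#'
#' Rules run in a fixed order, with call rates and allele frequencies
#' recomputed on the surviving data before each rule:
#' \enumerate{
#'   \item drop SNPs with call rate below `snp_call_rate_min`;
#'   \item drop SNPs with MAF below `maf_min` (skipped for the ROH profile);
#'   \item drop SNPs, then individuals, with call rate below
#'     `joint_call_rate_min`;
#'   \item drop SNPs with exact HWE p-value below `hwe_p_min`;
#'   \item drop SNPs with unknown (0/NA) or duplicated positions (all
#'     members of a duplicated (chromosome, position) group are removed);
#'   \item drop non-autosomal SNPs.
#' }
#' MAF and HWE are computed over non-missing genotypes pooled within the
#' dataset being filtered, so per-population filtering is obtained by
#' passing one population at a time.
#'
#' @param gm a [genotype_matrix()].
#' @param profile a [qc_profile()].
#' @return list with elements `gm` (filtered matrix) and `report` (a
#'   `qc_report` with one row per rule plus input/output dimensions).
#' @export
apply_qc <- function(gm, profile = qc_profile()) {
  validate_genotype_matrix(gm)
  stopifnot(inherits(profile, "qc_profile"))
  in_snps <- ncol(gm$dosage); in_samples <- nrow(gm$dosage)
  log <- data.frame(rule = integer(), description = character(),
                    snps_removed = integer(), samples_removed = integer(),
                    stringsAsFactors = FALSE)
  note <- function(rule, desc, nsnp, nsam) {
    rbind(log, data.frame(rule = rule, description = desc,
                          snps_removed = nsnp, samples_removed = nsam,
                          stringsAsFactors = FALSE))
  }
  drop_snps <- function(gm, bad) {
    if (!any(bad)) return(gm)
    if (all(bad)) stop("QC removed every SNP")
    subset_genotypes(gm, variant_filter = !bad)
  }

  # 1. SNP call rate
  cr <- colMeans(!is.na(gm$dosage))
  bad <- cr < profile$snp_call_rate_min
  log <- note(1L, "SNP call rate", sum(bad), 0L)
  gm <- drop_snps(gm, bad)

  # 2. MAF
  if (profile$apply_maf_filter) {
    p <- allele_frequencies(gm)
    maf <- pmin(p, 1 - p)
    bad <- !is.na(maf) & maf < profile$maf_min
    log <- note(2L, "minor allele frequency", sum(bad), 0L)
    gm <- drop_snps(gm, bad)
  } else {
    log <- note(2L, "minor allele frequency (disabled)", 0L, 0L)
  }

  # 3. joint call rate: SNPs first, then individuals
  cr <- colMeans(!is.na(gm$dosage))
  bad <- cr < profile$joint_call_rate_min
  n3s <- sum(bad)
  gm <- drop_snps(gm, bad)
  scr <- rowMeans(!is.na(gm$dosage))
  bads <- scr < profile$joint_call_rate_min
  if (all(bads)) stop("QC removed every sample")
  if (any(bads))
    gm <- subset_genotypes(gm, sample_filter = !bads)
  log <- note(3L, "joint call rate (SNPs, then samples)", n3s, sum(bads))

  # 4. exact HWE
  d <- gm$dosage
  pvals <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    hwe_exact_test(sum(g == 2L, na.rm = TRUE), sum(g == 1L, na.rm = TRUE),
                   sum(g == 0L, na.rm = TRUE))
  }, numeric(1))
  bad <- pvals < profile$hwe_p_min
  log <- note(4L, "Hardy-Weinberg exact test", sum(bad), 0L)
  gm <- drop_snps(gm, bad)

  # 5. unknown or duplicated positions
  if (profile$drop_unknown_or_duplicate_pos) {
    v <- gm$variants
    key <- paste(v$chromosome, v$position_bp)
    dup <- key %in% key[duplicated(key)]
    bad <- is.na(v$position_bp) | v$position_bp == 0L | dup
    log <- note(5L, "unknown or duplicated position", sum(bad), 0L)
    gm <- drop_snps(gm, bad)
  } else {
    log <- note(5L, "unknown or duplicated position (disabled)", 0L, 0L)
  }

  # 6. non-autosomal SNPs
  if (profile$autosomes_only) {
    bad <- !(gm$variants$chromosome %in% profile$autosomes)
    log <- note(6L, "non-autosomal chromosome", sum(bad), 0L)
    gm <- drop_snps(gm, bad)
  } else {
    log <- note(6L, "non-autosomal chromosome (disabled)", 0L, 0L)
  }

  report <- structure(list(rules = log,
                           input_snps = in_snps,
                           input_samples = in_samples,
                           output_snps = ncol(gm$dosage),
                           output_samples = nrow(gm$dosage),
                           profile = profile$name),
                      class = "qc_report")
  stopifnot(in_snps - sum(log$snps_removed) == ncol(gm$dosage),
            in_samples - sum(log$samples_removed) == nrow(gm$dosage))
  list(gm = gm, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report (profile '%s'): %d x %d -> %d x %d (samples x SNPs)\n",
              x$profile, x$input_samples, x$input_snps,
              x$output_samples, x$output_snps))
  print(x$rules, row.names = FALSE)
  invisible(x)
}

#' Flatten a QC report to a data.frame
#'
#' @param report a `qc_report` from [apply_qc()].
#' @return The per-rule removal table with dimension columns appended.
#' @export
qc_report_table <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  out <- report$rules
  out$input_snps <- report$input_snps
  out$output_snps <- report$output_snps
  out$input_samples <- report$input_samples
  out$output_samples <- report$output_samples
  out
}
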