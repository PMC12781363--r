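#' ROH detection parameters
#'
#' Parameters of the sliding-window run-of-homozygosity detector,
#' defaulting to the standard SNP-array settings: minimum run length
#' 500 kb, at least 15 consecutive SNPs, maximum gap between consecutive
#' SNPs 500 kb, minimum density of one SNP per 75 kb, a scanning window of
#' 50 SNPs moved one SNP at a time allowing at most five missing and one
#' heterozygous call per window, and a window hit-rate threshold of 0.05
#' for declaring a SNP inside a run.
#'
#' @param min_length_kb minimum run length (kb).
#' @param min_snps minimum number of SNPs in a run.
#' @param max_gap_kb maximum gap between consecutive SNPs inside a run (kb).
#' @param max_kb_per_snp maximum average spacing (kb per SNP) inside a run.
#' @param window_snps scanning window size (SNPs).
#' @param window_max_missing maximum missing calls per homozygous window.
#' @param window_max_het maximum heterozygous calls per homozygous window.
#' @param window_hit_threshold minimum fraction of homozygous windows
#'   covering a SNP for that SNP to be called in-run.
#' @return A `roh_params` list.
#' @export
roh_params <- function(min_length_kb = 500, min_snps = 15L,
                       max_gap_kb = 500, max_kb_per_snp = 75,
                       window_snps = 50L, window_max_missing = 5L,
                       window_max_het = 1L, window_hit_threshold = 0.05) {
  p <- list(min_length_kb = min_length_kb, min_snps = as.integer(min_snps),
            max_gap_kb = max_gap_kb, max_kb_per_snp = max_kb_per_snp,
            window_snps = as.integer(window_snps),
            window_max_missing = as.integer(window_max_missing),
            window_max_het = as.integer(window_max_het),
            window_hit_threshold = window_hit_threshold)
  if (any(unlist(p[c(1:5)]) <= 0) || p$window_max_missing < 0 ||
      p$window_max_het < 0)
    stop("roh_params must be positive (window allowances non-negative)")
  if (p$window_hit_threshold <= 0 || p$window_hit_threshold > 1)
    stop("window_hit_threshold must lie in (0, 1]")
  structure(p, class = "roh_params")
}

# ROH length classes in Mb: lower-inclusive boundaries
.roh_class_breaks <- c(0, 2, 4, 8, 16, Inf)
.roh_class_labels <- c("lt2", "2to4", "4to8", "8to16", "gt16")

roh_length_class <- function(length_bp) {
  cut(length_bp / 1e6, breaks = .roh_class_breaks,
      labels = .roh_class_labels, right = FALSE)
}

#' Detect runs of homozygosity
#'
#' Per sample and chromosome, a window of `window_snps` consecutive SNPs
#' slides one SNP at a time; a window is homozygous when it contains at
#' most `window_max_het` heterozygous and `window_max_missing` missing
#' calls.  Each SNP's hit fraction is the proportion of homozygous windows
#' among all windows covering it; SNPs at or above
#' `window_hit_threshold` are in-run.  Maximal stretches of consecutive
#' in-run SNPs are split at inter-SNP gaps larger than `max_gap_kb`,
#' trimmed so that both endpoints are homozygous non-missing SNPs, and
#' emitted when they satisfy the minimum SNP count, minimum length and
#' density constraints.  Chromosomes carrying fewer SNPs than the window
#' are scanned with the largest feasible window.
#'
#' The input should be prepared with the `"roh"` QC profile (no MAF
#' filter): removing low-MAF SNPs would artificially break up and shorten
#' runs.
#'
#' @param gm a [genotype_matrix()] (one population).
#' @param params a [roh_params()].
#' @return data.frame of segments: sample_id, chromosome, start_bp,
#'   end_bp (1-based closed, at the first/last SNP of the run), n_snps,
#'   length_bp, length_class.
#' @export
detect_roh <- function(gm, params = roh_params()) {
  validate_genotype_matrix(gm)
  stopifnot(inherits(params, "roh_params"))
  v <- gm$variants
  out <- vector("list", 0L)
  for (ch in unique(v$chromosome)) {
    idx <- which(v$chromosome == ch)
    pos <- v$position_bp[idx]
    if (is.unsorted(pos)) stop("unsorted positions on chromosome ", ch)
    for (s in seq_len(nrow(gm$dosage))) {
      g <- gm$dosage[s, idx]
      segs <- roh_scan_one(g, pos, params)
      if (nrow(segs)) {
        segs$sample_id <- gm$samples$sample_id[s]
        segs$chromosome <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (!length(out)) {
    return(data.frame(sample_id = character(), chromosome = character(),
                      start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = numeric(),
                      length_class = factor(character(),
                                            levels = .roh_class_labels),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[, c("sample_id", "chromosome", "start_bp", "end_bp", "n_snps",
                 "length_bp", "length_class")]
  rownames(res) <- NULL
  res
}

# single-sample single-chromosome scan; g in {0,1,2,NA}, pos sorted
roh_scan_one <- function(g, pos, params) {
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      n_snps = integer(), length_bp = numeric(),
                      length_class = factor(character(),
                                            levels = .roh_class_labels))
  m <- length(g)
  if (m < params$min_snps) return(empty)
  w <- min(params$window_snps, m)
  nw <- m - w + 1L
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  chet <- c(0L, cumsum(het))
  cmis <- c(0L, cumsum(mis))
  ws <- seq_len(nw)
  hom_win <- (chet[ws + w] - chet[ws]) <= params$window_max_het &
    (cmis[ws + w] - cmis[ws]) <= params$window_max_missing
  chom <- c(0L, cumsum(as.integer(hom_win)))
  j <- seq_len(m)
  lo <- pmax(1L, j - w + 1L)
  hi <- pmin(j, nw)
  # hi >= lo always (nw >= 1); windows covering SNP j start in [lo, hi]
  covering <- hi - lo + 1L
  hom_cov <- chom[hi + 1L] - chom[lo]
  in_run <- hom_cov / covering >= params$window_hit_threshold
  if (!any(in_run)) return(empty)
  r <- rle(in_run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pieces <- list()
  gap_bp <- params$max_gap_kb * 1000
  for (k in which(r$values)) {
    i1 <- starts[k]; i2 <- ends[k]
    # split at large inter-SNP gaps
    if (i2 > i1) {
      gaps <- which(diff(pos[i1:i2]) > gap_bp)
      cutpts <- c(i1 - 1L, i1 - 1L + gaps, i2)
    } else {
      cutpts <- c(i1 - 1L, i2)
    }
    for (q in seq_len(length(cutpts) - 1L)) {
      a <- cutpts[q] + 1L; b <- cutpts[q + 1L]
      # trim to homozygous non-missing endpoints
      while (a <= b && (is.na(g[a]) || g[a] == 1L)) a <- a + 1L
      while (b >= a && (is.na(g[b]) || g[b] == 1L)) b <- b - 1L
      if (b < a) next
      n_snps <- b - a + 1L
      len <- as.numeric(pos[b]) - as.numeric(pos[a]) + 1
      if (n_snps >= params$min_snps &&
          len >= params$min_length_kb * 1000 &&
          len / n_snps <= params$max_kb_per_snp * 1000) {
        pieces[[length(pieces) + 1L]] <-
          data.frame(start_bp = pos[a], end_bp = pos[b], n_snps = n_snps,
                     length_bp = len,
                     length_class = roh_length_class(len))
      }
    }
  }
  if (!length(pieces)) return(empty)
  do.call(rbind, pieces)
}

#' Summarize ROH segments by length class
#'
#' Per population: mean, SD and range of segment length plus segment
#' counts within the five length classes (`[0.5, 2)`, `[2, 4)`, `[4, 8)`,
#' `[8, 16)` and `>= 16` Mb, lower-inclusive).
#'
#' @param segments output of [detect_roh()].
#' @param population_of optional named vector mapping sample_id to
#'   population; when absent all segments are summarized as one population
#'   labelled `"all"`.
#' @return data.frame with one row per population.
#' @export
roh_summary <- function(segments, population_of = NULL) {
  pop <- if (is.null(population_of)) rep("all", nrow(segments))
         else unname(population_of[segments$sample_id])
  groups <- if (nrow(segments)) split(seq_len(nrow(segments)), pop) else list()
  rows <- lapply(names(groups), function(p) {
    s <- segments[groups[[p]], ]
    counts <- table(factor(s$length_class, levels = .roh_class_labels))
    data.frame(population = p, n_roh = nrow(s),
               mean_length_mb = mean(s$length_bp) / 1e6,
               sd_length_mb = if (nrow(s) > 1) sd(s$length_bp) / 1e6 else 0,
               min_length_mb = min(s$length_bp) / 1e6,
               max_length_mb = max(s$length_bp) / 1e6,
               n_lt2 = as.integer(counts["lt2"]),
               n_2to4 = as.integer(counts["2to4"]),
               n_4to8 = as.integer(counts["4to8"]),
               n_8to16 = as.integer(counts["8to16"]),
               n_gt16 = as.integer(counts["gt16"]),
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(population = character(), n_roh = integer(),
                      mean_length_mb = numeric(), sd_length_mb = numeric(),
                      min_length_mb = numeric(), max_length_mb = numeric(),
                      n_lt2 = integer(), n_2to4 = integer(),
                      n_4to8 = integer(), n_8to16 = integer(),
                      n_gt16 = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-SNP ROH incidence
#'
#' For every SNP, the fraction of the population's individuals having at
#' least one ROH segment whose interval contains the SNP position.
#'
#' @param segments [detect_roh()] output for the population in `gm`.
#' @param gm the same population's [genotype_matrix()].
#' @return Numeric vector (length `n_snps`, named by snp_id) of fractions.
#' @export
roh_incidence <- function(segments, gm) {
  n <- nrow(gm$dosage)
  if (n == 0L) stop("population has no samples")
  v <- gm$variants
  count <- numeric(nrow(v))
  for (s in unique(segments$sample_id)) {
    covered <- logical(nrow(v))
    segs <- segments[segments$sample_id == s, ]
    for (i in seq_len(nrow(segs))) {
      hit <- v$chromosome == segs$chromosome[i] &
        v$position_bp >= segs$start_bp[i] & v$position_bp <= segs$end_bp[i]
      covered <- covered | hit
    }
    count <- count + covered
  }
  setNames(count / n, v$snp_id)
}

#' Call ROH islands from per-SNP incidence
#'
#' Dual-threshold rule: candidate SNPs must have incidence at or above the
#' population's empirical `quantile` (nearest-rank) **and** at or above
#' `min_incidence`.  Candidates on the same chromosome separated by less
#' than `merge_gap_kb` are merged into maximal intervals whose bounds are
#' the first and last candidate SNP positions.
#'
#' @param incidence vector from [roh_incidence()].
#' @param variants the matching variant table (`gm$variants`).
#' @param quantile empirical quantile for the adaptive cutoff (default
#'   0.99, i.e. the top 1%).
#' @param min_incidence absolute incidence floor (default 0.35).
#' @param merge_gap_kb merge distance; candidates closer than this merge.
#' @return data.frame of islands: chromosome, start_bp, end_bp, n_snps
#'   (candidate SNPs), peak_incidence, mean_incidence (over all SNPs in
#'   the interval).
#' @export
detect_islands <- function(incidence, variants, quantile = 0.99,
                           min_incidence = 0.35, merge_gap_kb = 100) {
  stopifnot(length(incidence) == nrow(variants), length(incidence) >= 1L)
  cutoff <- nearest_rank_quantile(incidence, quantile)
  cand <- which(incidence >= cutoff & incidence >= min_incidence)
  empty <- data.frame(chromosome = character(), start_bp = integer(),
                      end_bp = integer(), n_snps = integer(),
                      peak_incidence = numeric(), mean_incidence = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  rows <- list()
  for (ch in unique(variants$chromosome[cand])) {
    ci <- cand[variants$chromosome[cand] == ch]
    pos <- variants$position_bp[ci]
    brk <- c(0L, which(diff(pos) >= merge_gap_kb * 1000), length(ci))
    for (q in seq_len(length(brk) - 1L)) {
      grp <- ci[(brk[q] + 1L):brk[q + 1L]]
      span <- variants$chromosome == ch &
        variants$position_bp >= variants$position_bp[grp[1L]] &
        variants$position_bp <= variants$position_bp[grp[length(grp)]]
      rows[[length(rows) + 1L]] <- data.frame(
        chromosome = ch,
        start_bp = variants$position_bp[grp[1L]],
        end_bp = variants$position_bp[grp[length(grp)]],
        n_snps = length(grp),
        peak_incidence = max(incidence[grp]),
        mean_incidence = mean(incidence[span]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$chromosome, out$start_bp), , drop = FALSE]
}

#' Shared ROH islands across the populations of a group
#'
#' Genomic intersection: maximal intervals covered by at least one island
#' in **every** member population, reported with the intersected
#' coordinates.
#'
#' @param islands_by_population named list of [detect_islands()] outputs
#'   (at least two populations).
#' @return data.frame with chromosome, start_bp, end_bp.
#' @export
shared_islands <- function(islands_by_population) {
  if (length(islands_by_population) < 2L)
    stop("a group must contain at least two populations")
  Reduce(intersect_intervals, islands_by_population)
}
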