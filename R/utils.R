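#' Nearest-rank empirical quantile
#'
#' Deterministic quantile used for ROH-island and F_ST outlier cutoffs:
#' the value at rank `ceiling(p * n)` of the sorted sample (type-1 inverse
#' empirical CDF).
#'
#' @param x numeric vector (NAs dropped).
#' @param p probability in (0, 1].
#' @return A single numeric value.
#' @export
nearest_rank_quantile <- function(x, p) {
  x <- x[!is.na(x)]
  stopifnot(length(x) >= 1L, p > 0, p <= 1)
  xs <- sort(x)
  xs[max(1L, ceiling(p * length(xs)))]
}

## interval utilities on 1-based closed intervals, per chromosome ------------

# data.frame(chromosome, start_bp, end_bp) -> same, overlapping/adjacent
# intervals merged (gap 0 means touching intervals merge)
merge_intervals <- function(df, min_gapwidth = 1L) {
  if (nrow(df) == 0L) return(df[, c("chromosome", "start_bp", "end_bp")])
  out <- lapply(split(df, df$chromosome), function(d) {
    ir <- IRanges::reduce(IRanges::IRanges(d$start_bp, d$end_bp),
                          min.gapwidth = min_gapwidth)
    data.frame(chromosome = d$chromosome[1L],
               start_bp = IRanges::start(ir), end_bp = IRanges::end(ir),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chromosome, out$start_bp), , drop = FALSE]
}

# genomic intersection of two interval sets (both merged internally)
intersect_intervals <- function(df1, df2) {
  empty <- data.frame(chromosome = character(), start_bp = integer(),
                      end_bp = integer(), stringsAsFactors = FALSE)
  if (nrow(df1) == 0L || nrow(df2) == 0L) return(empty)
  chroms <- intersect(unique(df1$chromosome), unique(df2$chromosome))
  out <- lapply(chroms, function(ch) {
    a <- df1[df1$chromosome == ch, ]
    b <- df2[df2$chromosome == ch, ]
    ir <- IRanges::intersect(
      IRanges::reduce(IRanges::IRanges(a$start_bp, a$end_bp)),
      IRanges::reduce(IRanges::IRanges(b$start_bp, b$end_bp)))
    if (length(ir) == 0L) return(NULL)
    data.frame(chromosome = ch, start_bp = IRanges::start(ir),
               end_bp = IRanges::end(ir), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(empty)
  rownames(out) <- NULL
  out[order(out$chromosome, out$start_bp), , drop = FALSE]
}

# total width of the union of intervals
union_width <- function(df) {
  if (nrow(df) == 0L) return(0)
  m <- merge_intervals(df)
  sum(as.numeric(m$end_bp) - as.numeric(m$start_bp) + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
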