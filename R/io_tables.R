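#' Write a result table as tab-separated text
#'
#' All tabular results of the pipeline (QC reports, diversity summaries,
#' ROH segments and islands, inbreeding records, LD bins, Ne trajectories,
#' F_ST windows) are plain data.frames and share this writer.  Column order
#' is taken from the data.frame; an empty table yields a header-only file.
#'
#' @param records a data.frame (possibly zero rows).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(records, path) {
  stopifnot(is.data.frame(records))
  ok <- tryCatch({
    utils::write.table(records, path, quote = FALSE, sep = "\t",
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Export genomic intervals as BED
#'
#' Internal coordinates are 1-based closed intervals; BED is 0-based
#' half-open, so `start` is decremented by one and `end` kept.  Works for
#' ROH segments, islands, F_ST outlier regions and any data.frame with
#' `chromosome`, `start_bp`, `end_bp` columns; remaining columns are
#' appended as a name/score-style fourth column when `name_col` is given.
#'
#' @param records data.frame with `chromosome`, `start_bp`, `end_bp`.
#' @param path output BED path.
#' @param name_col optional column to carry into the BED name field.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path, name_col = NULL) {
  stopifnot(all(c("chromosome", "start_bp", "end_bp") %in% names(records)))
  bed <- data.frame(records$chromosome,
                    as.integer(records$start_bp) - 1L,
                    as.integer(records$end_bp))
  if (!is.null(name_col)) bed[[4L]] <- records[[name_col]]
  utils::write.table(bed, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
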