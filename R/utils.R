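#' @importFrom stats quantile rbinom rpois sd cor cor.test kruskal.test
#'   wilcox.test rmultinom setNames p.adjust
#' @importFrom utils write.table read.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_polterm <- function(...) stop(sprintf(...), call. = FALSE)

#' Standard error of the mean
#'
#' Returns `NA` (flagged, not an error) for fewer than two observations.
#' @param x numeric vector
#' @return standard error, or `NA_real_` when undefined
#' @keywords internal
std_error <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# 0-based half-open intervals are used throughout (BED convention).
# Helpers below convert to/from the 1-based closed convention of GRanges
# at the I/O boundary only.

granges_to_bed0 <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

bed0_to_granges <- function(df, strand = NULL, seqlengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = if (is.null(strand)) "*" else strand
  )
  if (!is.null(seqlengths)) {
    GenomicRanges::seqlevels(gr) <- names(seqlengths)
    GenomicRanges::seqlengths(gr) <- seqlengths
  }
  gr
}

#' Write a data frame as a tab-separated table with a header line
#' @param df data frame
#' @param path output path
#' @return `path`, invisibly
#' @keywords internal
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
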