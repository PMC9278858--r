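#' Read-through region calling
#'
#' Background is estimated as an empirical quantile (default 95%) of total
#' signal in nonoverlapping 20-bp windows over protein-coding genes, which
#' are transcribed by RNA polymerase II and so carry only off-target signal
#' in an RNAPIII occupancy experiment. The 1-kb region downstream of each
#' gene's primary terminator is then tiled with 20-bp windows; windows whose
#' total signal exceeds the threshold are merged into fragments, fragments
#' separated by small gaps are merged, and the read-through (RT) region is
#' the interval from the first base after the primary tract to the 3'-most
#' base of the last retained fragment.
#'
#' @name rt-calling
NULL

#' Estimate the background signal threshold
#'
#' Each coding gene is divided into nonoverlapping windows of `window_bp`
#' starting at its 5' end; windows truncated at the gene end are discarded.
#' The threshold is the empirical `quantile` (linear interpolation between
#' order statistics, R type 7) of the per-window total strand-matched
#' signal.
#'
#' @param pair plus/minus `coverage_track` pair
#' @param coding_genes gene table of protein-coding genes
#' @param window_bp window width, default 20
#' @param quantile quantile level in (0,1), default 0.95
#' @return a `threshold_model` list: `window_bp`, `quantile`,
#'   `threshold_value` (per-window total signal units), `n_windows_used`
#' @export
background_threshold <- function(pair, coding_genes, window_bp = 20L,
                                 quantile = 0.95) {
  if (quantile <= 0 || quantile >= 1) stop_polterm("quantile must be in (0,1)")
  totals <- unlist(lapply(seq_len(nrow(coding_genes)), function(i) {
    g <- coding_genes[i, ]
    v <- strand_track(pair, g$strand)$values[[g$chrom]][(g$start + 1L):g$end]
    n_win <- length(v) %/% window_bp
    if (n_win == 0L) return(numeric())
    colSums(matrix(v[seq_len(n_win * window_bp)], nrow = window_bp))
  }))
  if (length(totals) == 0L)
    stop_polterm("no complete %d-bp windows in the coding gene set", window_bp)
  structure(
    list(window_bp = as.integer(window_bp), quantile = quantile,
         threshold_value = unname(stats::quantile(totals, quantile, type = 7)),
         n_windows_used = length(totals)),
    class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("threshold_model: %g (%d%% quantile of %d %d-bp windows)\n",
              x$threshold_value, round(100 * x$quantile), x$n_windows_used,
              x$window_bp))
  invisible(x)
}

# Merge marked windows (offset-space intervals) into fragments, then close
# gaps <= max_gap_bp. Input starts are sorted ascending.
merge_windows <- function(starts, window_bp, max_gap_bp) {
  if (length(starts) == 0L) return(NULL)
  frag_start <- starts[1L]
  frag_end <- starts[1L] + window_bp
  frags <- list()
  for (s in starts[-1L]) {
    if (s <= frag_end) {           # overlapping or adjacent window
      frag_end <- max(frag_end, s + window_bp)
    } else {
      frags[[length(frags) + 1L]] <- c(frag_start, frag_end)
      frag_start <- s
      frag_end <- s + window_bp
    }
  }
  frags[[length(frags) + 1L]] <- c(frag_start, frag_end)
  m <- do.call(rbind, frags)
  # close small gaps
  keep <- list(m[1L, ])
  for (i in seq_len(nrow(m))[-1L]) {
    prev <- keep[[length(keep)]]
    if (m[i, 1L] - prev[2L] <= max_gap_bp) {
      keep[[length(keep)]] <- c(prev[1L], m[i, 2L])
    } else {
      keep[[length(keep) + 1L]] <- m[i, ]
    }
  }
  do.call(rbind, keep)
}

#' Call the read-through region downstream of one gene's primary terminator
#'
#' Windows of `window_bp` are tiled from the first base after the primary
#' tract over `span_bp` downstream (transcription orientation), advancing by
#' `step_bp`; the default step `window_bp - 1` gives adjacent windows a 1-bp
#' overlap, and `step_bp = 1` selects the dense sliding reading. Windows
#' whose total strand-matched signal is strictly above the threshold are
#' merged; fragments separated by at most `max_gap_bp` are joined. The
#' returned region always starts at the first base after the primary tract
#' and ends at the 3'-most base of the last retained fragment, so fragments
#' disconnected from the terminator still extend the region (the bounding
#' interval); `fragments_merged` records the fragment count after gap
#' closing. A span extending past the chromosome end is truncated with a
#' warning.
#'
#' @param pair plus/minus `coverage_track` pair
#' @param anno a `terminator_annotation` with a primary terminator
#' @param threshold a `threshold_model` (or a bare numeric threshold value on
#'   the same per-window total scale)
#' @param span_bp downstream span, default 1000
#' @param window_bp window width, default 20
#' @param step_bp step between window starts; default `window_bp - 1`
#' @param max_gap_bp largest gap closed between fragments, default 20
#' @return an `rt_region` list: `gene_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open; degenerate `end == start` when empty),
#'   `rt_length_bp`, `fragments_merged`, `empty`
#' @export
call_rt_region <- function(pair, anno, threshold, span_bp = 1000L,
                           window_bp = 20L, step_bp = window_bp - 1L,
                           max_gap_bp = 20L) {
  if (is.null(anno$primary))
    stop_polterm("gene %s has no primary terminator", anno$gene_id)
  thr <- if (inherits(threshold, "threshold_model")) threshold$threshold_value
         else as.numeric(threshold)
  strand <- anno$gene$strand
  chrom <- anno$gene$chrom
  p3 <- tract_three_edge(anno$primary, strand)
  track <- strand_track(pair, strand)
  clen <- chrom_sizes(track)[[chrom]]
  avail <- if (strand == "+") clen - p3 else p3
  span_eff <- min(span_bp, avail)
  if (span_eff < span_bp)
    warning(sprintf("gene %s: downstream span truncated to %d bp at %s end",
                    anno$gene_id, span_eff, chrom), call. = FALSE)
  # per-base values in transcription orientation, offset 0 = first base
  # after the primary tract
  v <- if (strand == "+") {
    track$values[[chrom]][(p3 + 1L):(p3 + span_eff)]
  } else {
    rev(track$values[[chrom]][(p3 - span_eff + 1L):p3])
  }
  if (span_eff >= window_bp) {
    offs <- seq.int(0L, span_eff - window_bp, by = step_bp)
    # a final flush window so the 3' end of the span is always covered
    if (offs[length(offs)] != span_eff - window_bp)
      offs <- c(offs, span_eff - window_bp)
    cums <- c(0, cumsum(v))
    totals <- cums[offs + window_bp + 1L] - cums[offs + 1L]
    marked <- offs[totals > thr]
  } else {
    marked <- integer()
  }
  frags <- merge_windows(marked, window_bp, max_gap_bp)
  empty <- is.null(frags)
  rt_len <- if (empty) 0L else as.integer(min(max(frags[, 2L]), span_eff))
  region <- if (strand == "+") c(p3, p3 + rt_len) else c(p3 - rt_len, p3)
  structure(
    list(gene_id = anno$gene_id, chrom = chrom, strand = strand,
         start = region[1L], end = region[2L], rt_length_bp = rt_len,
         fragments_merged = if (empty) 0L else nrow(frags), empty = empty),
    class = "rt_region")
}

#' Read-through length of a called region
#' @param region an `rt_region`
#' @return integer length in bp (0 when empty)
#' @export
rt_length <- function(region) region$rt_length_bp

#' Call RT regions for every annotated gene
#'
#' @param pair plus/minus track pair
#' @param anno_table table from [annotate_terminators()] (flagged genes are
#'   skipped and reported in the result's `"n_flagged"` attribute)
#' @param threshold a `threshold_model`
#' @param ... passed to [call_rt_region()]
#' @return data frame, one row per gene with a primary terminator:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `rt_length_bp`,
#'   `fragments_merged`, `empty`
#' @export
call_rt_regions <- function(pair, anno_table, threshold, ...) {
  annos <- attr(anno_table, "annos")
  ok <- !anno_table$flagged
  rows <- lapply(annos[ok], function(a) {
    r <- call_rt_region(pair, a, threshold, ...)
    data.frame(gene_id = r$gene_id, chrom = r$chrom, strand = r$strand,
               start = r$start, end = r$end, rt_length_bp = r$rt_length_bp,
               fragments_merged = r$fragments_merged, empty = r$empty,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  structure(out, n_flagged = sum(!ok))
}

#' Write called RT regions as BED6 (name = gene_id, score = RT length)
#' @param rt_table result of [call_rt_regions()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_rt_bed <- function(rt_table, path) {
  df <- rt_table[!rt_table$empty, , drop = FALSE]
  df$name <- df$gene_id
  df$score <- df$rt_length_bp
  write_bed6(df, path)
}
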