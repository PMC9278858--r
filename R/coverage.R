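#' Strand-specific per-base coverage tracks
#'
#' A `coverage_track` holds one dense nonnegative numeric vector per
#' chromosome for one sample and one strand. Tracks are built from 4-column
#' bedGraph files (positions absent from the file are 0) and normalized to
#' counts per million (CPM) jointly over the plus/minus pair, matching
#' single-base-bin coverage normalization. Minus-strand files store
#' nonnegative values; strand is carried by file role, not by sign.
#'
#' @name coverage
NULL

#' Construct a coverage track
#'
#' @param values named list of numeric vectors, one per chromosome
#' @param chrom_sizes named integer vector; lengths must match `values`
#' @param strand `"+"` or `"-"`
#' @param sample_id,condition free-text labels
#' @param normalized whether values are CPM (`TRUE`) or raw counts
#' @param total_raw total raw read count the track was built from, if known
#' @return a `coverage_track`
#' @export
coverage_track <- function(values, chrom_sizes, strand,
                           sample_id = "sample", condition = "other",
                           normalized = FALSE, total_raw = NA_real_) {
  if (!strand %in% c("+", "-")) stop_polterm("strand must be '+' or '-'")
  if (!setequal(names(values), names(chrom_sizes)))
    stop_polterm("track chromosomes do not match chrom_sizes")
  values <- values[names(chrom_sizes)]
  for (chrom in names(values)) {
    v <- values[[chrom]]
    if (length(v) != chrom_sizes[[chrom]])
      stop_polterm("track length %d != chromosome length %d for %s",
                   length(v), chrom_sizes[[chrom]], chrom)
    if (any(!is.finite(v)) || any(v < 0))
      stop_polterm("coverage values must be finite and >= 0 (%s)", chrom)
  }
  structure(list(values = values, strand = strand, sample_id = sample_id,
                 condition = condition, normalized = normalized,
                 total_raw = total_raw),
            chrom_sizes = chrom_sizes, class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track %s [%s] strand %s: %d chromosome(s), total %.4g%s\n",
              x$sample_id, x$condition, x$strand, length(x$values),
              track_total(x), if (x$normalized) " (CPM)" else " (raw)"))
  invisible(x)
}

track_total <- function(track) sum(vapply(track$values, sum, numeric(1)))

parse_bedgraph <- function(path, chrom_sizes) {
  values <- lapply(chrom_sizes, numeric)
  info <- file.info(path)
  if (!is.na(info$size) && info$size == 0) return(values)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (length(gr) == 0L) return(values)
  df <- granges_to_bed0(gr)
  df$score <- gr$score
  unknown <- setdiff(unique(df$chrom), names(chrom_sizes))
  if (length(unknown))
    stop_polterm("%s: unknown chromosome '%s'", path, unknown[1L])
  for (chrom in unique(df$chrom)) {
    d <- df[df$chrom == chrom, , drop = FALSE]
    if (any(d$end > chrom_sizes[[chrom]]))
      stop_polterm("%s: interval past end of %s", path, chrom)
    cov <- rep(0L, chrom_sizes[[chrom]])
    for (i in seq_len(nrow(d))) {
      idx <- (d$start[i] + 1L):d$end[i]
      if (any(cov[idx] != 0L))
        stop_polterm("%s: overlapping bedGraph intervals on %s near %d",
                     path, chrom, d$start[i])
      cov[idx] <- 1L
    }
    v <- values[[chrom]]
    v[unlist(Map(function(s, e) (s + 1L):e, d$start, d$end))] <-
      rep(d$score, d$end - d$start)
    values[[chrom]] <- v
  }
  values
}

#' Load a strand-specific coverage pair from bedGraph files
#'
#' @param plus_file,minus_file bedGraph paths (4 whitespace-separated
#'   columns); an empty file yields an all-zero track
#' @param chrom_sizes named integer vector (see [read_chrom_sizes()])
#' @param sample_id,condition labels attached to both tracks
#' @param normalized whether the files already hold CPM values
#' @return list with elements `plus` and `minus` (two `coverage_track`s)
#' @export
load_coverage <- function(plus_file, minus_file, chrom_sizes,
                          sample_id = "sample", condition = "other",
                          normalized = FALSE) {
  list(
    plus = coverage_track(parse_bedgraph(plus_file, chrom_sizes), chrom_sizes,
                          "+", sample_id, condition, normalized),
    minus = coverage_track(parse_bedgraph(minus_file, chrom_sizes), chrom_sizes,
                           "-", sample_id, condition, normalized)
  )
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal value are collapsed into single intervals; zero runs are
#' omitted. Values are printed with full double precision so a write/load
#' round trip is lossless.
#'
#' @param track a `coverage_track`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    r <- rle(track$values[[chrom]])
    ends <- cumsum(r$lengths)
    keep <- r$values != 0
    if (!any(keep)) next
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%.17g", chrom, starts[keep], ends[keep],
                       r$values[keep]), con)
  }
  invisible(path)
}

#' Normalize a raw-count track pair to counts per million
#'
#' Each value is scaled by 1e6 / (joint raw total of the plus and minus
#' tracks), so total CPM over both strands is 1e6.
#'
#' @param pair list with `plus` and `minus` raw-count tracks
#' @return the pair, CPM-normalized, with `total_raw` recorded
#' @export
normalize_cpm <- function(pair) {
  total <- track_total(pair$plus) + track_total(pair$minus)
  if (total <= 0) stop_polterm("normalize_cpm: zero total raw count")
  for (s in c("plus", "minus")) {
    pair[[s]]$values <- lapply(pair[[s]]$values, function(v) v * 1e6 / total)
    pair[[s]]$normalized <- TRUE
    pair[[s]]$total_raw <- total
  }
  pair
}

#' Pick the strand-matched track from a plus/minus pair
#' @param pair list with `plus` and `minus` tracks
#' @param strand `"+"` or `"-"`
#' @return a `coverage_track`
#' @export
strand_track <- function(pair, strand) {
  if (strand == "+") pair$plus else if (strand == "-") pair$minus
  else stop_polterm("strand must be '+' or '-'")
}

#' Signal summary over one region
#'
#' @param track a `coverage_track` (already strand-matched; see
#'   [strand_track()])
#' @param chrom chromosome name
#' @param start,end 0-based half-open interval
#' @return list: `total`, `mean`, `max`, `length`
#' @export
region_signal <- function(track, chrom, start, end) {
  sizes <- chrom_sizes(track)
  if (!chrom %in% names(sizes)) stop_polterm("unknown chromosome: %s", chrom)
  if (start < 0 || end > sizes[[chrom]])
    stop_polterm("region [%d,%d) out of bounds for %s", start, end, chrom)
  if (start >= end) stop_polterm("zero-width region [%d,%d)", start, end)
  v <- track$values[[chrom]][(start + 1L):end]
  list(total = sum(v), mean = mean(v), max = max(v), length = end - start)
}

#' Average replicate tracks per base
#'
#' @param tracks list of same-strand, same-genome `coverage_track`s
#' @return a `coverage_track` of per-base means, labelled `"mean"`
#' @export
average_replicates <- function(tracks) {
  if (length(tracks) == 0L) stop_polterm("no tracks to average")
  strands <- vapply(tracks, `[[`, character(1), "strand")
  if (length(unique(strands)) != 1L)
    stop_polterm("cannot average tracks of mixed strands")
  sizes <- chrom_sizes(tracks[[1L]])
  values <- lapply(names(sizes), function(chrom) {
    Reduce(`+`, lapply(tracks, function(t) t$values[[chrom]])) / length(tracks)
  })
  names(values) <- names(sizes)
  coverage_track(values, sizes, strands[1L], sample_id = "mean",
                 condition = tracks[[1L]]$condition,
                 normalized = all(vapply(tracks, `[[`, logical(1), "normalized")))
}

#' Rank correlation between two samples over gene regions
#'
#' For each gene, the mean signal over the gene extended by `flank_bp` on
#' each side (strand-matched, clipped to the chromosome) is computed in both
#' samples; the Spearman (default) correlation of the two per-gene vectors is
#' returned. A constant vector makes the correlation undefined: the result
#' carries `rho = NA` and `defined = FALSE` rather than a silent 0.
#'
#' @param pair_a,pair_b plus/minus track pairs ([load_coverage()])
#' @param genes gene table
#' @param flank_bp flank width, default 500
#' @param method correlation method, default `"spearman"`
#' @param statistic `"mean"` (default) or `"total"` per-gene signal
#' @return list: `rho`, `defined`, `method`, `per_gene` data frame
#' @export
correlate_samples <- function(pair_a, pair_b, genes, flank_bp = 500L,
                              method = "spearman", statistic = "mean") {
  if (nrow(genes) < 3L) stop_polterm("need >= 3 genes to correlate")
  sizes <- chrom_sizes(pair_a$plus)
  gene_stat <- function(pair, g) {
    start <- max(0L, g$start - flank_bp)
    end <- min(sizes[[g$chrom]], g$end + flank_bp)
    sig <- region_signal(strand_track(pair, g$strand), g$chrom, start, end)
    if (statistic == "mean") sig$mean else sig$total
  }
  a <- vapply(seq_len(nrow(genes)), function(i) gene_stat(pair_a, genes[i, ]),
              numeric(1))
  b <- vapply(seq_len(nrow(genes)), function(i) gene_stat(pair_b, genes[i, ]),
              numeric(1))
  defined <- stats::sd(a) > 0 && stats::sd(b) > 0
  rho <- if (defined) stats::cor(a, b, method = method) else NA_real_
  list(rho = rho, defined = defined, method = method,
       per_gene = data.frame(gene_id = genes$gene_id, signal_a = a,
                             signal_b = b, stringsAsFactors = FALSE))
}
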