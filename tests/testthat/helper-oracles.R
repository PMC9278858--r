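# Shared fixtures and independent oracles. Oracles deliberately avoid the
# package's code paths: the tract oracle uses base-R regex (and a literal
# per-position loop), the RT oracle marks bases window by window.

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Regex-based run enumerator over a named character vector of sequences.
oracle_tracts_regex <- function(seqs, min_len) {
  rows <- list()
  for (chrom in names(seqs)) {
    for (strand in c("+", "-")) {
      base <- if (strand == "+") "T" else "A"
      m <- gregexpr(sprintf("%s{%d,}", base, min_len), seqs[[chrom]])[[1L]]
      if (m[1L] == -1L) next
      len <- attr(m, "match.length")
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = chrom, start = as.integer(m - 1L),
        end = as.integer(m - 1L + len), strand = strand,
        length = as.integer(len), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Literal per-position scan: extend a run base by base.
oracle_tracts_loop <- function(seqs, min_len) {
  rows <- list()
  for (chrom in names(seqs)) {
    chars <- strsplit(seqs[[chrom]], "")[[1L]]
    for (strand in c("+", "-")) {
      base <- if (strand == "+") "T" else "A"
      i <- 1L
      while (i <= length(chars)) {
        if (chars[i] == base) {
          j <- i
          while (j < length(chars) && chars[j + 1L] == base) j <- j + 1L
          if (j - i + 1L >= min_len)
            rows[[length(rows) + 1L]] <- data.frame(
              chrom = chrom, start = i - 1L, end = j, strand = strand,
              length = j - i + 1L, stringsAsFactors = FALSE)
          i <- j + 1L
        } else i <- i + 1L
      }
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Build a single-chromosome plus/minus track pair from per-base vectors.
make_pair <- function(plus, minus = NULL, chrom = "chrI") {
  n <- length(plus)
  if (is.null(minus)) minus <- numeric(n)
  sizes <- setNames(as.integer(n), chrom)
  list(plus = coverage_track(setNames(list(plus), chrom), sizes, "+"),
       minus = coverage_track(setNames(list(minus), chrom), sizes, "-"))
}

# Minimal terminator_annotation for a gene with a known primary tract.
make_anno <- function(gene_id, chrom, strand, gene_start, gene_end,
                      p_start, p_end, spacer = NA_integer_) {
  structure(list(
    gene_id = gene_id,
    gene = list(gene_id = gene_id, chrom = chrom, start = gene_start,
                end = gene_end, strand = strand),
    primary = data.frame(chrom = chrom, start = p_start, end = p_end,
                         strand = strand, length = p_end - p_start,
                         stringsAsFactors = FALSE),
    spacer_bp = spacer, flagged = FALSE, secondary = NULL),
    class = "terminator_annotation")
}

# Exhaustive RT-calling oracle in walk-offset space: enumerate every
# window, mark its bases, take marked runs, close gaps, report the 3'-most
# retained end (0 when nothing is marked).
oracle_rt <- function(v, thr, window_bp = 20L, step_bp = 19L,
                      max_gap_bp = 20L) {
  n <- length(v)
  marked <- rep(FALSE, n)
  offs <- integer()
  off <- 0L
  while (off + window_bp <= n) {
    offs <- c(offs, off)
    off <- off + step_bp
  }
  if (n >= window_bp) offs <- unique(c(offs, n - window_bp))  # flush window
  for (off in offs) {
    if (sum(v[(off + 1L):(off + window_bp)]) > thr)
      marked[(off + 1L):(off + window_bp)] <- TRUE
  }
  if (!any(marked)) return(list(rt_len = 0L, n_fragments = 0L))
  r <- rle(marked)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  frag <- data.frame(start = starts[r$values], end = ends[r$values])
  merged <- frag[1L, ]
  if (nrow(frag) > 1L) for (i in 2L:nrow(frag)) {
    if (frag$start[i] - merged$end[nrow(merged)] - 1L <= max_gap_bp) {
      merged$end[nrow(merged)] <- frag$end[i]
    } else merged <- rbind(merged, frag[i, ])
  }
  list(rt_len = max(merged$end), n_fragments = nrow(merged))
}

# Quick two-condition synthetic dataset for pipeline-level tests.
small_dataset <- function(seed = 42L, n_genes = 12L, ...) {
  args <- utils::modifyList(list(seed = seed, n_genes = n_genes,
                                 initiations_per_gene = 1000,
                                 reads_total = NULL),
                            list(...))
  simulate_dataset(do.call(sim_config, args))
}
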