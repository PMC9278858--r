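#' Terminator annotation
#'
#' Per-gene terminator annotation: the primary terminator is the first T-tract
#' downstream of (or abutting) the gene 3' end in transcription orientation;
#' T-tracts in the window immediately downstream of the primary tract are
#' secondary terminators. Tracts of 4-5 T are "weak", >= 6 T "strong".
#'
#' @name terminators
NULL

# Transcription-orientation coordinate helpers. For a '+' feature the 5' edge
# is `start` and the 3' edge is `end` (half-open); mirrored on '-'.
gene_three_prime <- function(gene) if (gene$strand == "+") gene$end else gene$start
tract_five_edge  <- function(tracts, strand)
  if (strand == "+") tracts$start else tracts$end
tract_three_edge <- function(tracts, strand)
  if (strand == "+") tracts$end else tracts$start

#' Assign the primary terminator of a gene
#'
#' The primary terminator is the same-strand tract with the smallest
#' orientation-aware distance (spacer) from the gene 3' end, searching at most
#' `max_search_bp` downstream. A tract whose 5' edge sits exactly at the 3'
#' end counts with spacer 0. When no tract is found the annotation is
#' returned with `primary = NULL` and `flagged = TRUE` - never dropped.
#'
#' @param gene one-row data frame (`gene_id`, `chrom`, `start`, `end`,
#'   `strand`)
#' @param tracts tract table from [find_t_tracts()]
#' @param max_search_bp search limit downstream of the 3' end (default 1000)
#' @return a `terminator_annotation` list: `gene_id`, `gene`, `primary`
#'   (one-row tract or `NULL`), `spacer_bp` (`NA` when absent), `flagged`,
#'   `secondary` (`NULL` until [annotate_secondary_terminators()])
#' @export
assign_primary_terminator <- function(gene, tracts, max_search_bp = 1000L) {
  gene <- as.list(gene[1, c("gene_id", "chrom", "start", "end", "strand")])
  tp <- gene_three_prime(gene)
  cand <- tracts[tracts$chrom == gene$chrom & tracts$strand == gene$strand, ,
                 drop = FALSE]
  spacer <- if (gene$strand == "+") cand$start - tp else tp - cand$end
  keep <- !is.na(spacer) & spacer >= 0L & spacer <= max_search_bp
  cand <- cand[keep, , drop = FALSE]
  spacer <- spacer[keep]
  anno <- structure(
    list(gene_id = gene$gene_id, gene = gene, primary = NULL,
         spacer_bp = NA_integer_, flagged = TRUE, secondary = NULL),
    class = "terminator_annotation")
  if (nrow(cand) == 0L) return(anno)
  i <- which.min(spacer)  # same-strand maximal tracts cannot tie on distance
  anno$primary <- cand[i, , drop = FALSE]
  anno$spacer_bp <- as.integer(spacer[i])
  anno$flagged <- FALSE
  anno
}

#' Annotate secondary terminators downstream of the primary
#'
#' A same-strand tract is secondary when its 5' edge lies within the
#' `window_bp`-wide half-open window starting at the first base after the
#' primary tract (orientation-aware); this equals the any-overlap rule for
#' tracts strictly downstream of the primary. Results are ordered 5' to 3'
#' in transcription orientation.
#'
#' @param anno a `terminator_annotation` with a primary present
#' @param tracts tract table
#' @param window_bp window width, default 700
#' @return the annotation with `secondary` filled in (possibly zero rows)
#' @export
annotate_secondary_terminators <- function(anno, tracts, window_bp = 700L) {
  if (is.null(anno$primary))
    stop_polterm(
      "gene %s has no primary terminator; call assign_primary_terminator first",
      anno$gene_id)
  strand <- anno$gene$strand
  p3 <- tract_three_edge(anno$primary, strand)
  cand <- tracts[tracts$chrom == anno$gene$chrom & tracts$strand == strand, ,
                 drop = FALSE]
  edge <- tract_five_edge(cand, strand)
  keep <- if (strand == "+") {
    edge >= p3 & edge < p3 + window_bp
  } else {
    edge <= p3 & edge > p3 - window_bp
  }
  sec <- cand[keep, , drop = FALSE]
  ord <- order(if (strand == "+") sec$start else -sec$end)
  anno$secondary <- sec[ord, , drop = FALSE]
  rownames(anno$secondary) <- NULL
  anno
}

#' Classify terminator strength from tract length
#'
#' Tracts of 4 or 5 T are weak terminators; tracts of 6 or more T are strong.
#'
#' @param tract a tract row, a `length` value, or a vector of lengths
#' @return character vector of `"weak"` / `"strong"`
#' @export
classify_terminator <- function(tract) {
  len <- if (is.data.frame(tract)) tract$length else as.integer(tract)
  if (any(len < 4L))
    stop_polterm("tract of length %d is not a terminator (minimum 4)",
                 min(len))
  ifelse(len <= 5L, "weak", "strong")
}

#' Annotate a gene set
#'
#' Convenience wrapper running primary assignment, secondary annotation and
#' strength classification over every gene.
#'
#' @param genes gene table ([read_genes_bed()])
#' @param tracts tract table ([find_t_tracts()])
#' @param max_search_bp see [assign_primary_terminator()]
#' @param window_bp see [annotate_secondary_terminators()]
#' @return a data frame, one row per gene: gene coordinates, primary tract
#'   coordinates and length (`NA` when flagged), `spacer_bp`, `flagged`,
#'   `n_weak_secondary`, `n_strong_secondary`; the per-gene
#'   `terminator_annotation` objects are kept in attribute `"annos"`
#' @export
annotate_terminators <- function(genes, tracts, max_search_bp = 1000L,
                                 window_bp = 700L) {
  annos <- lapply(seq_len(nrow(genes)), function(i) {
    a <- assign_primary_terminator(genes[i, ], tracts, max_search_bp)
    if (!a$flagged) a <- annotate_secondary_terminators(a, tracts, window_bp)
    a
  })
  names(annos) <- genes$gene_id
  rows <- lapply(annos, function(a) {
    has <- !a$flagged
    nsec <- if (has) nrow(a$secondary) else 0L
    cls <- if (nsec > 0L) classify_terminator(a$secondary) else character()
    data.frame(
      gene_id = a$gene_id, chrom = a$gene$chrom, strand = a$gene$strand,
      gene_start = a$gene$start, gene_end = a$gene$end,
      primary_start = if (has) a$primary$start else NA_integer_,
      primary_end = if (has) a$primary$end else NA_integer_,
      primary_len = if (has) a$primary$length else NA_integer_,
      primary_class = if (has) classify_terminator(a$primary) else NA_character_,
      spacer_bp = a$spacer_bp, flagged = a$flagged,
      n_weak_secondary = sum(cls == "weak"),
      n_strong_secondary = sum(cls == "strong"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, annos = annos)
}

#' Spacer statistics over a gene set
#'
#' Counts genes whose spacer (distance from the mature 3' end to the primary
#' terminator) is at most `cutoff_bp`, and returns the full spacer histogram.
#'
#' @param annos annotation table from [annotate_terminators()] or a list of
#'   `terminator_annotation` objects
#' @param cutoff_bp spacer cutoff, default 7
#' @return list: `n_within_cutoff`, `n_with_primary`, `n_genes`, `cutoff_bp`,
#'   `histogram` (table of spacer lengths over genes with a primary)
#' @export
spacer_statistics <- function(annos, cutoff_bp = 7L) {
  spacers <- if (is.data.frame(annos)) {
    if (nrow(annos) == 0L) stop_polterm("spacer_statistics: empty input")
    annos$spacer_bp
  } else {
    if (length(annos) == 0L) stop_polterm("spacer_statistics: empty input")
    vapply(annos, function(a) a$spacer_bp %||% NA_integer_, integer(1))
  }
  present <- spacers[!is.na(spacers)]
  list(
    n_within_cutoff = sum(present <= cutoff_bp),
    n_with_primary = length(present),
    n_genes = length(spacers),
    cutoff_bp = as.integer(cutoff_bp),
    histogram = table(spacer_bp = present)
  )
}

#' Sense/antisense tract counts per region
#'
#' For each stranded region, counts the tracts overlapping it that match
#' (sense) or oppose (antisense) the region's strand.
#'
#' @param regions data frame with `chrom`, `start`, `end`, `strand`
#' @param tracts tract table
#' @return `regions` with `sense` and `antisense` count columns appended
#' @export
tract_orientation_counts <- function(regions, tracts) {
  if (any(regions$start >= regions$end))
    stop_polterm("tract_orientation_counts: zero/negative-width region")
  sense <- integer(nrow(regions))
  anti <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- tracts$chrom == r$chrom & tracts$start < r$end & tracts$end > r$start
    sense[i] <- sum(hit & tracts$strand == r$strand)
    anti[i] <- sum(hit & tracts$strand != r$strand)
  }
  cbind(regions, sense = sense, antisense = anti)
}

#' Write tract and terminator-annotation outputs
#'
#' Tracts go to BED6 (name `T<length>`, score = length); annotations to a TSV
#' with a header line.
#'
#' @param tracts tract table
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tracts_bed <- function(tracts, path) {
  tracts$name <- paste0("T", tracts$length)
  tracts$score <- tracts$length
  write_bed6(tracts, path)
}

#' @rdname write_tracts_bed
#' @param anno_table table from [annotate_terminators()]
#' @export
write_annotation_tsv <- function(anno_table, path) {
  write_tsv(as.data.frame(anno_table), path)
}
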