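#' Genome sequences and gene models
#'
#' A genome is represented as a named character vector of upper-case
#' chromosome sequences over the alphabet {A,C,G,T,N}; gene models are plain
#' data frames in BED convention (0-based, half-open). Both are validated on
#' construction so downstream interval arithmetic can assume invariants.
#'
#' @name genome-io
NULL

#' Construct a validated genome object
#'
#' @param sequences named character vector, one upper-case sequence per
#'   chromosome
#' @return a `polterm_genome`: the validated vector with a `chrom_sizes`
#'   attribute (named integer vector of lengths)
#' @export
genome_sequence <- function(sequences) {
  if (length(sequences) == 0L)
    stop_polterm("genome is empty: at least one chromosome is required")
  nm <- names(sequences)
  if (is.null(nm) || any(!nzchar(nm)))
    stop_polterm("every chromosome must have a nonempty name")
  if (anyDuplicated(nm))
    stop_polterm("duplicated chromosome name: %s", nm[duplicated(nm)][1L])
  sequences <- toupper(sequences)
  for (chrom in nm) {
    bad <- regexpr("[^ACGTN]", sequences[[chrom]])
    if (bad > 0L)
      stop_polterm("non-ACGTN residue '%s' at %s:%d",
                   substr(sequences[[chrom]], bad, bad), chrom, bad)
  }
  structure(sequences, class = "polterm_genome",
            chrom_sizes = setNames(nchar(sequences), nm))
}

#' @export
print.polterm_genome <- function(x, ...) {
  cs <- chrom_sizes(x)
  cat(sprintf("polterm_genome: %d chromosome(s), %s bp total\n",
              length(cs), format(sum(as.numeric(cs)), big.mark = ",")))
  invisible(x)
}

#' Chromosome sizes of a genome or track
#' @param x a `polterm_genome` or `coverage_track`
#' @return named integer vector of chromosome lengths
#' @export
chrom_sizes <- function(x) attr(x, "chrom_sizes")

#' Read a genome from FASTA
#' @param path FASTA file
#' @return a `polterm_genome`
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop_polterm("FASTA not found: %s", path)
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  genome_sequence(seqs)
}

#' Write a genome to FASTA
#' @param genome a `polterm_genome`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read / write chrom.sizes (two-column TSV)
#' @param path file path
#' @return named integer vector
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "size"),
                          stringsAsFactors = FALSE)
  setNames(as.integer(df$size), df$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes named integer vector
#' @export
write_chrom_sizes <- function(sizes, path) {
  utils::write.table(data.frame(names(sizes), unname(sizes)), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Find T-tracts on both strands of a genome
#'
#' Scans every chromosome for maximal runs of consecutive T (reported on the
#' plus strand) and consecutive A (the plus-strand image of a minus-strand
#' T-tract). `N` residues break runs; a tract never spans one. Runs shorter
#' than `min_len` are dropped.
#'
#' @param genome a `polterm_genome` (or named character vector of sequences)
#' @param min_len minimum run length, default 4
#' @return data frame with columns `chrom`, `start`, `end` (0-based,
#'   half-open), `strand` (`+`/`-`), `length`, sorted by (chrom, start)
#' @export
find_t_tracts <- function(genome, min_len = 4L) {
  if (!inherits(genome, "polterm_genome")) genome <- genome_sequence(genome)
  min_len <- as.integer(min_len)
  if (is.na(min_len) || min_len < 1L) stop_polterm("min_len must be >= 1")
  out <- vector("list", 2L * length(genome))
  k <- 0L
  for (chrom in names(chrom_sizes(genome))) {
    chars <- strsplit(unclass(genome)[[chrom]], "", fixed = TRUE)[[1L]]
    for (strand in c("+", "-")) {
      base <- if (strand == "+") "T" else "A"
      r <- rle(chars == base)
      ends <- cumsum(r$lengths)                      # 1-based inclusive ends
      keep <- r$values & r$lengths >= min_len
      if (!any(keep)) next
      k <- k + 1L
      out[[k]] <- data.frame(
        chrom = chrom,
        start = as.integer(ends[keep] - r$lengths[keep]),  # 0-based start
        end   = as.integer(ends[keep]),
        strand = strand,
        length = as.integer(r$lengths[keep]),
        stringsAsFactors = FALSE
      )
    }
  }
  if (k == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out[seq_len(k)])
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read gene models from a BED6 file
#'
#' Score column is ignored; strand is required. Coordinates are kept 0-based
#' half-open. `gene_class` defaults to "tRNA-like" and can be overridden.
#'
#' @param path BED6 file
#' @param gene_class class label for all genes in the file
#' @param chrom_sizes optional named vector used to bounds-check intervals
#' @return data frame (`gene_id`, `chrom`, `start`, `end`, `strand`,
#'   `gene_class`)
#' @export
read_genes_bed <- function(path, gene_class = "tRNA-like", chrom_sizes = NULL) {
  if (!file.exists(path)) stop_polterm("BED not found: %s", path)
  gr <- rtracklayer::import(path, format = "BED")
  df <- granges_to_bed0(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  name <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
  genes <- data.frame(gene_id = name, chrom = df$chrom, start = df$start,
                      end = df$end, strand = strand,
                      gene_class = gene_class, stringsAsFactors = FALSE)
  validate_genes(genes, chrom_sizes)
}

validate_genes <- function(genes, chrom_sizes = NULL) {
  if (anyDuplicated(genes$gene_id))
    stop_polterm("duplicated gene_id: %s",
                 genes$gene_id[duplicated(genes$gene_id)][1L])
  if (any(!genes$strand %in% c("+", "-")))
    stop_polterm("gene strand must be '+' or '-' (gene %s)",
                 genes$gene_id[!genes$strand %in% c("+", "-")][1L])
  bad <- genes$start < 0L | genes$start >= genes$end
  if (any(bad))
    stop_polterm("invalid interval for gene %s", genes$gene_id[bad][1L])
  if (!is.null(chrom_sizes)) {
    unknown <- setdiff(unique(genes$chrom), names(chrom_sizes))
    if (length(unknown))
      stop_polterm("unknown chromosome in gene annotation: %s", unknown[1L])
    over <- genes$end > chrom_sizes[genes$chrom]
    if (any(over))
      stop_polterm("gene %s extends past chromosome end", genes$gene_id[over][1L])
  }
  genes
}

#' Write intervals as BED6
#'
#' @param df data frame with `chrom`, `start`, `end`, `strand` and optional
#'   `name`/`score` columns (0-based half-open)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_bed6 <- function(df, path) {
  bed <- data.frame(
    chrom = df$chrom, start = df$start, end = df$end,
    name = if (!is.null(df$name)) df$name else ".",
    score = if (!is.null(df$score)) df$score else 0,
    strand = df$strand, stringsAsFactors = FALSE
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
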