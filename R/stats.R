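#' Termination statistics
#'
#' Per-gene termination efficiency is summarized by the RT index: the signal
#' over the called read-through region as a percentage of the signal over
#' the gene region (5' end through the 3' edge of the primary tract). Genes
#' are ranked by the mean log2 fold change of mutant over wild-type signal
#' downstream of the primary terminator (the mutant-dependency score),
#' quartiled (Q1 = most impaired), and compared with rank-based tests.
#'
#' @name termination-stats
NULL

# Gene region in transcription orientation: 5' end through the primary
# tract 3' edge, as genome coordinates (0-based half-open).
gene_region <- function(anno_row) {
  if (anno_row$strand == "+") c(anno_row$gene_start, anno_row$primary_end)
  else c(anno_row$primary_start, anno_row$gene_end)
}

#' Per-gene termination summary (RT index)
#'
#' @param pair plus/minus `coverage_track` pair for one condition
#' @param anno_table table from [annotate_terminators()]
#' @param rt_table matching [call_rt_regions()] result
#' @param condition condition label stored in the output
#' @return data frame, one row per gene with a primary terminator:
#'   `gene_id`, `condition`, `gene_body_signal`, `rt_signal`, `rt_index`
#'   (percent; `NA` and flagged when the body signal is 0), `rt_length_bp`,
#'   `primary_tract_len`, `n_weak_secondary`, `n_strong_secondary`.
#'   Attribute `"n_zero_body"` counts flagged genes.
#' @export
termination_summary <- function(pair, anno_table, rt_table, condition = "WT") {
  at <- as.data.frame(anno_table)[!anno_table$flagged, , drop = FALSE]
  rt <- rt_table[match(at$gene_id, rt_table$gene_id), , drop = FALSE]
  body <- numeric(nrow(at))
  rts <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    g <- at[i, ]
    reg <- gene_region(g)
    track <- strand_track(pair, g$strand)
    body[i] <- region_signal(track, g$chrom, reg[1L], reg[2L])$total
    rts[i] <- if (rt$empty[i]) 0 else
      region_signal(track, g$chrom, rt$start[i], rt$end[i])$total
  }
  idx <- ifelse(body > 0, 100 * rts / body, NA_real_)
  out <- data.frame(
    gene_id = at$gene_id, condition = condition,
    gene_body_signal = body, rt_signal = rts, rt_index = idx,
    rt_length_bp = rt$rt_length_bp, primary_tract_len = at$primary_len,
    n_weak_secondary = at$n_weak_secondary,
    n_strong_secondary = at$n_strong_secondary,
    stringsAsFactors = FALSE)
  structure(out, n_zero_body = sum(body == 0))
}

#' Fixed-window RT index variant
#'
#' Sensitivity-check companion to [termination_summary()]: instead of the
#' called RT region, the numerator is the signal over a fixed window
#' immediately downstream of the primary tract (default 700 bp), so the
#' ratio does not depend on the threshold or the caller. Useful to verify
#' that conclusions are robust to the region-calling step.
#'
#' @param pair plus/minus track pair
#' @param anno_table annotation table
#' @param window_bp fixed downstream window, default 700
#' @return data frame: `gene_id`, `gene_body_signal`, `downstream_signal`,
#'   `rt_index_fixed` (percent, `NA` when the body signal is 0)
#' @export
rt_index_fixed_window <- function(pair, anno_table, window_bp = 700L) {
  at <- as.data.frame(anno_table)[!anno_table$flagged, , drop = FALSE]
  sizes <- chrom_sizes(pair$plus)
  body <- numeric(nrow(at))
  down <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    g <- at[i, ]
    reg <- gene_region(g)
    track <- strand_track(pair, g$strand)
    body[i] <- region_signal(track, g$chrom, reg[1L], reg[2L])$total
    if (g$strand == "+") {
      a <- g$primary_end
      b <- min(sizes[[g$chrom]], a + window_bp)
    } else {
      b <- g$primary_start
      a <- max(0L, b - window_bp)
    }
    down[i] <- region_signal(track, g$chrom, a, b)$total
  }
  data.frame(gene_id = at$gene_id, gene_body_signal = body,
             downstream_signal = down,
             rt_index_fixed = ifelse(body > 0, 100 * down / body, NA_real_),
             stringsAsFactors = FALSE)
}

#' Estimate per-gene read-through fraction at the primary terminator
#'
#' The fraction of polymerases escaping primary termination is estimated as
#' the ratio of mean per-base signal in a short window immediately
#' downstream of the primary tract to that in a window immediately upstream
#' of it. With single-base occupancy tracks and uniform dwell away from
#' pauses, both window means are proportional to the polymerase flux, so the
#' ratio estimates the survival probability through the tract. Class-level
#' estimates should pool genes with the ratio of summed signals
#' (`down_total` / `up_total`), which is robust at low per-gene counts.
#'
#' @param pair plus/minus track pair
#' @param anno_table annotation table
#' @param window_bp width of the upstream and downstream windows, default 10
#' @return data frame: `gene_id`, `primary_tract_len`, `up_total`,
#'   `down_total`, `readthrough_hat` (per-gene ratio; `NA` when the
#'   upstream window is empty)
#' @export
estimate_readthrough <- function(pair, anno_table, window_bp = 10L) {
  at <- as.data.frame(anno_table)[!anno_table$flagged, , drop = FALSE]
  up <- numeric(nrow(at))
  down <- numeric(nrow(at))
  for (i in seq_len(nrow(at))) {
    g <- at[i, ]
    track <- strand_track(pair, g$strand)
    if (g$strand == "+") {
      up[i] <- region_signal(track, g$chrom, g$primary_start - window_bp,
                             g$primary_start)$total
      down[i] <- region_signal(track, g$chrom, g$primary_end,
                               g$primary_end + window_bp)$total
    } else {
      up[i] <- region_signal(track, g$chrom, g$primary_end,
                             g$primary_end + window_bp)$total
      down[i] <- region_signal(track, g$chrom, g$primary_start - window_bp,
                               g$primary_start)$total
    }
  }
  data.frame(gene_id = at$gene_id, primary_tract_len = at$primary_len,
             up_total = up, down_total = down,
             readthrough_hat = ifelse(up > 0, down / up, NA_real_),
             stringsAsFactors = FALSE)
}

#' Per-base log2 fold-change track
#'
#' `log2((mutant + pseudocount) / (wt + pseudocount))` per base; with equal
#' tracks (including both zero) the result is 0 everywhere.
#'
#' @param mut_track,wt_track same-strand `coverage_track`s
#' @param pseudocount nonnegative pseudocount, default 1 (CPM units)
#' @return an `fc_track`: per-chromosome numeric vectors (may be negative)
#'   with `strand` and `chrom_sizes` attributes
#' @export
log2_fold_change_track <- function(mut_track, wt_track, pseudocount = 1) {
  if (pseudocount < 0) stop_polterm("pseudocount must be >= 0")
  if (mut_track$strand != wt_track$strand)
    stop_polterm("fold change requires same-strand tracks")
  sizes <- chrom_sizes(mut_track)
  values <- lapply(names(sizes), function(chrom)
    log2((mut_track$values[[chrom]] + pseudocount) /
         (wt_track$values[[chrom]] + pseudocount)))
  names(values) <- names(sizes)
  structure(list(values = values, strand = mut_track$strand),
            chrom_sizes = sizes, class = "fc_track")
}

#' @rdname log2_fold_change_track
#' @param mut_pair,wt_pair plus/minus pairs
#' @return for the pair version, a list of two `fc_track`s (`plus`, `minus`)
#' @export
log2_fold_change_pair <- function(mut_pair, wt_pair, pseudocount = 1) {
  list(plus = log2_fold_change_track(mut_pair$plus, wt_pair$plus, pseudocount),
       minus = log2_fold_change_track(mut_pair$minus, wt_pair$minus, pseudocount))
}

# Mean of a per-base step function over real interval [a, b) in index space
# (0-based); used for fractional-width bins. `cums` = c(0, cumsum(v)).
step_integral <- function(cums, v, x) {
  i <- pmin(floor(x), length(v))
  cums[i + 1L] + (x - i) * c(v, 0)[i + 1L]
}

#' Rebin a per-base vector into equal fractional-width bins
#'
#' @param v numeric vector (per-base values, 5' to 3')
#' @param nbins number of bins; bins may be fractional-width when
#'   `length(v)` is not a multiple (edge bases are weighted by overlap)
#' @return numeric vector of per-bin mean per-base values
#' @export
rebin_mean <- function(v, nbins) {
  L <- length(v)
  edges <- seq(0, L, length.out = nbins + 1L)
  cums <- c(0, cumsum(v))
  ints <- step_integral(cums, v, edges)
  diff(ints) / diff(edges)
}

# Per-base values over the gene region plus flanks, 5' to 3' in
# transcription orientation; positions beyond the chromosome are NA.
oriented_values <- function(track_values, clen, start, end, strand) {
  idx <- seq.int(start, end - 1L)
  v <- rep(NA_real_, length(idx))
  ok <- idx >= 0L & idx < clen
  v[ok] <- track_values[idx[ok] + 1L]
  if (strand == "-") rev(v) else v
}

#' Metagene matrix over scaled gene regions
#'
#' For each gene with a primary terminator, the region from the gene 5' end
#' to the 3' edge of the primary tract is scaled to `body_bins` bins (per-bin
#' mean per-base signal, fractional base weighting at bin edges); optional
#' fixed-width flank bins are added on each side. Minus-strand genes are
#' mirrored so column 1 is always 5'.
#'
#' @param pair plus/minus track pair, or a `log2_fold_change_pair()` result
#' @param anno_table annotation table
#' @param body_bins number of scaled gene-body bins, default 100
#' @param flank_bp flank width on each side, default 0 (no flanks)
#' @param flank_bin_bp width of fixed flank bins, default 10
#' @return genes x bins numeric matrix (rownames = gene ids) with
#'   attributes `"summary"` (column means over genes, `NA` removed) and
#'   `"bin_labels"`
#' @export
metagene_matrix <- function(pair, anno_table, body_bins = 100L,
                            flank_bp = 0L, flank_bin_bp = 10L) {
  at <- as.data.frame(anno_table)[!anno_table$flagged, , drop = FALSE]
  if (nrow(at) == 0L) stop_polterm("no genes with a primary terminator")
  n_flank <- if (flank_bp > 0L) flank_bp %/% flank_bin_bp else 0L
  flank_bp <- n_flank * flank_bin_bp
  ncol_out <- body_bins + 2L * n_flank
  m <- matrix(NA_real_, nrow(at), ncol_out, dimnames = list(at$gene_id, NULL))
  sizes <- chrom_sizes(if (!is.null(pair$plus)) pair$plus else pair)
  for (i in seq_len(nrow(at))) {
    g <- at[i, ]
    reg <- gene_region(g)
    track <- strand_track(pair, g$strand)
    v <- oriented_values(track$values[[g$chrom]], sizes[[g$chrom]],
                         reg[1L] - flank_bp, reg[2L] + flank_bp, g$strand)
    body <- v[(flank_bp + 1L):(length(v) - flank_bp)]
    row <- rebin_mean(body, body_bins)
    if (n_flank > 0L) {
      upf <- colMeans(matrix(v[seq_len(flank_bp)], flank_bin_bp))
      dnf <- colMeans(matrix(v[(length(v) - flank_bp + 1L):length(v)],
                             flank_bin_bp))
      row <- c(upf, row, dnf)
    }
    m[i, ] <- row
  }
  labels <- c(if (n_flank) paste0("up", seq_len(n_flank)),
              paste0("body", seq_len(body_bins)),
              if (n_flank) paste0("down", seq_len(n_flank)))
  colnames(m) <- labels
  structure(m, summary = colMeans(m, na.rm = TRUE), bin_labels = labels)
}

#' Heatmap matrix of log2 fold change around genes
#'
#' [metagene_matrix()] computed on a fold-change track pair, with rows
#' ordered by descending row mean; the ordering is kept in attribute
#' `"ordering"` for reuse.
#'
#' @param fc_pair result of [log2_fold_change_pair()]
#' @param anno_table annotation table
#' @param ... passed to [metagene_matrix()]
#' @return ordered matrix with attributes `"ordering"` (gene ids, most
#'   increased first) and `"row_mean"`
#' @export
heatmap_matrix <- function(fc_pair, anno_table, ...) {
  m <- metagene_matrix(fc_pair, anno_table, ...)
  rm_ <- rowMeans(m, na.rm = TRUE)
  ord <- order(-rm_, rownames(m))
  out <- m[ord, , drop = FALSE]
  structure(out, ordering = rownames(m)[ord], row_mean = rm_[ord],
            summary = NULL, bin_labels = attr(m, "bin_labels"))
}

#' Rank genes by mutant dependency and assign quartiles
#'
#' The dependency score of a gene is the mean per-base log2 fold change
#' (mutant / wild type) over the window immediately downstream of the
#' primary tract. Genes are ranked by descending score (ties broken by
#' gene id) and split into quartiles by rank; Q1 holds the 25% of genes
#' with the strongest mutant accumulation (most termination impairment).
#'
#' @param fc_pair result of [log2_fold_change_pair()]
#' @param anno_table annotation table
#' @param downstream_window_bp scoring window, default 700
#' @return data frame: `gene_id`, `dependency_score`, `rank`, `quartile`
#'   (factor Q1-Q4)
#' @export
rank_by_dependency <- function(fc_pair, anno_table,
                               downstream_window_bp = 700L) {
  at <- as.data.frame(anno_table)[!anno_table$flagged, , drop = FALSE]
  if (nrow(at) < 4L) stop_polterm("need >= 4 genes to form quartiles")
  sizes <- chrom_sizes(fc_pair$plus)
  score <- vapply(seq_len(nrow(at)), function(i) {
    g <- at[i, ]
    tr <- strand_track(fc_pair, g$strand)
    if (g$strand == "+") {
      a <- g$primary_end
      b <- min(sizes[[g$chrom]], a + downstream_window_bp)
    } else {
      b <- g$primary_start
      a <- max(0L, b - downstream_window_bp)
    }
    mean(tr$values[[g$chrom]][(a + 1L):b])
  }, numeric(1))
  ord <- order(-score, at$gene_id)
  rank <- integer(nrow(at))
  rank[ord] <- seq_len(nrow(at))
  quart <- factor(paste0("Q", ceiling(4 * rank / nrow(at))),
                  levels = paste0("Q", 1:4))
  data.frame(gene_id = at$gene_id, dependency_score = score, rank = rank,
             quartile = quart, stringsAsFactors = FALSE)
}

#' Mean secondary-terminator counts per dependency quartile
#'
#' @param quartiles result of [rank_by_dependency()]
#' @param anno_table annotation table
#' @return data frame: `quartile`, `kind` (weak/strong), `mean`, `se`
#'   (`NA` flagged for single-gene quartiles), `n`
#' @export
terminators_per_quartile <- function(quartiles, anno_table) {
  at <- as.data.frame(anno_table)
  merged <- merge(quartiles, at[, c("gene_id", "n_weak_secondary",
                                    "n_strong_secondary")], by = "gene_id")
  out <- do.call(rbind, lapply(levels(merged$quartile), function(q) {
    sub <- merged[merged$quartile == q, , drop = FALSE]
    if (nrow(sub) == 0L) stop_polterm("empty quartile %s", q)
    do.call(rbind, lapply(c(weak = "n_weak_secondary",
                            strong = "n_strong_secondary"), function(col) {
      data.frame(quartile = q,
                 kind = if (col == "n_weak_secondary") "weak" else "strong",
                 mean = mean(sub[[col]]), se = std_error(sub[[col]]),
                 n = nrow(sub), stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Omnibus and pairwise group comparisons
#'
#' Kruskal-Wallis across the groups plus two-sided Mann-Whitney rank-sum
#' tests for every group pair. Raw p-values by default (the displayed
#' convention for starred pairwise panels); Benjamini-Hochberg adjustment
#' available via `adjust = "BH"`.
#'
#' @param values numeric vector of observations
#' @param groups group labels (coerced to factor), same length
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method for the
#'   pairwise p-values
#' @return list: `kruskal` (`statistic`, `p_value`, `df`, `defined`),
#'   `pairwise` data frame (`group_a`, `group_b`, `statistic`, `p_value`)
#' @export
group_tests <- function(values, groups, adjust = "none") {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop_polterm("need >= 2 groups")
  if (any(tabulate(groups) == 0L)) stop_polterm("empty group")
  if (length(unique(values)) == 1L) {
    kw <- list(statistic = NA_real_, p_value = NA_real_,
               df = nlevels(groups) - 1L, defined = FALSE)
  } else {
    k <- stats::kruskal.test(values, groups)
    kw <- list(statistic = unname(k$statistic), p_value = k$p.value,
               df = unname(k$parameter), defined = TRUE)
  }
  combs <- utils::combn(levels(groups), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(combs)), function(j) {
    a <- values[groups == combs[1L, j]]
    b <- values[groups == combs[2L, j]]
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    data.frame(group_a = combs[1L, j], group_b = combs[2L, j],
               statistic = unname(w$statistic), p_value = w$p.value,
               stringsAsFactors = FALSE)
  }))
  if (adjust != "none") pw$p_value <- stats::p.adjust(pw$p_value, adjust)
  list(kruskal = kw, pairwise = pw)
}

#' Paired Wilcoxon signed-rank test for per-gene condition comparisons
#'
#' @param x,y paired numeric vectors (e.g. WT and mutant RT index per gene)
#' @return list: `statistic`, `p_value`, `n`, `defined` (`FALSE` when every
#'   pairwise difference is 0)
#' @export
paired_wilcoxon <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  d <- x[ok] - y[ok]
  if (all(d == 0))
    return(list(statistic = NA_real_, p_value = NA_real_, n = sum(ok),
                defined = FALSE))
  w <- suppressWarnings(stats::wilcox.test(x[ok], y[ok], paired = TRUE,
                                           exact = FALSE))
  list(statistic = unname(w$statistic), p_value = w$p.value, n = sum(ok),
       defined = TRUE)
}

#' Mean RT index per primary-tract-length class
#'
#' @param summaries result of [termination_summary()]
#' @param pool_from tract lengths at or above this value are pooled into one
#'   class (default 8); use `Inf` to keep every length separate
#' @return data frame: `tract_len_class`, `mean_rt_index`, `se`, `n`,
#'   ordered by increasing length (pooled class last)
#' @export
cluster_by_terminator_length <- function(summaries, pool_from = 8L) {
  s <- summaries[is.finite(summaries$rt_index), , drop = FALSE]
  cls <- ifelse(s$primary_tract_len >= pool_from,
                paste0(">=", pool_from), as.character(s$primary_tract_len))
  lv <- unique(cls[order(s$primary_tract_len)])
  out <- do.call(rbind, lapply(lv, function(l) {
    v <- s$rt_index[cls == l]
    data.frame(tract_len_class = l, mean_rt_index = mean(v),
               se = std_error(v), n = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pearson correlation of a metric between conditions
#'
#' @param summary_a,summary_b [termination_summary()] results for the two
#'   conditions, paired by `gene_id`
#' @param metric `"rt_index"` or `"rt_length_bp"`
#' @return list: `r`, `p_value`, `n`, `defined`, `pairs` data frame
#' @export
correlate_conditions <- function(summary_a, summary_b,
                                 metric = c("rt_index", "rt_length_bp")) {
  metric <- match.arg(metric)
  m <- merge(summary_a[, c("gene_id", metric)],
             summary_b[, c("gene_id", metric)],
             by = "gene_id", suffixes = c("_a", "_b"))
  a <- m[[paste0(metric, "_a")]]
  b <- m[[paste0(metric, "_b")]]
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = sum(ok),
                defined = FALSE, pairs = m[ok, , drop = FALSE]))
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = sum(ok),
       defined = TRUE, pairs = m[ok, , drop = FALSE])
}
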