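#' Synthetic termination data
#'
#' Generates a synthetic genome carrying tRNA-like genes with designed
#' terminators, and simulates condition-dependent RNAPIII occupancy with
#' known ground truth. Each initiated polymerase walks 5' to 3'; at the 3'
#' edge of every T-tract it releases with a probability that increases with
#' tract length (no release at T4, intermediate at T5, efficient at T6 and
#' above, after the in vitro behaviour of these terminators), and at
#' downstream pause sites it releases with a condition-dependent fail-safe
#' probability (high in "WT", low in the termination-deficient "mutant").
#' Occupancy at a base is the summed dwell of all polymerases over it, so
#' paused positions accumulate signal as in nascent-transcript 3'-end maps.
#'
#' @name synthetic-data
NULL

#' Simulation configuration
#'
#' Defaults state the simulated world: ~100-bp genes, spacers mostly at most
#' 7 bp, primary tracts of 4-12 T with release probability rising steeply
#' between lengths 4 and 6, a strong fail-safe release in WT
#' (`p_failsafe_WT = 0.5` per pause site) that the mutant lacks
#' (`p_failsafe_mut = 0.05`), sparse downstream pause sites, and a low
#' uniform Poisson background.
#'
#' @param seed integer seed; identical seed + config give bit-identical
#'   output
#' @param n_genes number of tRNA-like genes
#' @param gene_length_range min/max gene length (bp)
#' @param spacer_probs probabilities of spacers 0..10 bp
#' @param primary_len_probs probabilities of primary tract lengths 4..12
#' @param weak_secondary_range,strong_secondary_range min/max counts of
#'   weak (T4-T5) and strong (T6-T8) secondary tracts per gene; overridden
#'   by `n_weak_secondary` / `n_strong_secondary` per-gene vectors if given
#' @param n_weak_secondary,n_strong_secondary optional explicit per-gene
#'   secondary-tract counts (recycled to `n_genes`)
#' @param primary_len optional explicit per-gene primary tract length
#' @param p_term named release probabilities per tract length (names
#'   "4".."12"; lengths beyond the map use the last value)
#' @param p_failsafe_WT,p_failsafe_mut fail-safe release probability per
#'   downstream pause site in each condition
#' @param pause_site_rate per-bp probability of a pause site in the 1-kb
#'   downstream window
#' @param dwell_pause relative dwell at pause sites and tract 3' edges
#'   (ordinary bases dwell 1)
#' @param p_stall stall-without-release probability at the proximal part of
#'   long tracts (length >= `stall_min_len`); 0 (off) by default
#' @param stall_min_len minimum tract length for stalling, default 9
#' @param initiations_per_gene Poisson mean of initiation events per gene
#'   (exact count when `initiations_fixed = TRUE`)
#' @param initiations_fixed use exactly `initiations_per_gene` polymerases
#' @param reads_total reads sampled multinomially from the occupancy
#'   distribution; `NULL` emits raw occupancy (no resampling)
#' @param background_noise_rate per-base Poisson mean of background counts
#' @param coding_background_rate per-base Poisson mean of additional
#'   RNAPII-associated background over coding-gene bodies (strand-matched).
#'   Coding genes are the thresholding substrate because their background
#'   sits above ambient noise; default 5x the ambient rate
#' @param strand_balance alternate genes between strands (half on each)
#' @param n_coding,coding_length protein-coding background genes emitted for
#'   threshold estimation (they carry background noise only)
#' @param span_bp downstream window length simulated past the primary tract
#' @return a `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 50L,
                       gene_length_range = c(70L, 120L),
                       spacer_probs = c(8, 10, 12, 12, 10, 8, 6, 5, 1.5, 1, 0.5),
                       primary_len_probs = c(0.15, 0.25, 0.25, 0.15, 0.08,
                                             0.05, 0.04, 0.02, 0.01),
                       weak_secondary_range = c(0L, 3L),
                       strong_secondary_range = c(0L, 2L),
                       n_weak_secondary = NULL,
                       n_strong_secondary = NULL,
                       primary_len = NULL,
                       p_term = c(`4` = 0.05, `5` = 0.5, `6` = 0.9,
                                  `7` = 0.92, `8` = 0.94, `9` = 0.95,
                                  `10` = 0.96, `11` = 0.97, `12` = 0.98),
                       p_failsafe_WT = 0.5,
                       p_failsafe_mut = 0.05,
                       pause_site_rate = 0.02,
                       dwell_pause = 5,
                       p_stall = 0,
                       stall_min_len = 9L,
                       initiations_per_gene = 1000,
                       initiations_fixed = FALSE,
                       reads_total = 2e6,
                       background_noise_rate = 0.05,
                       coding_background_rate = 0.25,
                       strand_balance = TRUE,
                       n_coding = 20L,
                       coding_length = 2000L,
                       span_bp = 1000L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              gene_length_range = gene_length_range,
              spacer_probs = spacer_probs / sum(spacer_probs),
              primary_len_probs = primary_len_probs / sum(primary_len_probs),
              weak_secondary_range = weak_secondary_range,
              strong_secondary_range = strong_secondary_range,
              n_weak_secondary = n_weak_secondary,
              n_strong_secondary = n_strong_secondary,
              primary_len = primary_len,
              p_term = p_term, p_failsafe_WT = p_failsafe_WT,
              p_failsafe_mut = p_failsafe_mut,
              pause_site_rate = pause_site_rate, dwell_pause = dwell_pause,
              p_stall = p_stall, stall_min_len = as.integer(stall_min_len),
              initiations_per_gene = initiations_per_gene,
              initiations_fixed = initiations_fixed,
              reads_total = reads_total,
              background_noise_rate = background_noise_rate,
              coding_background_rate = coding_background_rate,
              strand_balance = strand_balance,
              n_coding = as.integer(n_coding),
              coding_length = as.integer(coding_length),
              span_bp = as.integer(span_bp))
  probs <- c(cfg$p_term, cfg$p_failsafe_WT, cfg$p_failsafe_mut,
             cfg$pause_site_rate, cfg$p_stall)
  if (any(probs < 0 | probs > 1))
    stop_polterm("all probabilities must lie in [0,1]")
  if (any(diff(cfg$p_term) < 0))
    stop_polterm("default-profile contract: p_term must be non-decreasing in tract length")
  structure(cfg, class = "sim_config")
}

p_term_of <- function(cfg, len) {
  nm <- as.character(len)
  known <- names(cfg$p_term)
  unname(ifelse(nm %in% known, cfg$p_term[nm],
                cfg$p_term[length(cfg$p_term)]))
}

# Tract-free random background: sample bases, then break every run of >= 4
# T (or A) by substitution at every 4th run position. Substitution with C/G
# cannot create new T/A runs.
random_tractfree_seq <- function(n) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  for (base in c("T", "A")) {
    r <- rle(s == base)
    long <- which(r$values & r$lengths >= 4L)
    if (!length(long)) next
    ends <- cumsum(r$lengths)
    for (i in long) {
      start <- ends[i] - r$lengths[i] + 1L
      fix <- seq.int(start + 3L, ends[i], by = 4L)
      s[fix] <- if (base == "T") "C" else "G"
    }
  }
  s
}

#' Generate a synthetic genome with designed terminators
#'
#' Background sequence is generated free of any T/A run of length >= 4, then
#' the designed tracts are written in, so scanning the emitted genome
#' recovers exactly the designed terminators around each gene. Genes are
#' laid out sequentially, each in a slot with a 600-bp upstream flank and a
#' clear `span_bp` downstream window; minus-strand genes are mirrored within
#' their slot. Protein-coding background genes are placed on a second
#' chromosome and receive no polymerase signal, only noise. Pause-site
#' positions are drawn here so both conditions share them.
#'
#' @param config a [sim_config()]
#' @return a `sim_genome` list: `genome` (a `polterm_genome`), `genes`,
#'   `coding_genes`, `tracts` (designed tracts with `gene_id` and `role`),
#'   `truth` (per gene: tract design, spacer, read-through fraction
#'   `1 - p_term(primary length)`), `pause_sites` (per-gene offsets from the
#'   primary tract 3' edge), `config`
#' @export
simulate_genome <- function(config) {
  cfg <- config
  set.seed(cfg$seed)
  n <- cfg$n_genes
  glen <- sample(cfg$gene_length_range[1L]:cfg$gene_length_range[2L], n,
                 replace = TRUE)
  spacer <- sample(0:10, n, replace = TRUE, prob = cfg$spacer_probs)
  plen <- if (!is.null(cfg$primary_len)) rep_len(cfg$primary_len, n)
          else sample(4:12, n, replace = TRUE, prob = cfg$primary_len_probs)
  nweak <- if (!is.null(cfg$n_weak_secondary))
    rep_len(cfg$n_weak_secondary, n)
  else sample(cfg$weak_secondary_range[1L]:cfg$weak_secondary_range[2L], n,
              replace = TRUE)
  nstrong <- if (!is.null(cfg$n_strong_secondary))
    rep_len(cfg$n_strong_secondary, n)
  else sample(cfg$strong_secondary_range[1L]:cfg$strong_secondary_range[2L],
              n, replace = TRUE)
  strand <- if (cfg$strand_balance) rep_len(c("+", "-"), n)
            else rep("+", n)

  up_flank <- 600L
  down_clear <- cfg$span_bp + 200L
  slot <- up_flank + glen + spacer + plen + down_clear
  slot_start <- cumsum(c(0L, head(slot, -1L)))
  total <- sum(slot)
  seq_chars <- random_tractfree_seq(total)

  genes <- vector("list", n)
  tracts <- vector("list", n)
  pause_sites <- vector("list", n)
  for (i in seq_len(n)) {
    s0 <- slot_start[i]
    # forward-frame layout within the slot; mirrored for '-' genes
    fw_gene <- c(up_flank, up_flank + glen[i])
    fw_primary <- c(fw_gene[2L] + spacer[i], fw_gene[2L] + spacer[i] + plen[i])
    # secondary tracts: random non-overlapping starts in the 700-bp window
    sec_len <- c(if (nweak[i] > 0L) sample(4:5, nweak[i], replace = TRUE),
                 if (nstrong[i] > 0L) sample(6:8, nstrong[i], replace = TRUE))
    n_sec <- length(sec_len)
    sec_off <- integer(0)
    if (n_sec > 0L) {
      # slots of 30 bp keep tracts separated and maximal
      cand <- sample(seq.int(20L, 680L, by = 30L), n_sec)
      ord <- order(cand)
      sec_off <- cand[ord]
      sec_len <- sec_len[ord]
    }
    fw_sec_start <- fw_primary[2L] + sec_off
    n_pause <- stats::rbinom(1L, cfg$span_bp, cfg$pause_site_rate)
    pw <- sort(sample.int(cfg$span_bp, n_pause))  # offsets 1..span past tract
    pause_sites[[i]] <- pw

    tr <- data.frame(
      role = c("primary", rep("secondary", n_sec)),
      fw_start = c(fw_primary[1L], fw_sec_start),
      length = c(plen[i], sec_len), stringsAsFactors = FALSE)

    if (strand[i] == "+") {
      tr$start <- s0 + tr$fw_start
      gene_start <- s0 + fw_gene[1L]
      gene_end <- s0 + fw_gene[2L]
      base <- "T"
    } else {
      # mirror: forward-frame position x maps to slot end - x
      tr$start <- s0 + slot[i] - (tr$fw_start + tr$length)
      gene_start <- s0 + slot[i] - fw_gene[2L]
      gene_end <- s0 + slot[i] - fw_gene[1L]
      base <- "A"
    }
    for (j in seq_len(nrow(tr))) {
      seq_chars[(tr$start[j] + 1L):(tr$start[j] + tr$length[j])] <- base
      # clear one flanking base so the written tract stays maximal at its
      # designed length (background T/A runs of 1-3 could otherwise extend it)
      flank <- c(tr$start[j], tr$start[j] + tr$length[j] + 1L)
      flank <- flank[flank >= 1L & flank <= total]
      seq_chars[flank] <- "C"
    }
    gid <- sprintf("tQ%03d", i)
    genes[[i]] <- data.frame(gene_id = gid, chrom = "chrSim",
                             start = gene_start, end = gene_end,
                             strand = strand[i], gene_class = "tRNA-like",
                             stringsAsFactors = FALSE)
    tracts[[i]] <- data.frame(gene_id = gid, chrom = "chrSim",
                              start = tr$start, end = tr$start + tr$length,
                              strand = strand[i], length = tr$length,
                              role = tr$role, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  tracts <- do.call(rbind, tracts)

  bg_len <- cfg$n_coding * (cfg$coding_length + 100L) + 100L
  coding <- data.frame(
    gene_id = sprintf("cds%03d", seq_len(cfg$n_coding)),
    chrom = "chrBg",
    start = 100L + (seq_len(cfg$n_coding) - 1L) * (cfg$coding_length + 100L),
    strand = rep_len(c("+", "-"), cfg$n_coding),
    gene_class = "coding", stringsAsFactors = FALSE)
  coding$end <- coding$start + cfg$coding_length
  coding <- coding[, c("gene_id", "chrom", "start", "end", "strand",
                       "gene_class")]

  genome <- genome_sequence(c(
    chrSim = paste(seq_chars, collapse = ""),
    chrBg = paste(random_tractfree_seq(bg_len), collapse = "")))

  truth <- data.frame(
    gene_id = genes$gene_id, strand = genes$strand,
    gene_length = glen, spacer_bp = spacer, primary_len = plen,
    n_weak_secondary = nweak, n_strong_secondary = nstrong,
    readthrough_fraction = 1 - p_term_of(cfg, plen),
    n_pause_sites = lengths(pause_sites), stringsAsFactors = FALSE)

  structure(list(genome = genome, genes = genes, coding_genes = coding,
                 tracts = tracts, truth = truth, pause_sites = pause_sites,
                 config = cfg),
            class = "sim_genome")
}

# One gene's polymerase walk, vectorized over polymerases. Returns the
# occupancy vector over the walk (5'->3' from the gene start through
# span_bp past the primary tract 3' edge) and the release accounting.
walk_gene <- function(gene_tracts, gene_len, spacer, pause_off, cfg,
                      p_failsafe, n_init) {
  plen <- gene_tracts$length[gene_tracts$role == "primary"]
  walk_len <- gene_len + spacer + plen + cfg$span_bp
  p3_off <- gene_len + spacer + plen          # last base of the primary tract
  # release events in walk offset space (1-based base index within the walk):
  # primary tract 3' edge, secondary tract 3' edges (precomputed by the
  # caller as attr "sec_fw_end"), and fail-safe pause sites
  tract_edges <- c(p3_off, attr(gene_tracts, "sec_fw_end"))
  ev <- data.frame(pos = tract_edges, p = p_term_of(cfg, gene_tracts$length))
  if (length(pause_off))
    ev <- rbind(ev, data.frame(pos = p3_off + pause_off, p = p_failsafe))
  ev <- ev[ev$pos <= walk_len, , drop = FALSE]
  ev <- ev[order(ev$pos), , drop = FALSE]

  dwell <- rep(1, walk_len)
  dwell[ev$pos] <- cfg$dwell_pause

  # stall-without-release at the proximal part of long tracts (optional)
  stalled <- 0L
  n <- n_init
  occ <- numeric(walk_len)
  if (cfg$p_stall > 0 && plen >= cfg$stall_min_len) {
    st <- stats::rbinom(1L, n, cfg$p_stall)
    stalled <- st
    occ[gene_len + spacer + 1L] <- occ[gene_len + spacer + 1L] +
      st * cfg$dwell_pause
    n <- n - st
  }
  released <- 0L
  seg_start <- 1L
  for (k in seq_len(nrow(ev))) {
    pos <- ev$pos[k]
    occ[seg_start:pos] <- occ[seg_start:pos] + n * dwell[seg_start:pos]
    rel <- stats::rbinom(1L, n, ev$p[k])
    released <- released + rel
    n <- n - rel
    seg_start <- pos + 1L
    if (n == 0L) break
  }
  if (n > 0L && seg_start <= walk_len)
    occ[seg_start:walk_len] <- occ[seg_start:walk_len] + n * dwell[seg_start:walk_len]
  list(occ = occ, released = released, runoff = n, stalled = stalled,
       n_init = n_init)
}

#' Simulate condition-dependent polymerase occupancy
#'
#' Walks `initiations_per_gene` polymerases (Poisson, or exact with
#' `initiations_fixed`) through every gene. Releases are Bernoulli at tract
#' 3' edges (`p_term` by tract length, both conditions) and at pause sites
#' (`p_failsafe_WT` or `p_failsafe_mut`). Dwell is 1 at ordinary bases and
#' `dwell_pause` at pause sites and tract 3' edges; occupancy is summed
#' dwell. Survivors run off at the `span_bp` boundary: their dwell over
#' traversed bases counts, but no terminal pile-up is added at the boundary.
#' If `reads_total` is set, that many reads are drawn multinomially from the
#' occupancy distribution; uniform per-base Poisson background noise is
#' added on both strands genome-wide.
#'
#' @param sim a `sim_genome`
#' @param condition `"WT"` or `"mutant"`
#' @return list: `pair` (plus/minus raw-count `coverage_track`s), `truth`
#'   (per gene: initiated, released, run-off, stalled, realized survivors
#'   past the primary tract and the configured read-through fraction),
#'   `condition`
#' @export
simulate_transcription <- function(sim, condition = c("WT", "mutant")) {
  condition <- match.arg(condition)
  cfg <- sim$config
  set.seed(cfg$seed + if (condition == "WT") 104729L else 224737L)
  p_failsafe <- if (condition == "WT") cfg$p_failsafe_WT else cfg$p_failsafe_mut
  sizes <- chrom_sizes(sim$genome)
  cov <- list(`+` = lapply(sizes, numeric), `-` = lapply(sizes, numeric))

  truth <- sim$truth
  truth$condition <- condition
  truth$n_init <- 0L
  truth$released <- 0L
  truth$runoff <- 0L
  truth$stalled <- 0L
  truth$survived_primary <- 0L

  for (i in seq_len(nrow(sim$genes))) {
    g <- sim$genes[i, ]
    tr <- sim$tracts[sim$tracts$gene_id == g$gene_id, , drop = FALSE]
    prim <- tr[tr$role == "primary", ]
    spacer <- truth$spacer_bp[i]
    gene_len <- g$end - g$start
    p3_off <- gene_len + spacer + prim$length
    # secondary 3'-edge offsets in walk space
    sec <- tr[tr$role == "secondary", , drop = FALSE]
    if (nrow(sec)) {
      d5 <- if (g$strand == "+") sec$start - prim$end else prim$start - sec$end
      attr(tr, "sec_fw_end") <- p3_off + d5 + sec$length
    }
    n_init <- if (cfg$initiations_fixed) as.integer(cfg$initiations_per_gene)
              else stats::rpois(1L, cfg$initiations_per_gene)
    if (n_init == 0L) {
      truth$n_init[i] <- 0L
      next
    }
    # survivors past the primary tract, drawn first so the realized
    # read-through fraction is recorded exactly, then the walk continues
    # conditional on it; implemented by drawing the primary release inside
    # the walk and reading the count back from the first event.
    w <- walk_gene(tr, gene_len, spacer, sim$pause_sites[[i]], cfg,
                   p_failsafe, n_init)
    # survivors past primary = polymerases whose walk passed base p3_off =
    # occupancy-based accounting: arrivals at p3_off minus releases there.
    # Recover from the occupancy chain: the base after the tract edge holds
    # n_after * dwell (dwell 1 unless it is itself an event base).
    truth$n_init[i] <- n_init
    truth$released[i] <- w$released
    truth$runoff[i] <- w$runoff
    truth$stalled[i] <- w$stalled
    after <- p3_off + 1L
    nb_dwell <- 1
    if (after <= length(w$occ)) {
      if (after %in% (p3_off + sim$pause_sites[[i]])) nb_dwell <- cfg$dwell_pause
      truth$survived_primary[i] <- round(w$occ[after] / nb_dwell)
    }
    # place the walk on the genome
    if (g$strand == "+") {
      pos <- (g$start + 1L):(g$start + length(w$occ))
      v <- cov[["+"]][[g$chrom]]
      v[pos] <- v[pos] + w$occ
      cov[["+"]][[g$chrom]] <- v
    } else {
      pos <- g$end:(g$end - length(w$occ) + 1L)
      v <- cov[["-"]][[g$chrom]]
      v[pos] <- v[pos] + w$occ
      cov[["-"]][[g$chrom]] <- v
    }
  }
  if (sum(truth$n_init) == 0L)
    stop_polterm("zero initiation events across the gene set")

  # read sampling from the occupancy distribution, then additive background
  if (!is.null(cfg$reads_total)) {
    flat <- unlist(cov, use.names = FALSE)
    tot <- sum(flat)
    reads <- as.numeric(stats::rmultinom(1L, cfg$reads_total, flat))
    idx <- 0L
    for (s in c("+", "-")) for (chrom in names(sizes)) {
      len <- sizes[[chrom]]
      cov[[s]][[chrom]] <- reads[(idx + 1L):(idx + len)]
      idx <- idx + len
    }
  }
  if (cfg$background_noise_rate > 0) {
    for (s in c("+", "-")) for (chrom in names(sizes)) {
      cov[[s]][[chrom]] <- cov[[s]][[chrom]] +
        stats::rpois(sizes[[chrom]], cfg$background_noise_rate)
    }
  }
  # coding genes carry RNAPII-associated background above ambient noise
  # (the reason they serve as the thresholding substrate)
  if (cfg$coding_background_rate > 0) {
    for (i in seq_len(nrow(sim$coding_genes))) {
      cg <- sim$coding_genes[i, ]
      idx <- (cg$start + 1L):cg$end
      cov[[cg$strand]][[cg$chrom]][idx] <-
        cov[[cg$strand]][[cg$chrom]][idx] +
        stats::rpois(length(idx), cfg$coding_background_rate)
    }
  }
  pair <- list(
    plus = coverage_track(cov[["+"]], sizes, "+",
                          sample_id = paste0(condition, "_1"),
                          condition = condition),
    minus = coverage_track(cov[["-"]], sizes, "-",
                           sample_id = paste0(condition, "_1"),
                           condition = condition))
  list(pair = pair, truth = truth, condition = condition)
}

#' Write a simulated dataset to disk
#'
#' Emits everything the pipeline consumes: genome FASTA, chrom.sizes, gene
#' and coding-gene BED6, designed-tract BED6, per-condition strand-specific
#' bedGraph pairs (raw counts; CPM normalization is applied downstream),
#' per-condition truth TSV, and a key=value echo of the configuration.
#'
#' @param sim a `sim_genome`
#' @param transcription list of [simulate_transcription()] results
#' @param outdir output directory (created if needed)
#' @return named list of written paths, invisibly
#' @export
emit_coverage <- function(sim, transcription, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, paste0(...))
  paths <- list(
    genome = write_genome_fasta(sim$genome, p("genome.fa")),
    chrom_sizes = write_chrom_sizes(chrom_sizes(sim$genome), p("chrom.sizes")),
    genes = {
      g <- sim$genes; g$name <- g$gene_id; g$score <- 0L
      write_bed6(g, p("genes.bed"))
    },
    coding = {
      g <- sim$coding_genes; g$name <- g$gene_id; g$score <- 0L
      write_bed6(g, p("coding.bed"))
    },
    tracts = write_tracts_bed(sim$tracts, p("tracts_designed.bed")))
  for (tx in transcription) {
    cond <- tx$condition
    paths[[paste0(cond, "_plus")]] <-
      write_coverage(tx$pair$plus, p(cond, "_plus.bedgraph"))
    paths[[paste0(cond, "_minus")]] <-
      write_coverage(tx$pair$minus, p(cond, "_minus.bedgraph"))
    paths[[paste0(cond, "_truth")]] <-
      write_tsv(tx$truth, p("truth_", cond, ".tsv"))
  }
  cfg <- sim$config
  scal <- vapply(cfg, function(x)
    is.atomic(x) && !is.null(x), logical(1))
  echo <- vapply(cfg[scal], function(x) paste(x, collapse = ","), character(1))
  writeLines(paste0(names(echo), "=", echo), p("config.txt"))
  paths$config <- p("config.txt")
  invisible(paths)
}

#' One-call synthetic dataset (genome + both conditions)
#'
#' @param config a [sim_config()]
#' @param outdir optional directory; when given, files are written with
#'   [emit_coverage()]
#' @return list: `sim` (the `sim_genome`), `WT` and `mutant`
#'   ([simulate_transcription()] results), `paths` (when written)
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  sim <- simulate_genome(config)
  wt <- simulate_transcription(sim, "WT")
  mut <- simulate_transcription(sim, "mutant")
  out <- list(sim = sim, WT = wt, mutant = mut)
  if (!is.null(outdir))
    out$paths <- emit_coverage(sim, list(wt, mut), outdir)
  out
}
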