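#' Pipeline orchestration
#'
#' A single key=value configuration file drives the whole analysis: tract
#' annotation, per-condition read-through calling, and the termination
#' statistics set. Every run writes a provenance block (configuration echo,
#' package version, input checksums) and one structured log line per stage,
#' so flagged-gene counts and threshold values are always visible.
#'
#' @name pipeline
NULL

pipeline_param_spec <- list(
  min_tract_len = c(1, 50), max_search_bp = c(1, 1e6),
  secondary_window = c(1, 1e5), rt_span = c(20, 1e5),
  window = c(1, 1e4), step = c(1, 1e4), quantile = c(1e-6, 1 - 1e-6),
  max_gap = c(0, 1e4), pseudocount = c(0, 1e6),
  body_bins = c(1, 1e4), flank = c(0, 1e5),
  dependency_window = c(1, 1e5), seed = c(0, 2^31 - 1),
  normalized = c(0, 1)
)

pipeline_defaults <- list(
  min_tract_len = 4, max_search_bp = 1000, secondary_window = 700,
  rt_span = 1000, window = 20, step = 19, quantile = 0.95, max_gap = 20,
  pseudocount = 1, body_bins = 100, flank = 500, dependency_window = 700,
  seed = 1, normalized = 0
)

pipeline_path_keys <- c("genome", "genes_bed", "coding_bed", "chrom_sizes",
                        "wt_plus", "wt_minus", "mut_plus", "mut_minus",
                        "outdir")

#' Read and validate a pipeline configuration
#'
#' The file holds one `key = value` pair per line (`#` comments allowed).
#' Unknown keys are rejected; numeric parameters are range-checked.
#'
#' @param path configuration file
#' @param overrides named list applied on top of the file (CLI overrides)
#' @return a validated `pipeline_config` list with `paths` and `params`
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  kv <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_polterm("config file not found: %s", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", ln))[[1L]]
      if (length(m) != 3L) stop_polterm("cannot parse config line: %s", ln)
      kv[[m[2L]]] <- trimws(m[3L])
    }
  }
  kv[names(overrides)] <- overrides
  unknown <- setdiff(names(kv), c(names(pipeline_param_spec),
                                  pipeline_path_keys))
  if (length(unknown)) stop_polterm("unknown config key: %s", unknown[1L])
  params <- pipeline_defaults
  for (key in intersect(names(kv), names(pipeline_param_spec))) {
    val <- suppressWarnings(as.numeric(kv[[key]]))
    rng <- pipeline_param_spec[[key]]
    if (is.na(val) || val < rng[1L] || val > rng[2L])
      stop_polterm("config %s=%s outside [%g, %g]", key, kv[[key]],
                   rng[1L], rng[2L])
    params[[key]] <- val
  }
  paths <- kv[intersect(names(kv), pipeline_path_keys)]
  structure(list(paths = paths, params = params), class = "pipeline_config")
}

log_stage <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[polterm] stage=%s %s", stage,
                  paste(names(kv), kv, sep = "=", collapse = " ")))
}

write_provenance <- function(config, outdir) {
  inputs <- unlist(config$paths[names(config$paths) != "outdir"])
  sums <- if (length(inputs)) tools::md5sum(inputs[file.exists(inputs)])
          else character()
  lines <- c(
    paste0("polterm_version=", as.character(utils::packageVersion("polterm"))),
    paste0(names(config$params), "=", unlist(config$params)),
    paste0(names(config$paths), "=", unlist(config$paths)),
    paste0("md5:", names(sums), "=", sums))
  writeLines(lines, file.path(outdir, "provenance.txt"))
}

require_paths <- function(config, keys) {
  for (key in keys) {
    p <- config$paths[[key]]
    if (is.null(p)) stop_polterm("config is missing required path '%s'", key)
    if (!file.exists(p)) stop_polterm("%s file not found: %s", key, p)
  }
}

#' Run terminator annotation
#'
#' @param config a `pipeline_config` (paths: `genome`, `genes_bed`,
#'   `outdir`)
#' @return list: `tracts`, `anno_table`, `paths` of written files
#' @export
run_annotate <- function(config) {
  require_paths(config, c("genome", "genes_bed"))
  outdir <- config$paths$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  genome <- read_genome_fasta(config$paths$genome)
  genes <- read_genes_bed(config$paths$genes_bed,
                          chrom_sizes = chrom_sizes(genome))
  tracts <- find_t_tracts(genome, p$min_tract_len)
  anno <- annotate_terminators(genes, tracts, p$max_search_bp,
                               p$secondary_window)
  paths <- list(
    tracts = write_tracts_bed(tracts, file.path(outdir, "tracts.bed")),
    anno = write_annotation_tsv(anno, file.path(outdir, "terminators.tsv")))
  write_provenance(config, outdir)
  log_stage("annotate", genes = nrow(genes), tracts = nrow(tracts),
            flagged = sum(anno$flagged))
  invisible(list(tracts = tracts, anno_table = anno, paths = paths))
}

load_condition <- function(config, condition) {
  keys <- if (condition == "WT") c("wt_plus", "wt_minus")
          else c("mut_plus", "mut_minus")
  require_paths(config, c(keys, "chrom_sizes"))
  sizes <- read_chrom_sizes(config$paths$chrom_sizes)
  pair <- load_coverage(config$paths[[keys[1L]]], config$paths[[keys[2L]]],
                        sizes, sample_id = condition, condition = condition,
                        normalized = config$params$normalized > 0)
  if (!pair$plus$normalized) pair <- normalize_cpm(pair)
  pair
}

#' Run read-through calling for one condition
#'
#' @param config a `pipeline_config`
#' @param condition `"WT"` or `"mutant"`
#' @param annotate optional result of [run_annotate()] (recomputed if
#'   missing)
#' @return list: `threshold`, `rt_table`, `pair`, `paths`
#' @export
run_rt <- function(config, condition = "WT", annotate = NULL) {
  require_paths(config, c("coding_bed", "chrom_sizes"))
  outdir <- config$paths$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  if (is.null(annotate)) annotate <- run_annotate(config)
  pair <- load_condition(config, condition)
  coding <- read_genes_bed(config$paths$coding_bed, gene_class = "coding",
                           chrom_sizes = chrom_sizes(pair$plus))
  thr <- background_threshold(pair, coding, p$window, p$quantile)
  rt <- call_rt_regions(pair, annotate$anno_table, thr, span_bp = p$rt_span,
                        window_bp = p$window, step_bp = p$step,
                        max_gap_bp = p$max_gap)
  tag <- if (condition == "WT") "wt" else "mutant"
  paths <- list(
    bed = write_rt_bed(rt, file.path(outdir, paste0("rt_", tag, ".bed"))),
    tsv = write_tsv(rt, file.path(outdir, paste0("rt_", tag, ".tsv"))))
  log_stage("rt-call", condition = condition, genes = nrow(rt),
            empty = sum(rt$empty), threshold = signif(thr$threshold_value, 6))
  invisible(list(threshold = thr, rt_table = rt, pair = pair, paths = paths))
}

#' Run the two-condition termination statistics set
#'
#' Requires both conditions; emits the per-gene summary (conditions side by
#' side), metagene and fold-change heatmap matrices, quartile tables and
#' group tests.
#'
#' @param config a `pipeline_config`
#' @return list of computed objects and written `paths`, invisibly
#' @export
run_stats <- function(config) {
  outdir <- config$paths$outdir %||% "."
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  ann <- run_annotate(config)
  wt <- run_rt(config, "WT", ann)
  mut <- run_rt(config, "mutant", ann)
  sum_wt <- termination_summary(wt$pair, ann$anno_table, wt$rt_table, "WT")
  sum_mut <- termination_summary(mut$pair, ann$anno_table, mut$rt_table,
                                 "mutant")
  merged <- merge(sum_wt, sum_mut, by = "gene_id",
                  suffixes = c("_WT", "_mutant"))
  fc <- log2_fold_change_pair(mut$pair, wt$pair, p$pseudocount)
  quart <- rank_by_dependency(fc, ann$anno_table, p$dependency_window)
  tq <- terminators_per_quartile(quart, ann$anno_table)
  gt_strong <- group_tests(
    merge(quart, as.data.frame(ann$anno_table))$n_strong_secondary,
    merge(quart, as.data.frame(ann$anno_table))$quartile)
  mg_wt <- metagene_matrix(wt$pair, ann$anno_table, p$body_bins)
  hm <- heatmap_matrix(fc, ann$anno_table, body_bins = p$body_bins,
                       flank_bp = p$flank)
  len_cls <- cluster_by_terminator_length(sum_wt)
  corr <- correlate_conditions(sum_wt, sum_mut, "rt_index")
  pw <- paired_wilcoxon(sum_wt$rt_index, sum_mut$rt_index)
  paths <- list(
    summary = write_tsv(merged, file.path(outdir, "termination_summary.tsv")),
    quartiles = write_tsv(quart, file.path(outdir, "quartiles.tsv")),
    quartile_terminators = write_tsv(tq, file.path(outdir,
                                                   "quartile_terminators.tsv")),
    metagene = write_tsv(as.data.frame(mg_wt),
                         file.path(outdir, "metagene_wt.tsv")),
    heatmap = write_tsv(as.data.frame(hm), file.path(outdir, "heatmap_fc.tsv")),
    length_classes = write_tsv(len_cls, file.path(outdir,
                                                  "rt_index_by_tract_length.tsv")),
    tests = write_tsv(
      data.frame(test = c("kruskal_strong_by_quartile",
                          "paired_wilcoxon_rt_index", "pearson_rt_index"),
                 statistic = c(gt_strong$kruskal$statistic, pw$statistic,
                               corr$r),
                 p_value = c(gt_strong$kruskal$p_value, pw$p_value,
                             corr$p_value)),
      file.path(outdir, "tests.tsv")))
  log_stage("stats", genes = nrow(merged),
            zero_body_wt = attr(sum_wt, "n_zero_body"),
            zero_body_mut = attr(sum_mut, "n_zero_body"))
  invisible(list(summary_wt = sum_wt, summary_mut = sum_mut, merged = merged,
                 fc = fc, quartiles = quart, quartile_terminators = tq,
                 group_tests = gt_strong, metagene = mg_wt, heatmap = hm,
                 length_classes = len_cls, correlation = corr,
                 paired_wilcoxon = pw, annotate = ann, wt = wt, mut = mut,
                 paths = paths))
}

#' Command-line entry point
#'
#' Subcommands: `annotate`, `rt-call`, `stats`, `metagene`, `simulate`,
#' `all`. Exit codes: 0 success, 2 input validation failure, 3 internal
#' invariant violation. Arguments: `--config FILE`, `--outdir DIR`,
#' `--seed INT`, `--condition WT|mutant`, plus `key=value` overrides of any
#' configuration parameter.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`)
#' @return exit code, invisibly
#' @export
polterm_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    message("usage: polterm <annotate|rt-call|stats|metagene|simulate|all> ",
            "[--config FILE] [--outdir DIR] [--seed INT] ",
            "[--condition WT|mutant] [key=value ...]")
    return(invisible(2L))
  }
  cmd <- args[1L]
  args <- args[-1L]
  opts <- list(config = NULL, outdir = NULL, seed = NULL, condition = "WT")
  overrides <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (a %in% c("--config", "--outdir", "--seed", "--condition")) {
      opts[[sub("^--", "", a)]] <- args[i + 1L]
      i <- i + 2L
    } else if (grepl("=", a, fixed = TRUE)) {
      kv <- strsplit(a, "=", fixed = TRUE)[[1L]]
      overrides[[kv[1L]]] <- paste(kv[-1L], collapse = "=")
      i <- i + 1L
    } else {
      message("unrecognized argument: ", a)
      return(invisible(2L))
    }
  }
  if (!is.null(opts$outdir)) overrides$outdir <- opts$outdir
  if (!is.null(opts$seed)) overrides$seed <- opts$seed
  status <- tryCatch({
    config <- read_pipeline_config(opts$config, overrides)
    switch(cmd,
      annotate = run_annotate(config),
      "rt-call" = run_rt(config, opts$condition),
      stats = ,
      all = run_stats(config),
      metagene = {
        res <- run_rt(config, opts$condition)
        ann <- run_annotate(config)
        m <- metagene_matrix(res$pair, ann$anno_table,
                             config$params$body_bins)
        write_tsv(as.data.frame(m),
                  file.path(config$paths$outdir %||% ".", "metagene.tsv"))
      },
      simulate = {
        cfg <- sim_config(seed = as.integer(config$params$seed))
        simulate_dataset(cfg, config$paths$outdir %||% "sim_out")
      },
      {
        message("unknown subcommand: ", cmd)
        return(invisible(2L))
      })
    0L
  }, error = function(e) {
    message("polterm error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
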