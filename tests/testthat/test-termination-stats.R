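# Shared two-condition fixture (built once per file).
stats_fixture <- local({
  ds <- small_dataset(seed = 19L, n_genes = 16L)
  wt <- normalize_cpm(ds$WT$pair)
  mut <- normalize_cpm(ds$mutant$pair)
  ann <- annotate_terminators(ds$sim$genes, find_t_tracts(ds$sim$genome))
  thr <- background_threshold(wt, ds$sim$coding_genes)
  thr_m <- background_threshold(mut, ds$sim$coding_genes)
  list(ds = ds, wt = wt, mut = mut, ann = ann,
       rt_wt = call_rt_regions(wt, ann, thr),
       rt_mut = call_rt_regions(mut, ann, thr_m))
})

test_that("RT index is the RT/body signal percentage", {
  f <- stats_fixture
  s <- termination_summary(f$wt, f$ann, f$rt_wt, "WT")
  expect_equal(s$rt_index, 100 * s$rt_signal / s$gene_body_signal)
  expect_true(all(s$rt_signal >= 0))
  expect_true(all(s$rt_index >= 0, na.rm = TRUE))
  # definitional example: body 100, RT 50 -> 50%
  v <- numeric(1500)
  v[101:205] <- 100 / 105                 # gene body + tract region
  v[221:260] <- 50 / 40                   # read-through signal
  pair <- make_pair(v)
  anno <- make_anno("g1", "chrI", "+", 100L, 200L, 201L, 205L)
  ann1 <- structure(
    data.frame(gene_id = "g1", chrom = "chrI", strand = "+",
               gene_start = 100L, gene_end = 200L, primary_start = 201L,
               primary_end = 205L, primary_len = 4L, primary_class = "weak",
               spacer_bp = 1L, flagged = FALSE, n_weak_secondary = 0L,
               n_strong_secondary = 0L, stringsAsFactors = FALSE),
    annos = list(g1 = anno))
  rt1 <- data.frame(gene_id = "g1", chrom = "chrI", strand = "+",
                    start = 205L, end = 260L, rt_length_bp = 55L,
                    fragments_merged = 1L, empty = FALSE,
                    stringsAsFactors = FALSE)
  s1 <- termination_summary(pair, ann1, rt1)
  expect_equal(s1$gene_body_signal, 100)
  expect_equal(s1$rt_signal, 50)
  expect_equal(s1$rt_index, 50)
  # empty RT region -> 0%; zero body -> flagged NA
  rt1$empty <- TRUE
  expect_equal(termination_summary(pair, ann1, rt1)$rt_index, 0)
  s0 <- termination_summary(make_pair(numeric(1500)), ann1, rt1)
  expect_true(is.na(s0$rt_index))
  expect_equal(attr(s0, "n_zero_body"), 1L)
})

test_that("log2 fold change follows the pseudocount formula", {
  a <- make_pair(rep(8, 30))$plus
  b <- make_pair(rep(8, 30))$plus
  expect_equal(log2_fold_change_track(a, b)$values$chrI, rep(0, 30))
  # both zero -> 0
  z <- make_pair(numeric(30))$plus
  expect_equal(log2_fold_change_track(z, z)$values$chrI, rep(0, 30))
  # mut = 2x wt with values >> pseudocount -> close to 1
  big <- make_pair(rep(2000, 30))$plus
  half <- make_pair(rep(1000, 30))$plus
  fc <- log2_fold_change_track(big, half, pseudocount = 1)$values$chrI
  expect_equal(fc, rep(log2(2001 / 1001), 30))
  expect_true(all(abs(fc - 1) < 0.01))
  expect_error(log2_fold_change_track(a, b, pseudocount = -1), ">= 0")
  expect_error(log2_fold_change_track(a, make_pair(numeric(30))$minus),
               "same-strand")
})

test_that("fractional rebinning matches closed-form integrals", {
  # constant signal -> every bin equals it, any bin count
  expect_equal(rebin_mean(rep(3, 97), 10), rep(3, 10))
  # linear ramp: bin means equal the midpoint (trapezoid) value of the
  # underlying step function integrated exactly
  L <- 50L
  v <- (seq_len(L) - 1)    # per-base values 0,1,...,49
  nb <- 7L
  got <- rebin_mean(v, nb)
  edges <- seq(0, L, length.out = nb + 1L)
  exact <- vapply(seq_len(nb), function(j) {
    a <- edges[j]; b <- edges[j + 1L]
    # integral of the step function value floor(x) over [a,b]
    xs <- seq(floor(a), ceiling(b))
    tot <- 0
    for (k in seq_len(length(xs) - 1L)) {
      lo <- max(a, xs[k]); hi <- min(b, xs[k + 1L])
      if (hi > lo) tot <- tot + v[xs[k] + 1L] * (hi - lo)
    }
    tot / (b - a)
  }, numeric(1))
  expect_equal(got, exact)
  # bins can outnumber bases
  expect_equal(rebin_mean(c(2, 4), 4), c(2, 2, 4, 4))
})

test_that("metagene rows are scale invariant and 5'-anchored", {
  v <- numeric(3000)
  v[1:3000] <- 1
  sizes <- c(chrI = 3000L)
  pair <- make_pair(rep(1, 3000))
  # two genes, one twice the length, same constant signal -> identical rows
  ann <- structure(
    data.frame(gene_id = c("a", "b"), chrom = "chrI", strand = "+",
               gene_start = c(100L, 1000L), gene_end = c(200L, 1200L),
               primary_start = c(205L, 1205L), primary_end = c(210L, 1210L),
               primary_len = 5L, primary_class = "weak", spacer_bp = 5L,
               flagged = FALSE, n_weak_secondary = 0L,
               n_strong_secondary = 0L, stringsAsFactors = FALSE))
  m <- metagene_matrix(pair, ann, body_bins = 50)
  expect_equal(dim(m), c(2L, 50L))
  expect_equal(unname(m["a", ]), rep(1, 50))
  expect_equal(unname(m["a", ]), unname(m["b", ]))
  expect_equal(unname(attr(m, "summary")), rep(1, 50))
  # minus-strand mirroring: ramp rising along the genome appears reversed
  ramp <- numeric(3000)
  ramp[100:210] <- seq_along(100:210)
  pair2 <- make_pair(rev_minus <- numeric(3000), ramp)
  ann_m <- ann[1, ]
  ann_m$strand <- "-"
  ann_m$gene_start <- 105L; ann_m$gene_end <- 210L
  ann_m$primary_start <- 100L; ann_m$primary_end <- 105L
  m2 <- metagene_matrix(pair2, ann_m, body_bins = 10)
  expect_true(all(diff(m2[1, ]) < 0))  # 5' column first after mirroring
  # flank bins appear on both sides
  m3 <- metagene_matrix(pair, ann, body_bins = 20, flank_bp = 40,
                        flank_bin_bp = 10)
  expect_equal(ncol(m3), 20L + 8L)
})

test_that("heatmap ordering is a permutation sorted by row mean", {
  f <- stats_fixture
  fc <- log2_fold_change_pair(f$mut, f$wt)
  hm <- heatmap_matrix(fc, f$ann, body_bins = 30)
  expect_setequal(rownames(hm), f$ann$gene_id[!f$ann$flagged])
  expect_true(all(diff(attr(hm, "row_mean")) <= 0))
  # equal conditions -> all-zero matrix
  fc0 <- log2_fold_change_pair(f$wt, f$wt)
  hm0 <- heatmap_matrix(fc0, f$ann, body_bins = 30)
  expect_true(all(hm0 == 0))
})

test_that("dependency ranking forms rank-based quartiles", {
  f <- stats_fixture
  fc <- log2_fold_change_pair(f$mut, f$wt)
  q <- rank_by_dependency(fc, f$ann)
  expect_equal(sort(q$rank), seq_len(nrow(q)))
  expect_equal(unname(table(q$quartile)), rep(nrow(q) / 4, 4),
               ignore_attr = TRUE)
  expect_equal(q$gene_id[order(q$rank)][1],
               q$gene_id[which.max(q$dependency_score)])
  # 8 genes with distinct scores -> Q1 = top 2 (hand-built fc tracks)
  sizes <- c(chrI = 8000L)
  wtv <- rep(1, 8000)
  mutv <- rep(1, 8000)
  ann8 <- structure(data.frame(
    gene_id = paste0("g", 1:8), chrom = "chrI", strand = "+",
    gene_start = 900L * (0:7), gene_end = 900L * (0:7) + 100L,
    primary_start = 900L * (0:7) + 104L, primary_end = 900L * (0:7) + 110L,
    primary_len = 6L, primary_class = "strong", spacer_bp = 4L,
    flagged = FALSE, n_weak_secondary = 0L, n_strong_secondary = 0L,
    stringsAsFactors = FALSE))
  for (i in 1:8) mutv[(900 * (i - 1) + 111):(900 * (i - 1) + 400)] <- 2^i
  fc8 <- log2_fold_change_pair(make_pair(mutv), make_pair(wtv))
  q8 <- rank_by_dependency(fc8, ann8)
  expect_equal(q8$gene_id[q8$quartile == "Q1"], c("g7", "g8"))
  # all-equal scores: deterministic lexicographic tie-break
  fc_eq <- log2_fold_change_pair(make_pair(wtv), make_pair(wtv))
  q_eq <- rank_by_dependency(fc_eq, ann8)
  expect_equal(q_eq$gene_id[order(q_eq$rank)], paste0("g", 1:8))
  expect_error(rank_by_dependency(fc8, ann8[1:3, ]), ">= 4 genes")
})

test_that("per-quartile terminator counts and their SEs are exact", {
  quart <- data.frame(gene_id = paste0("g", 1:8),
                      dependency_score = 8:1, rank = 1:8,
                      quartile = factor(rep(paste0("Q", 1:4), each = 2)))
  at <- data.frame(gene_id = paste0("g", 1:8),
                   n_weak_secondary = c(1L, 3L, 0L, 0L, 2L, 2L, 5L, 1L),
                   n_strong_secondary = 2L)
  tq <- terminators_per_quartile(quart, at)
  expect_equal(tq$mean[tq$kind == "strong"], rep(2, 4))
  expect_equal(tq$se[tq$kind == "strong"], rep(0, 4))
  w1 <- tq[tq$kind == "weak" & tq$quartile == "Q1", ]
  expect_equal(w1$mean, 2)
  expect_equal(w1$se, sd(c(1, 3)) / sqrt(2))
  # single-gene quartile: SE undefined and flagged as NA
  quart1 <- quart[c(1, 3, 5, 7), ]
  quart1$quartile <- factor(paste0("Q", 1:4))
  tq1 <- terminators_per_quartile(quart1, at)
  expect_true(all(is.na(tq1$se)))
  # empty quartile errors
  quart_bad <- quart
  quart_bad$quartile <- factor(rep("Q1", 8), levels = paste0("Q", 1:4))
  expect_error(terminators_per_quartile(quart_bad, at), "empty quartile")
})

test_that("Kruskal-Wallis H matches the rank-formula hand computation", {
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  grp <- rep(c("a", "b", "c"), each = 3)
  gt <- group_tests(vals, grp)
  # H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1), no ties
  r <- rank(vals)
  rbar <- tapply(r, grp, mean)
  H <- 12 / (9 * 10) * sum(3 * rbar^2) - 3 * 10
  expect_equal(gt$kruskal$statistic, H)
  expect_true(gt$kruskal$defined)
  expect_equal(nrow(gt$pairwise), 3L)
  # with ties: compare against kruskal's tie-corrected hand formula
  vals_t <- c(1, 1, 2, 2, 3, 3, 4, 4, 5)
  rt_ <- rank(vals_t)
  rbar_t <- tapply(rt_, grp, mean)
  H_t <- 12 / (9 * 10) * sum(3 * rbar_t^2) - 3 * 10
  ties <- table(vals_t)
  H_t <- H_t / (1 - sum(ties^3 - ties) / (9^3 - 9))
  expect_equal(group_tests(vals_t, grp)$kruskal$statistic, H_t)
  # identical groups -> pairwise p 1 (up to tie handling)
  gt2 <- group_tests(rep(c(1, 2, 3), 2), rep(c("x", "y"), each = 3))
  expect_gt(gt2$pairwise$p_value, 0.9)
  # relabeling equal-size groups leaves H invariant
  perm <- c(a = "c", b = "a", c = "b")
  expect_equal(group_tests(vals, perm[grp])$kruskal$statistic, H)
  # all observations identical -> flagged
  gt3 <- group_tests(rep(1, 6), rep(c("x", "y"), 3))
  expect_false(gt3$kruskal$defined)
  expect_error(group_tests(1:5, rep("a", 5)), ">= 2 groups")
})

test_that("paired Wilcoxon flags the all-zero-difference case", {
  pw <- paired_wilcoxon(c(1, 2, 3, 4), c(2, 4, 6, 8))
  ref <- suppressWarnings(wilcox.test(c(1, 2, 3, 4), c(2, 4, 6, 8),
                                      paired = TRUE, exact = FALSE))
  expect_equal(pw$p_value, ref$p.value)
  expect_false(paired_wilcoxon(c(1, 2), c(1, 2))$defined)
})

test_that("tract-length classes pool and average RT indices", {
  s <- data.frame(gene_id = paste0("g", 1:6),
                  rt_index = c(50, 30, 30, 10, 8, 6),
                  primary_tract_len = c(4L, 5L, 5L, 8L, 9L, 12L))
  cl <- cluster_by_terminator_length(s, pool_from = 8)
  expect_equal(cl$tract_len_class, c("4", "5", ">=8"))
  expect_equal(cl$mean_rt_index, c(50, 30, 8))
  expect_equal(cl$n, c(1L, 2L, 3L))
  expect_equal(cl$se[2], sd(c(30, 30)) / sqrt(2))
  expect_equal(cl$se[2], 0)
  # single class -> overall mean
  s$primary_tract_len <- 5L
  cl1 <- cluster_by_terminator_length(s)
  expect_equal(cl1$mean_rt_index, mean(s$rt_index))
})

test_that("condition correlation is Pearson over gene pairs", {
  sa <- data.frame(gene_id = paste0("g", 1:6), rt_index = c(1, 3, 5, 7, 9, 11),
                   rt_length_bp = 1:6)
  sb <- sa
  expect_equal(correlate_conditions(sa, sb)$r, 1)
  sb$rt_index <- rev(sa$rt_index)
  expect_equal(correlate_conditions(sa, sb)$r, -1)
  set.seed(6)
  sb$rt_index <- rnorm(6)
  res <- correlate_conditions(sa, sb)
  cx <- sa$rt_index; cy <- sb$rt_index
  r_hand <- sum((cx - mean(cx)) * (cy - mean(cy))) /
    sqrt(sum((cx - mean(cx))^2) * sum((cy - mean(cy))^2))
  expect_equal(res$r, r_hand)
  sb$rt_index <- rep(2, 6)
  expect_false(correlate_conditions(sa, sb)$defined)
})

test_that("read-through estimator tracks configured truth", {
  cfg <- sim_config(seed = 13, n_genes = 30, primary_len = 5,
                    n_weak_secondary = 0, n_strong_secondary = 0,
                    pause_site_rate = 0, background_noise_rate = 0,
                    initiations_per_gene = 3000, initiations_fixed = TRUE,
                    reads_total = NULL)
  ds <- simulate_dataset(cfg)
  ann <- annotate_terminators(ds$sim$genes, find_t_tracts(ds$sim$genome))
  est <- estimate_readthrough(normalize_cpm(ds$WT$pair), ann)
  pooled <- sum(est$down_total) / sum(est$up_total)
  expect_lt(abs(pooled - 0.5), 0.02)
})

test_that("fixed-window RT index is caller-independent", {
  f <- stats_fixture
  fx <- rt_index_fixed_window(f$wt, f$ann, window_bp = 700)
  expect_equal(nrow(fx), 16L)
  expect_equal(fx$rt_index_fixed,
               100 * fx$downstream_signal / fx$gene_body_signal)
  # hand check one '+' gene against region_signal
  g <- as.data.frame(f$ann)[as.data.frame(f$ann)$strand == "+", ][1, ]
  tr <- strand_track(f$wt, "+")
  down <- region_signal(tr, g$chrom, g$primary_end, g$primary_end + 700)$total
  expect_equal(fx$downstream_signal[fx$gene_id == g$gene_id], down)
  # correlates with the called RT index but needs no threshold at all
  s <- termination_summary(f$wt, f$ann, f$rt_wt)
  expect_gt(cor(fx$rt_index_fixed, s$rt_index, method = "spearman"), 0.5)
})
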