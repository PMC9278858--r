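# polterm

Quantitative analysis of RNA polymerase III (RNAPIII) transcription
termination from strand-specific, single-nucleotide occupancy tracks.

RNAPIII terminates at runs of thymidines (T-tracts) on the nontemplate
strand. Termination is imperfect: a fraction of polymerases reads through
the first T-tract downstream of a gene (the *primary terminator*) and is
caught further downstream by *secondary terminators* and by a fail-safe,
helicase-assisted release pathway. `polterm` turns this biology into a
reproducible pipeline for nascent-transcription data (CRAC / NET-seq style
coverage) contrasting a wild-type with a termination-deficient mutant:

- **Terminator annotation** — scan a genome for maximal T-tracts
  (`>= 4` T on either strand; `N` breaks runs), assign each gene the first
  same-strand tract at or after its 3′ end (primary terminator, with its
  spacer), collect tracts in the 700 bp further downstream as secondary
  terminators, and classify tract strength (4–5 T = weak, `>= 6` T =
  strong).
- **Coverage handling** — strand-specific bedGraph pairs as dense per-base
  tracks, counts-per-million normalization over the strand pair, region
  summaries, replicate averaging, and Spearman replicate correlation over
  genes ± 500 bp.
- **Read-through (RT) calling** — a background threshold set at the 95%
  quantile of total signal in nonoverlapping 20-bp windows over
  protein-coding (RNAPII) genes; the 1 kb downstream of each primary
  terminator tiled with 20-bp windows (1-bp overlap), above-threshold
  windows merged, small gaps closed, giving each gene an RT region and an
  **RT length**.
- **Termination statistics** — the **RT index** (RT-region signal as a
  percentage of gene-region signal; higher = leakier termination), per-base
  log2 fold-change tracks (mutant/WT, pseudocount 1 CPM), scaled metagene
  and fold-change heatmap matrices, ranking of genes by mutant dependency
  with quartile assignment (Q1 = most impaired), per-quartile
  secondary-terminator summaries, Kruskal–Wallis / Wilcoxon group tests,
  and Pearson condition correlations.
- **Synthetic data** — a stochastic polymerase-elongation simulator with
  known ground truth: Bernoulli release at each tract 3′ edge with
  probability increasing in tract length (none at T4, intermediate at T5,
  efficient at `>= 6` T), condition-dependent fail-safe release at
  downstream pause sites, dwell-weighted occupancy, multinomial read
  sampling and Poisson background. Every pipeline stage is testable
  without any external download.

In symbols, for gene *g* with primary terminator ending at its 3′ edge
*t(g)*:

    RT index(g) = 100 * S(RT region(g)) / S(5' end(g) .. t(g))

where *S* is total CPM signal, and the simulator's ground-truth
read-through fraction at a primary tract of length *L* is `1 − p_term(L)`.

## Worked example

Simulate a 20-gene two-condition dataset, then run the analysis from the
files on disk:

```r
library(polterm)

cfg <- sim_config(seed = 7, n_genes = 20)
ds  <- simulate_dataset(cfg, outdir = "sim_demo")

genome <- read_genome_fasta("sim_demo/genome.fa")
tracts <- find_t_tracts(genome, min_len = 4)
genes  <- read_genes_bed("sim_demo/genes.bed", chrom_sizes = chrom_sizes(genome))
anno   <- annotate_terminators(genes, tracts)

st <- spacer_statistics(anno, cutoff_bp = 7)
cat(sprintf("%d of %d genes have a spacer of at most 7 bp\n",
            st$n_within_cutoff, st$n_with_primary))

sizes <- read_chrom_sizes("sim_demo/chrom.sizes")
wt  <- normalize_cpm(load_coverage("sim_demo/WT_plus.bedgraph",
                                   "sim_demo/WT_minus.bedgraph", sizes))
mut <- normalize_cpm(load_coverage("sim_demo/mutant_plus.bedgraph",
                                   "sim_demo/mutant_minus.bedgraph", sizes))
coding <- read_genes_bed("sim_demo/coding.bed", "coding", sizes)

thr <- background_threshold(wt, coding)
print(thr)

rt_wt  <- call_rt_regions(wt,  anno, thr)
rt_mut <- call_rt_regions(mut, anno, background_threshold(mut, coding))
s_wt   <- termination_summary(wt,  anno, rt_wt,  "WT")
s_mut  <- termination_summary(mut, anno, rt_mut, "mutant")

cat(sprintf("median RT index: WT %.1f%%  mutant %.1f%%\n",
            median(s_wt$rt_index), median(s_mut$rt_index)))
cat(sprintf("median RT length: WT %d bp  mutant %d bp\n",
            median(s_wt$rt_length_bp), median(s_mut$rt_length_bp)))
pw <- paired_wilcoxon(s_wt$rt_index, s_mut$rt_index)
cat(sprintf("paired Wilcoxon on RT index: p = %.2g\n", pw$p_value))
```

Output:

```
18 of 20 genes have a spacer of at most 7 bp
threshold_model: 4.9553 (95% quantile of 2000 20-bp windows)
median RT index: WT 9.9%  mutant 32.6%
median RT length: WT 305 bp  mutant 1000 bp
paired Wilcoxon on RT index: p = 9.6e-05
```

Reading this: most spacers are short (the simulator emulates the tight
gene–terminator spacing of real tRNA genes); background over RNAPII genes
sets a threshold of ~5 CPM per 20-bp window; the fail-safe-deficient
mutant shows a ~3× higher RT index and read-through that typically runs
off the 1-kb analysis window, while WT read-through is resolved within
~300 bp — the qualitative signature of a fail-safe termination defect.

## Command line

```sh
exec/polterm annotate --config pipeline.cfg --outdir out
exec/polterm rt-call  --config pipeline.cfg --condition mutant
exec/polterm all      --config pipeline.cfg
exec/polterm simulate --outdir fixtures --seed 7
```

`pipeline.cfg` is a `key = value` file (paths: `genome`, `genes_bed`,
`coding_bed`, `chrom_sizes`, `wt_plus`, `wt_minus`, `mut_plus`,
`mut_minus`, `outdir`; parameters: `min_tract_len`, `secondary_window`,
`rt_span`, `window`, `step`, `quantile`, `max_gap`, `pseudocount`,
`body_bins`, `flank`, `dependency_window`, `seed`). Unknown keys are
rejected; every run writes `provenance.txt` (config echo, version, input
checksums). Exit codes: 0 success, 2 input validation failure.

## Further reading

`vignettes/polterm-methods.Rmd` documents the model, every tunable
parameter with its default and rationale, what the simulator does and does
not emulate, numerical edge cases, and known limitations.
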