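---
title: "polterm: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{polterm: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes and why
the defaults are what they are. It states no empirical result that the
test suite or the acceptance script does not itself compute.

## The analysis model

RNAPIII terminates at T-tracts on the nontemplate strand, but imperfectly:
a fraction of polymerases reads through the first tract downstream of a
gene and continues until it is released at a further tract or by a
fail-safe, helicase-dependent pathway acting at downstream pause sites.
The pipeline quantifies this per gene and per condition:

1. **T-tract scan.** Maximal runs of `T` (plus strand) or `A` (minus
   strand image) of length at least `min_tract_len` (default 4). `N`
   breaks a run; only uninterrupted runs count, so no composite tract
   (e.g. `TTTCTT`) is ever assembled.
2. **Primary terminator.** The same-strand tract with the smallest
   nonnegative orientation-aware distance (spacer) from the gene 3' end,
   searched up to `max_search_bp` (default 1,000 bp — the same extent as
   the read-through analysis window; genes without one are flagged and
   carried through, never dropped).
3. **Secondary terminators.** Same-strand tracts whose 5' edge falls in
   the `secondary_window` (default 700 bp) immediately after the primary
   tract. Tracts of 4–5 T are classed *weak*, 6 or more *strong*.
4. **Background threshold.** Protein-coding (RNAPII-transcribed) genes
   carry only nonspecific signal in an RNAPIII occupancy experiment; the
   threshold is the `quantile` (default 0.95) of total signal in
   nonoverlapping `window` (20 bp) windows over those genes, windows
   truncated at a gene end discarded.
5. **Read-through (RT) region.** 20-bp windows tiled over the 1 kb after
   the primary tract, above-threshold windows merged, fragments separated
   by at most `max_gap` (20 bp) joined; the region runs from the first
   base after the tract to the 3'-most retained fragment end. RT length
   is the region's extent, 0 when empty.
6. **RT index.** 100 × (RT-region signal) / (signal from the gene 5' end
   through the primary tract 3' edge). Genes with zero body signal are
   flagged (`NA`), counted, and excluded from aggregates.
7. **Condition contrast.** Per-base log2((mutant + 1 CPM)/(WT + 1 CPM));
   genes ranked by the mean of that ratio over `dependency_window`
   (700 bp) downstream of the primary tract; quartiles by rank, Q1 = most
   mutant-dependent. Group comparisons use Kruskal–Wallis, pairwise
   Mann–Whitney, and per-gene paired Wilcoxon; condition correlations use
   Pearson; replicate correlations use Spearman over gene ± 500 bp means.

### Assumptions

- Coverage is strand-specific, per-base, nonnegative, and comparable
  between conditions after counts-per-million (CPM) normalization over
  the strand pair.
- One primary terminator per gene describes the termination landscape;
  genes whose downstream windows overlap other loci are not masked
  (a deliberate non-goal; exclude such genes upstream if needed).
- Replicates, when present, are averaged per base before all downstream
  statistics — the simplest auditable merge rule.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `min_tract_len` | 4 | nt | shortest tract with any termination activity |
| `max_search_bp` | 1000 | bp | primary-terminator search limit; matches the RT window |
| `secondary_window` | 700 | bp | extent of secondary termination region |
| `rt_span` | 1000 | bp | downstream analysis window |
| `window` / `step` | 20 / 19 | bp | "20-bp windows with 1-bp overlap", read literally as step 19; `step = 1` selects the dense reading, and the two converge after merging |
| `quantile` | 0.95 | — | background quantile over coding-gene windows |
| `max_gap` | 20 | bp | reproducible stand-in for manual gap merging; one window width is the smallest natural unit |
| `pseudocount` | 1 | CPM | fold-change damping; the common coverage-comparison default |
| `body_bins` | 100 | bins | metagene gene-body scaling |
| `flank` | 500 | bp | replicate-correlation flank |
| `dependency_window` | 700 | bp | ranking window; matches the secondary-terminator window (the exact window behind the published ordering is unstated, so the two are aligned and configurable) |

## Choices made where the design was open

- **Coordinates.** Everything internal is 0-based half-open (BED
  convention); "downstream" and "3'" are transcription-oriented and
  mirrored for minus-strand genes. GRanges conversion happens only at
  file I/O.
- **Secondary-window edge.** The intersect-based published method fixes
  no edge rule. Here a tract is secondary iff its 5' edge lies in
  `[primary 3' end, primary 3' end + 700)` — identical to any-overlap
  intersection restricted to tracts strictly downstream of the primary.
  A tract whose 5' edge sits on the last window base is therefore
  included even if it extends past the boundary.
- **Window tiling.** With step 19, offsets 0, 19, … never cover the last
  11 bases of the span, so a final flush window at `span − window` is
  always added; otherwise a uniformly saturated span could not yield
  RT length = span. The exhaustive oracle in the tests tiles identically.
- **Strictly-greater threshold.** "Above the threshold" is `>`, so an
  all-zero track with threshold 0 yields empty regions.
- **Bounding interval.** Fragments disconnected from the terminator by
  more than `max_gap` still extend the region (the RT region is the
  union's bounding interval) and `fragments_merged` records the count.
  This makes the caller sensitive to any above-threshold window in the
  span — which is why the threshold substrate must sit above ambient
  noise (see the simulator notes).
- **RT index definition.** The operational definition (called RT region
  over gene region) is primary; `rt_index_fixed_window()` provides the
  fixed-window variant (700 bp downstream / gene body) as a
  threshold-free sensitivity check.
- **Quartiles.** Quartile of a gene with rank r among n is
  `ceiling(4 r / n)`; ties in the dependency score are broken by gene id,
  so the partition is deterministic and Q1 always holds the top quarter.
- **Pairwise p-values** are raw by default (matching starred-panel
  display conventions); Benjamini–Hochberg is available via
  `group_tests(..., adjust = "BH")`.
- **Plots and display-only outlier trimming** are not implemented: every
  quantity is emitted as TSV and the display-side k×IQR exclusion rule
  has no numeric consumer here. TSV outputs are never outlier-trimmed.

## The synthetic-data generator

`sim_config()` states a world; `simulate_genome()` and
`simulate_transcription()` realize it deterministically per seed.

**Genome.** Background sequence is generated free of T/A runs ≥ 4, then
designed tracts are written in with cleared flanking bases, so scanning
the emitted FASTA recovers exactly the designed terminators. Genes
(default 50, 70–120 bp, alternating strands) sit in disjoint slots with a
600-bp upstream flank and a clear 1.2-kb downstream window. Spacers are
drawn from 0–10 bp with ~93% mass at ≤ 7 bp, emulating the tight spacing
of real tRNA genes. Protein-coding background genes (20 × 2 kb) occupy a
second chromosome.

**Polymerase walk.** Each of `initiations_per_gene` polymerases (Poisson,
or exact) walks 5'→3'. At every tract 3' edge it releases with
`p_term(L)`; the default profile is anchored on in vitro behaviour —
essentially no release at T4 (0.05), intermediate at T5 (0.5), efficient
at T6 (0.9), rising to 0.98 at T12 — and must be non-decreasing. At each
downstream pause site (Bernoulli placement, `pause_site_rate = 0.02`/bp,
shared between conditions) it releases with the fail-safe probability:
0.5 in "WT", 0.05 in the termination-deficient "mutant". Dwell is 1 at
ordinary bases and `dwell_pause = 5` at pause sites and tract edges;
occupancy is summed dwell, so paused positions pile up signal as in
nascent 3'-end maps. Survivors stop at the 1-kb boundary: their dwell
over traversed bases counts, but no terminal pile-up is added there.
An optional stall-without-release mode (`p_stall`, off by default) parks
a fraction of polymerases at the proximal end of long tracts (≥ 9 T) to
stress the caller with terminator-proximal signal.

**Reads and noise.** `reads_total` (default 2 × 10⁶) reads are drawn
multinomially from the occupancy distribution — finite sequencing depth
matters: with infinite depth, arbitrarily small surviving flux stays
"above background" and RT length saturates at the span. Uniform
per-base Poisson noise (0.05/base) is added genome-wide, and coding genes
receive additional strand-matched background (0.25/base): they are the
thresholding substrate precisely because RNAPII loci carry nonspecific
signal above ambient noise. Without that lift the 95% threshold sits at
ambient q95 and ~5% of noise windows in every span are false positives,
which the bounding-interval rule stretches toward the 1-kb cap.

**Ground truth.** Per gene: the configured read-through fraction
`1 − p_term(L_primary)`, the realized survivor count past the primary
tract, released / run-off / stalled accounting (which sums exactly to
initiations), and the shared pause-site positions.

**What it does not emulate.** RNA secondary structure and its effect on
the fail-safe pathway, helicase translocation kinetics, per-U stepwise
release within a tract (release is one Bernoulli at the 3' edge),
sequencing errors, fragment-length effects, multimapping ambiguity, and
overlapping transcription units. A green test therefore establishes that
the pipeline measures the stated stochastic world correctly — not that
real libraries satisfy that world.

### Calibration experiment design

The acceptance suite runs the simulator in specific regimes:

- *Parameter recovery* uses 200 genes per tract-length class
  {4, 5, 6, 9, 12} at 500 polymerases each, with no secondary tracts, no
  pause sites and no noise: the estimator (ratio of summed signal in
  10-bp windows just downstream vs just upstream of the primary tract)
  then measures the primary-terminator Bernoulli in isolation, and must
  land within ±0.02 of truth per class.
- *Directional contrast* uses T5 primaries (the intermediate-efficiency
  regime where both conditions have downstream signal) at 10⁴
  polymerases per gene with all other parameters at their defaults.
- *Quartile enrichment* varies the designed strong-secondary count
  (0–3 per gene) with everything else fixed. Strong secondaries release
  equally in both conditions, so they do not change the mutant/WT flux
  ratio — they quench absolute signal toward the 1-CPM pseudocount, which
  is exactly how scarcity of strong terminators surfaces as higher
  measured mutant dependency.

## Numerical notes

- Quantiles use linear interpolation between order statistics (R type 7,
  the common default of scientific array libraries), tested against a
  hand-computed interpolation.
- Metagene binning integrates the per-base step function exactly over
  fractional bin edges; genes shorter than the bin count produce
  fractional bins, not errors.
- RT-index scale invariance (the CPM factor cancels) is exact in real
  arithmetic; in floating point it is exactly reproducible only under
  power-of-two rescaling, since window sums are computed via cumulative
  sums and borderline threshold ties may otherwise flip.
- A span reaching past the chromosome end is truncated with a warning;
  a zero-width region is an error; an undefined statistic (constant
  vector, all-tied differences, single-gene group) is returned flagged
  (`defined = FALSE` / `NA`), never silently coerced to a number.
- All randomness flows from explicit integer seeds; condition-specific
  streams are derived from the configured seed with fixed offsets, so a
  dataset is byte-identical across runs of the same configuration.

## Known limitations

- The RT caller inherits the published method's resolution limits: RT
  length is right-censored at the 1-kb span and quantized at window
  granularity near its end.
- Thresholding assumes the coding-gene background distribution matches
  the downstream-window background; systematic differences (mappability,
  copy number) would bias calls in real data.
- Dependency ranking uses a fixed downstream window; genes whose
  read-through extends past it are compressed at the top of the ranking.
- The spacer statistic on real genomes depends on the annotation release
  used; document the files, and expect counts near — not exactly at —
  published values.
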