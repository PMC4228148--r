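---
title: "Detecting and classifying intergenic mis-transcription near Pol III sites"
author: "polIIItx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying intergenic mis-transcription near Pol III sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polIIItx)
```

## The biological question and the analysis model

Chromatin-bound RNA polymerase III complexes — TFIIIC/TFIIIB/Pol III at
tRNA genes (tDNAs), TFIIIC alone at extra-TFIIIC (*ETC*) sites — act as
boundaries to local Pol II transcription in budding yeast. When complex
assembly is compromised, strand-specific RNA-seq of mutant versus wild-type
cells shows new or extended transcripts precisely in the intergenic
neighborhoods of these sites. The analytical difficulty is that standard
gene-level differential expression is blind to signal *outside* annotated
genes, and that the interesting events are defined by their geometry
relative to gene ends and Pol III sites, not just by fold change.

`polIIItx` therefore works on a complete, strand-resolved partition of the
genome. Per strand, annotated gene footprints are subtracted from each
chromosome; every remaining maximal gap (an *intergenic block*) is
demarcated into windows of `window_size` (default 500 bp) anchored at the
block's left edge. The partition is exact: on each strand the gene
footprints and windows tile `[0, chromosome length)` with no gaps or
overlaps, which in turn guarantees that the 5'-anchor counting rule below
assigns every fragment exactly once.

Counts are modelled as negative binomial, `var = mu + alpha * mu^2`.
Library depth is normalized by median-of-ratios size factors. For each
region, the two condition sums are compared with a conditional exact test:
conditional on the total `K`, every split `(a, K - a)` is assigned its
probability under the null of a shared normalized mean, and the p-value is
the summed probability of splits no more likely than the observed one.
Benjamini-Hochberg correction is applied within the gene family and the
intergenic-window family separately, mirroring an analysis that treats
coding and intergenic space as separate experiments; a joint mode exists
behind `de_config(joint_bh = TRUE)`.

Significant up-regulated intergenic windows are *chained* (adjacent windows
of one block, subject to an expression-continuity check) and every chain is
classified by a fixed-precedence geometric rule set:

1. **readthrough** — contiguous with the 3' end of a same-strand upstream
   transcript, overlapping a tDNA, and continuing past the tDNA's far edge;
2. **five_prime_extension** — contiguous with the 5' start of a same-strand
   downstream gene;
3. **three_prime_extension** — contiguous with the 3' end of a same-strand
   upstream gene;
4. **derepressed_intergenic** — everything else.

Precedence matters because a readthrough chain necessarily also touches an
upstream gene's 3' end; readthrough is tested first because it is the more
specific geometry. The original observations behind these categories were
made by manual browser inspection; the rule set is an explicit, reproducible
stand-in for that judgement, not a claim about the original curators'
criteria. Down-regulated intergenic chains are counted but not categorized,
since the category scheme describes gained transcription.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `window_size` | 500 bp | intergenic window size; the granularity of DE detection outside genes |
| `min_window` | 100 bp | a trailing remainder shorter than this merges into the preceding window |
| `include_noncoding_in_genespace` | `TRUE` | whether ncRNA/tRNA genes are subtracted from intergenic space |
| `padj_cutoff` | 0.05 | BH-adjusted significance threshold |
| `pseudocount` | 1 | added to normalized condition means for finite fold changes from zero |
| `dispersion_floor` | 1e-8 | lower bound on the dispersion used in the exact test |
| `proximity_threshold` | 500 bp | strand-blind distance defining "near" a Pol III site |
| `contiguity_gap` | 0 bp | maximal gap for chaining windows / touching gene ends |
| `expression_continuity_ratio` | 0.1 | minimum window coverage relative to the chain maximum |
| `dialect` | `reverse` | strandedness of the library (dUTP-type kits are `reverse`) |

Notes on the less obvious choices:

* **Remainder rule.** A block of length `L > 500` yields `floor(L/500)`
  full windows; the remainder becomes its own window when at least
  `min_window` bases, otherwise it merges into the preceding window (so a
  window can reach `500 + min_window - 1` bases). This keeps windows
  length-comparable without discarding sequence. Blocks at or below 500
  bases form one unsplit window.
* **Left-edge anchoring.** Windows are anchored at the block's left edge
  regardless of strand. This is an assumption, not a biological claim: any
  fixed anchor gives an equivalent partition, and gene-adjacent geometry is
  recovered because the *last* window of a block always ends exactly at the
  block's right boundary.
* **Gene space.** By default both protein-coding and non-coding genes are
  subtracted from intergenic space. With
  `include_noncoding_in_genespace = FALSE` only protein-coding genes are
  subtracted, in which case tDNAs live inside intergenic blocks and
  same-strand readthrough across a tDNA becomes representable in window
  space. Both readings of "annotated gene space" are supported because the
  field uses both.
* **5'-anchor counting.** A fragment increments the same-strand region
  containing its 5'-most reference base (mate-union span for pairs; the
  paired-end mate union counts once, orphan mates singly). A point rule is
  chosen over fractional overlap because it makes counting conservation
  exact over the disjoint partition.
* **Uniqueness.** "Uniquely mapped" is operationalized as reported-hit-count
  == 1 where the aligner records it (NH tag), else mapping quality >= 10;
  both knobs are exposed because aligners differ.
* **Replicate correlation** is Pearson on `log2(count + 1)`; the transform
  is logged in the QC output since the statistic is otherwise dominated by
  the most highly expressed regions.

## The dispersion and testing path

Per-region empirical dispersion comes from the method of moments on
normalized counts: `alpha = max(0, (v - mu * xi) / mu^2)` with `v` the
within-condition sample variance pooled across conditions, `mu` the overall
normalized mean and `xi = mean(1/s_j)` the shot-noise scale. A trend
`alpha(mu) = a0 + a1/mu` is fitted by unweighted least squares, negative
fits clipped to the floor, and each region tests with
`max(empirical, fitted, floor)`. This "maximum" sharing is deliberately
conservative: a region whose replicates happen to disagree is tested with
its own inflated dispersion. With two replicates per condition the variance
estimate has two degrees of freedom, so this conservatism is substantial —
under a fully null simulation roughly 3-4% of regions reach p < 0.05
instead of the nominal 5%, and occasional strongly changed single windows
are sacrificed. That trade-off (few false discoveries at some cost in
per-window sensitivity) shapes everything downstream, including which
planted events the classifier can recover.

Numerical details: the exact-test enumeration is vectorized over all
`K + 1` splits up to `K = 10,000`; beyond that the enumeration walks
outward from the conditional mode in blocks until the neglected tail mass
is below `1e-12` of the conditional total (the distribution is unimodal, so
truncation error is bounded by the stopped tails). Observed-probability
ties use a `1 + 1e-7` relative tolerance, the usual guard for exact tests
on discrete support. `K = 0` returns p = 1 by convention. All-zero regions
report p = 1 with a flagged (NA) fold change.

## What the simulator emulates — and what it does not

`simulate_genome()` lays out gene "cassettes" along chromosomes: plain
genes, trans-acting up-regulated genes (emulating the activation of a
transcription factor regulon independent of Pol III sites), and one
cassette type per intergenic event class, each constructed so its class
geometry is unambiguous:

* *5'-extension*: tDNA, a 700-bp gap, then a gene — the gap windows are
  raised in the mutant (upstream-start transcription running into the
  gene), as at loci where a tDNA sits a few hundred bases upstream of a
  promoter;
* *3'-extension*: gene, then a convergent (opposite-strand) tDNA 550 bp
  downstream — only the window adjacent to the gene's 3' end is raised
  (termination readthrough that stops at the tDNA);
* *readthrough*: gene with a convergent tDNA 150 bp past its terminator —
  windows are raised from the gene end until well past the tDNA's far
  edge;
* *de-repression*: an isolated window one window away from the nearest
  gene, near a tDNA, raised from a silent baseline.

Event tDNAs for readthrough/3'-extension cassettes are placed on the
opposite strand (convergent orientation). This is deliberate: under the
default gene-space definition a same-strand tDNA splits the intergenic
block, so a chain could never overlap it; convergent geometry matches known
readthrough loci and keeps the default partition expressive.

Counts invert the analysis model: `NB(mean = s_j * q_i * fold, alpha)` with
log-normal gene baselines (median 100), a near-silent intergenic baseline,
true library factors `s_j`, two replicates per condition, and a planted
fold of 16 (within the 5-20-fold range of reported events). The read-level
generator emits 100-base stranded records whose 5' positions are uniform in
their region, so re-counting them reproduces the drawn matrix exactly —
that round trip is asserted in the tests.

The intergenic baseline default is 10 reads/window/sample. A 40-55M-read
yeast library covers a 12-Mb genome a few hundred-fold, so even "silent"
500-bp windows collect tens of reads, which is exactly what makes
de-repression calls with extremely small adjusted p-values possible in real
data. A baseline much below that (e.g. 0.5 reads/window) would make a
16-fold event statistically undetectable after FDR control across ~2,000
windows — the generator would then be simulating a study design that cannot
work, which is not a useful test-bed. The value is a property of the
emulated sequencing depth, not a tuning knob.

What the simulator does **not** emulate: sequencing error, fragment-length
and positional biases, PCR duplicates, splicing, overlapping gene models,
partial (graded) readthrough, antisense leakage of stranded protocols, and
biological replicate heterogeneity beyond the NB dispersion. Passing the
recovery tests therefore demonstrates the pipeline's logic and statistics,
not robustness to every artifact of real libraries.

## Problem sizes and expected behaviour

The standard synthetic scenario used throughout the tests is 200 genes, 40
tDNAs, 10 *ETC* sites, and 10 planted events per class at 16-fold with
`alpha = 0.1` and 2v2 replication (~2,200 regions). At these sizes the
pipeline recovers planted events with per-class precision and recall at or
above 0.8, and every chain called readthrough overlaps a tDNA — a hard
invariant, asserted with zero tolerance. Individual windows are
occasionally lost to the conservative dispersion path (replicate-variance
outliers), which is why recall is not 1: a 3'-extension rests on a single
diagnostic window, so one lost window is one lost event, whereas multi-window
classes degrade more gracefully. Null calibration (10,000 null NB regions,
`mu = 100`, `alpha = 0.1`) keeps the raw p < 0.05 fraction between 1% and
7%, and a simulated genome with no planted events yields at most a
small-number false-positive remainder after BH. Known library-depth factors
spanning 0.5-2x are recovered within a few percent at 2,000 regions. These
are the sizes the acceptance script (`scripts/acceptance.R`) re-runs from
scratch.

## Known limitations

* Two conditions only; no GLM designs, batch covariates, or shrinkage
  estimators of later-generation DE methods. The statistics are the classic
  exact-test pipeline by design, since the classifier consumes its output
  shape (per-window calls) directly.
* The classifier is geometric and operates on the DE table plus catalog; it
  does not re-examine base-level coverage, so a readthrough whose signal
  decays below significance just past the tDNA is classified as a
  3'-extension (the continuity requirement is per-window, at the
  `expression_continuity_ratio`).
* "Contiguity" with a gene end defaults to exact window adjacency
  (`contiguity_gap = 0`); annotations whose UTR ends are imprecise may need
  a small positive gap.
* Distance to Pol III sites is strand-blind by construction; orientation
  enters only through the gene-end contiguity rules.
* Counting assumes the partition is complete on the chromosomes the reads
  map to; reads on chromosomes absent from the size table are an error, not
  silently dropped.
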