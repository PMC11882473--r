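---
title: "Models and methods in ripintegrate"
author: "ripintegrate authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ripintegrate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ripintegrate)
```

# Overview

`ripintegrate` implements an integrative analysis of a knockdown RNA-seq
experiment and a RIP-seq (RNA immunoprecipitation sequencing) experiment for
an RNA-binding protein: which genes change expression, which splicing events
change, where the protein binds, and whether the bound transcripts are
enriched among the regulated ones.  Every stage is re-implemented from its
statistical definition so that the whole chain can be validated by parameter
recovery on synthetic data with planted truths.

The pipeline stages are:

1. **QC and counting** — raw-read filtering, strand-aware unique-fragment
   counting against a gene model, FPKM.
2. **Expression** — a minimal negative-binomial Wald screen with
   median-of-ratios normalisation.
3. **Splicing** — junction-based detection of ten alternative-splicing event
   classes, inclusion-ratio quantification and a Student t-test across
   replicates.
4. **Peak calling** — a 5-bp sliding-window scan per gene, peak assembly by
   depth-run rules, a within-gene read-shuffle permutation null, and an
   IP-versus-input fold-enrichment filter.
5. **Integration** — hypergeometric overlap of the differential genes,
   regulated-splicing genes and peak target genes, plus generic GMT-based
   over-representation with Benjamini–Hochberg control.

# Raw-read QC and counting

`filterRawReads()` applies two rules in a fixed order: reads with more than
`max_n = 2` ambiguous `N` bases are discarded first, then reads shorter than
`min_len = 16` nt.  Base-quality and adapter trimming are treated as an
upstream concern.

`countGenes()` counts one unit per uniquely mapped fragment (one BED12
record).  A fragment is assigned to a gene when every one of its blocks
intersects that gene's exon union and, for strand-specific libraries (the
default), its strand equals the gene strand.  Fragments compatible with more
than one gene are ambiguous and are counted for none — deterministic and
conservative; the ambiguous tally is reported per sample.  FPKM uses the
exon-union length: `fpkm = count * 1e9 / (length_bp * total_mapped)`.  The
choice of exon-union length (rather than a transcript-specific effective
length) is deliberate: the screen below consumes counts, and FPKM is only a
reporting unit.

# The negative-binomial screen

Counts are normalised with median-of-ratios size factors (geometric-mean
reference over genes expressed in all samples, factors rescaled to geometric
mean one).  Per gene, the dispersion $\alpha$ in
$\mathrm{Var}(K) = \mu + \alpha\mu^2$ is estimated by method of moments from
the pooled within-group variance of normalised counts, floored at $10^{-8}$.
The Wald statistic on the log2 fold-change uses the delta-method standard
error from the NB variance of each group mean (pseudo-count 0.5 on the
means).  With three replicates per group, a standard-normal reference for
this statistic is anticonservative (the moment dispersion estimate is noisy
at $n = 3$), so the statistic is referred to a Student t distribution with
$n_1 + n_2 - 2$ degrees of freedom; in null simulations at the package's
default study design this keeps the raw $p < 0.05$ rate at 4–5%, which the
acceptance suite checks against the band $[0.03, 0.07]$.

There is no dispersion shrinkage, no outlier refitting and no multi-factor
design: the screen's contract is calibration and fold-change recovery, not
feature parity with full differential-expression frameworks.  Default
thresholds for calling a gene up or down are fold change $> 1.5$ or $< 0.67$
at raw $p < 0.05$; a stricter preset (two-fold at 5% FDR) is available
because both conventions are common in knockdown screens, and the two can
disagree substantially — users should state which they used.

Two laboratory-assay helpers live in this module: relative qPCR expression
$2^{-\Delta\Delta C_T}$ and the CCK-8 proliferation rate
$(OD_{exp} - OD_{blank}) / (OD_{ctrl} - OD_{blank}) \times 100\%$.

# Splicing events from junction reads

All splicing evidence is junction reads: gaps between consecutive blocks of
a spliced alignment, keyed by chromosome, strand, donor (exonic end, 0-based
half-open) and acceptor (exonic start).  `detectEvents()` classifies
observed junctions against the annotated exon model of each gene into ten
disjoint classes:

| class | geometry |
|---|---|
| `ES` | one exclusion junction skipping exactly one annotated exon, both inclusion junctions annotated or observed |
| `cassetteExon` | the multi-exon-skip variant of `ES` |
| `A5SS` / `A3SS` | two junctions sharing an acceptor (donor) whose alternative donor (acceptor) exons overlap; names are strand-aware |
| `MXE` | two internal, non-overlapping exons with a common upstream donor and downstream acceptor and no junction joining them |
| `5pMXE` / `3pMXE` | the mutually-exclusive pattern at transcript termini: alternative first (last) exons |
| `A5SS&ES` / `A3SS&ES` | an exclusion junction that both skips an exon and uses an alternative splice site on its donor (acceptor) side |
| `IntronR` | an annotated junction whose intron is also covered by intron–exon boundary-spanning reads |

Composite classes take precedence over their components, and each junction
serves as exclusion evidence for at most one event, so the ten strata are
disjoint and significant-event totals add up over classes.  Events using at
least one un-annotated junction are flagged novel.  Because exact geometric
definitions of the terminal and composite classes vary between tools, the
rules above are this package's stated definitions, chosen so that each class
is decidable from junctions plus the exon model alone.

`quantifyEvents()` computes, per sample, the inclusion ratio
`inc / (inc + exc)` where `inc` and `exc` sum the counts of the event's
inclusion and exclusion junctions (the junction-read PSI).  For `IntronR`
the retention side cannot be seen in junction reads, so inclusion evidence
is the boundary-spanning read count and exclusion is the spliced-junction
count.  Samples with fewer than `min_cov = 10` supporting reads are flagged
undefined — a floor the annotation of real libraries needs but whose exact
value is not critical, since the downstream test also requires two defined
replicates per group.

`testRase()` applies a two-sided equal-variance Student t-test on the
per-sample ratios and BH-FDR across tested events (`fdr <= 0.05` by
default).  Events with zero variance in both groups get $p = 1$ when the
means agree and a flagged $p = 0$ when they differ (a degenerate case that
only arises at extreme coverage).  The t-test on binomial proportions is
well calibrated at the default per-event depth of 200 junction reads; the
acceptance suite verifies a 3–7% raw positive rate on null events and
recall $\ge 0.8$ at FDR 5% for planted ratio shifts of 0.3.

# RIP-seq peak calling

Peaks are called per gene from the IP library's per-base coverage:

* **Window scan.**  Windows of 5 bp advancing by 5 bp; each window scores
  its mean per-base depth; the trailing partial window keeps its actual
  width.
* **Assembly.**  A peak opens at the first window of any run of 8
  consecutive windows each at $\ge 2.5\times$ the background depth — the
  gene's mean per-base IP depth — or of any run whose median depth exceeds
  50.  The background is per-gene, not chromosome-wide, to match the
  per-gene permutation null.  An open peak extends until 8 consecutive
  windows drop below 4% of its running maximum window depth, then closes
  just before that run; abutting peaks merge.  The 4%-of-max ending rule
  presumes sparse, CLIP-like coverage in which inter-peak windows are
  mostly empty; on dense coverage it would extend peaks indefinitely.
* **Permutation null.**  Each gene's IP reads are re-placed uniformly over
  the gene span 500 times (lengths preserved, clipped at the edge); each
  shuffle records the maximum window depth over the gene.  A candidate's
  empirical p-value is $(1 + \#\{\text{shuffle max} \ge \text{candidate
  max}\}) / (1 + 500)$ — the add-one convention, so p is never exactly
  zero.  The shuffle distribution is computed once per gene and shared by
  its candidates; the shuffling loop is compiled (Rcpp) and draws from R's
  RNG, so a fixed seed reproduces every p-value exactly.
* **Filtering.**  Stage 1 keeps candidates that are permutation-significant
  ($p < 0.05$) *or* reach an absolute maximum per-base depth of 10.
  Stage 2 keeps candidates whose IP abundance exceeds 4 times the input
  abundance.  Abundance is the mean per-base depth per million mapped
  reads over the peak's *enriched core* — the windows at or above the
  opening threshold — with one pseudo-read added to the input.  Restricting
  to the core matters because the ending rule deliberately tolerates long
  low-coverage tails, which would otherwise dilute the IP/input contrast;
  counting whole reads instead of depth would likewise credit the input
  with a read-length overhang around narrow peaks.

Target genes are the de-duplicated gene assignments of the surviving peaks.
Note that an unbiased enrichment estimate is necessarily centred slightly
below the true per-base enrichment (the IP library total includes the
binding reads themselves; the input pseudo-count shrinks the ratio), so a
strict $>4\times$ filter removes roughly half of sites whose true
enrichment is exactly $4\times$.  Recovery is essentially complete from
$\sim 6\times$ upward at the default simulated depths.

# Integration and enrichment

Gene-set overlaps are tested with the exact hypergeometric upper tail
$P[X \ge x]$ for $X \sim \mathrm{Hypergeometric}(N, K, n)$.  The universe
matters more than anything else in these tests; the pipeline defaults to
all genes detected in the RNA-seq stage (non-zero count in at least one
sample), and the universe is an explicit argument everywhere.  Identifiers
are harmonised by upper-casing (a pragmatic cross-species symbol match), or
through a user-supplied two-column ortholog map.  Over-representation
against a user-supplied GMT collection performs one hypergeometric test per
term with BH-FDR across terms; no ontology structure is used.

# The synthetic-data generator

The generator is first-class, tested code; every downstream stage is
validated against its planted truths.  It emulates:

* **Annotation** — non-overlapping genes, 1.5–3 kb, separated by at least
  500 bp on one synthetic chromosome with alternating strands.  A
  configurable fraction of genes (default 0.8) carries a second transcript
  realising one of the ten event classes, cycled in pairs so that every
  class appears on both strands.
* **Expression** — a 3-vs-3 design; log-normal gene abundances scaled to
  the library size, negative-binomial counts with
  $\mathrm{Var} = \mu + \alpha\mu^2$ ($\alpha = 0.1$ by default), mild
  log-normal library-size variation, and a planted $\pm$`de_log2fc` shift
  for a fraction of genes.
* **Splicing** — per event and replicate, isoform-1 usage is binomial at
  depth 200; shifted events move the second group's inclusion ratio by
  $\pm 0.3$.  Isoform reads are split multinomially over that isoform's
  unique junctions, so summed inclusion counts recover the planted ratio
  exactly in expectation.
* **Binding** — input reads uniform over each gene body; IP libraries get
  the same uniform background (50 reads per gene by default, 30 bp reads)
  plus Poisson extra reads confined to one planted 100 bp interval per
  bound gene, raising its per-base rate to `peak_enrichment` times
  background.  Input is deeper (200 reads per gene), as input libraries
  sample the whole transcriptome.
* **Raw reads** — labelled mixtures of clean, N-containing and short reads
  for the QC filter.

The generator makes no attempt at sequence-level realism: no base
composition, no error or quality model, no adapter content, and read
placement is uniform within the gene body rather than exon-restricted —
deliberately matching the support of the permutation null.  Consequently,
passing recovery tests demonstrates the statistical machinery under the
stated models, not robustness to real-data artefacts such as positional
bias, PCR duplication structure, overlapping genes or annotation error.

Determinism: one master seed fans out to per-stage child seeds through a
stable string hash (`childSeed()`), so adding a stage never perturbs the
randomness of earlier stages; fixed seeds give byte-identical GTF, BED,
FASTQ and TSV outputs.

# Numerical and design choices

* Problem sizes in the shipped checks — 200 oracle tracks, 1000 null genes
  at 500 shuffles, 2000-gene expression simulations, 1000 null splicing
  events — were chosen so the whole suite completes in minutes on one CPU
  while keeping Monte-Carlo error well inside the asserted bands.
* Zero-count genes receive $p = 1$; fold-changes at zero means use the 0.5
  pseudo-count; the permutation p-value can never be zero by construction.
* Ties in window depths are broken by the leftmost-window convention of the
  scan; assembly is seed-free and order-independent.
* The two stated DEG threshold conventions (1.5-fold at raw p, two-fold at
  FDR) are both exposed; the looser one is the default.
* `IntronR` events require a boundary-count table; without one, no
  retention events are emitted rather than mis-using junction evidence.

# Known limitations

* The NB screen supports exactly two groups with replicates; no covariates.
* Event classification assumes a clean exon model; highly overlapping or
  fragmented annotations can suppress events (junctions whose flanks cannot
  be matched to annotated exons are left unclassified).
* The peak caller's ending rule is unsuitable for dense coverage (see
  above); on such data the whole gene becomes one candidate and the fold
  filter removes it.
* Cross-species identifier harmonisation by upper-casing is a heuristic;
  supply an ortholog map when orthology is not one-to-one by symbol.
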