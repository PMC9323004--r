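---
title: "Clonotype fate bias in paired scRNA-seq/scTCR-seq data: models and methods"
author: "clonofate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonotype fate bias: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`clonofate` analyses paired single-cell gene expression and TCR
repertoire data of the kind produced by droplet-based scRNA-seq plus
V(D)J sequencing of antigen-specific CD4+ T cells from several animals:
quality control, construction of a simplified reference map of
transcriptional subtypes, projection-based classification of query
cells, repertoire structure (clonal expansion, privacy), and the
question at the core of the package — whether individual T cell clones
are *fate-biased*, i.e. skewed toward one transcriptional subtype beyond
what the sample-wide subtype mixture explains.

# The clonotype bias statistic

Each clonotype (the set of cells sharing an identical paired TCR
alpha/beta CDR3 sequence) has a subtype composition $f = (f_1, \dots,
f_K)$; the whole sample has a background composition $q$. The bias of a
clone is

$$ c \;=\; \max_i \frac{f_i - q_i}{1 - q_i}, $$

clamped below at 0. $c = 1$ iff the clone is composed uniquely of cells
of one subtype; $c = 0$ iff it matches the background exactly. The
normalisation by $1 - q_i$ makes enrichment in a rare subtype count as
much as enrichment in a common one. The predominant subtype is the
argmax; ties resolve toward the larger $f_i$, then label order.

Small clones reach high $c$ by chance, so significance is calibrated by
permutation (`permutationNull()`): cell-subtype labels are shuffled
across cells, clones are reassembled at their observed sizes, and $c$ is
recomputed, preserving both the clonal size structure and the global
subtype frequencies. Null means and standard deviations are summarised
per clone-size bin and each observed clone with at least `minSize = 10`
cells gets $Z = (c - \mu_{\text{bin}})/\sigma_{\text{bin}}$
(`biasZScores()`). A clone is flagged when $Z$ strictly exceeds the
threshold (default 5; the two-sided standard-normal tail at 5 is
$5.7\times10^{-7}$, reported by `biasTailProbability()`). The statistic
is one-directional, but both one- and two-sided tail p-values are
reported; flagging uses the $Z$ threshold.

Numerical choices:

* **Background $q$** is computed per sample over all clonotype-assigned
  cells, including minor subtypes. Backgrounds with any $q_i = 1$ are
  degenerate and rejected.
* **Size bins.** A clone size forms its own exact bin when at least 30
  distinct clones share it; rarer sizes pool into geometric bins
  (1, 2–5, 6–9, 10–14, 15–21, 22–46, 47–100, >100). Exact bins take
  precedence at lookup. Bins left with fewer than 30 null draws are
  merged with a neighbour (with a warning) — a defensive rule, since
  with the required `nPerm >= 100` every bin holds at least 100 draws.
* **Degenerate bins.** If a bin's null standard deviation is 0 (e.g.
  singleton clones, where $c \equiv 1$), $Z$ is reported as $+\infty$
  when $c$ exceeds the null mean and 0 otherwise, flagged in `sd_zero`.
* **`nPerm` defaults to 1000**, seeded and configurable; the null
  converges at the usual $1/\sqrt{n}$ Monte-Carlo rate and the test
  suite checks bin means against exhaustive multinomial enumeration for
  small clones.

# Quality control

`computeCellQC()` reports detected genes, total UMIs, and mitochondrial
(`mt-*`) and ribosomal (`Rps*`/`Rpl*`) percentages on the total-count
denominator. `applyQCFilters()` applies, in order:

1. fixed thresholds — genes > 700, 1500 < UMIs < 15000 (strict
   inequalities on both ends), ribosomal % < 50, mitochondrial % < 10 —
   with first-violated-rule attribution in that order;
2. a per-sample percentile trim, applied exactly once to the survivors:
   any cell strictly outside the [1st, 99th] percentile interval of any
   of the four statistics is removed. Quantiles use linear
   interpolation (R type 7) with inclusive bounds, so a cell sitting
   exactly on a percentile is kept and constant-statistic samples lose
   nobody. All four parameters are evaluated on the same survivor set
   in a single pass (the alternative — re-trimming sequentially per
   parameter — is order-dependent and was rejected for that reason).

The percentile step is deliberately not idempotent (re-applying it
re-trims the new tails); the package applies it once.

# Reference map and projection

`buildReference()` log-normalises counts (counts per 10⁴, `log1p` — the
standard convention), standardises the variable-gene panel within each
batch as a light-weight batch correction (anchor-based integration is
out of scope; synthetic batches share programs, so per-batch centring
and scaling suffices), computes a PCA embedding (`dims = 20`), builds a
shared-nearest-neighbour graph (`k = 10`) and detects modularity
communities at `resolution = 0.4`. The SNN/community step is delegated
to the Seurat implementation, on whose resolution convention these
defaults are calibrated.

Two coordinate sets are kept deliberately. Clustering runs on the
batch-corrected PCA scores; the stored reference `embedding`, however,
is the reference expression pushed through the *global* per-gene
scaling statistics and the loadings — exactly the pipeline
`projectCells()` applies to a query. Consequently self-projection
reproduces the stored embedding to machine precision, and query and
reference coordinates are always directly comparable for neighbour
search, silhouettes and label transfer.

`selectVariableGenes()` ranks genes by the biological component of a
fitted mean–variance trend and removes, by default, mitochondrial,
ribosomal, heat-shock (`Hsp*`), interferon-stimulated (`Ifit*`, `Isg*`,
`Irf7`, `Oas*`, `Mx1/2`, `Rsad2`), cell-cycle and TCR-segment genes
(panel size default 800). Excluding cycling genes keeps cycling cells
classifiable by lineage rather than by phase. All lists are
user-overridable; the built-in cell-cycle list is a core mouse S/G2M
set shipped with the package.

`annotateSubtypes()` scores marker signatures per cell with a
rank-based statistic (`scoreSignature()`) and assigns every cluster the
best-scoring subtype, merging clusters that agree — mirroring the
manual merge-and-annotate step of reference-atlas construction. The
signature score is a min–max normalised Mann–Whitney U: 1 when the
signature occupies the cell's top ranks, 0 when every signature gene
ranks beyond `maxRank` (default 1500), ~0.5 for a random set. The
min–max form (rather than $1 - U/(n\,\mathrm{maxRank})$) is chosen so
that the fully-truncated case is exactly 0.

`classifySubtypes()` transfers labels by majority vote of the `k = 20`
nearest reference cells (Euclidean distance in the 20-dimensional
space), breaking ties by summed inverse distance. The value of `k` and
the metric are package defaults — reasonable for label transfer in a
20-dimensional PCA space — not quantities inherited from any particular
reference implementation. Reference–query correspondence is audited by
per-subtype marker profiles (`subtypeProfile()`), per-subtype
silhouettes of query cells against reference subtypes
(`silhouetteBySubtype()`), per-subtype rank-sum differential expression
(`discriminantGenes()`), and a joint re-embedding
(`recalculateEmbedding()`) that flags communities with less than 25%
reference membership as putative novel states (the 25% is an artifact
choice, exposed as `novelThreshold`).

`downsampleCounts()` implements binomial thinning — every UMI retained
independently with probability $p$ — and `depthRobustness()` reports
classification agreement against full-depth labels across a fraction
grid, plus median genes/UMIs per cell, and optionally a lenient
agreement that tolerates swaps within related lineages (effector vs
memory of the same helper type).

# The synthetic cohort generator

`generateCohort()` emulates the statistical structure the analysis
assumes, so every stage is testable without any download:

* several samples ("animals"), nine default subtypes (six major, three
  minor) with a fixed background composition;
* clone-first sampling: clone sizes from a mixture law that places half
  of the clonal space in large clones (25–60 cells), the remainder in a
  truncated-geometric tail — at the default 2000 cells per sample this
  yields on the order of 20 clones above 20 cells per sample, and
  roughly half of all cells in such clones;
* per-cell subtypes multinomial in the background for unbiased clones;
  planted-bias clones receive their focal subtype with probability
  $f = q + c(1-q)$ solving the bias equation for the requested $c$
  (default target 0.8 for a planted fraction of 10% of expanded
  clones, matching the ~9–13% of biased expanded clonotypes such
  experiments report);
* negative-binomial UMI counts (dispersion 0.3) with marker means
  elevated by $e^{\text{markerLogFC}}$ in their subtype; mitochondrial
  and ribosomal genes carry realistic library shares (~5% and ~15%);
  at the defaults (2000 genes, baseline mean 1.5) cells have ~3000
  UMIs and comfortably pass the QC thresholds;
* CDR3 pairs: amino-acid strings C…F of length 10–16 with a random
  codon back-translation, so nucleotide keys are strictly finer than
  amino-acid keys; clonotypes are unique per clone and disjoint across
  samples except for explicitly planted shared clones (repertoires are
  private by construction, as observed in such cohorts);
* knobs for QC-violating cells, cycling-program cells and two-alpha
  "doublet" cells to exercise the corresponding policies.

What the generator does *not* emulate — transcriptome-wide
co-expression structure, ambient RNA, sequencing errors on CDR3s,
batch-specific depth differences — bounds what passing tests show: they
validate the statistical machinery under the stated generative model,
not performance on any particular real dataset.

# Problem sizes and determinism

The test suite exercises the pipeline at desk scale: reference cohorts
of ~1200 cells over 300 genes with 150-gene panels (at a realistic
~3500 UMIs per cell), repertoire cohorts of 2000–4000 cells, permutation
nulls of 500–10000 iterations. All stochastic steps are seeded:
identical spec and seed reproduce cohorts byte-identically, reference
builds are deterministic, and permutation nulls are reproducible.

# Known limitations

* Batch correction by per-batch standardisation assumes batches share
  subtype programs; strong batch-specific states would require proper
  anchor-based integration.
* The clustering resolution convention follows the Seurat
  implementation it delegates to; other community-detection backends
  would need recalibrated defaults.
* Clonotype keys are CDR3-only (alpha+beta); V/J segments are not part
  of the key, so distinct rearrangements converging on the same CDR3
  pair would merge (rare, and consistent with treating CDR3 pairs as
  clonal barcodes).
* The bias test conditions on the observed subtype labels; uncertainty
  in subtype classification is not propagated into the null.
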