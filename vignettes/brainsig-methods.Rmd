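---
title: "Methods: anatomic and cell-type signatures of brain diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: anatomic and cell-type signatures of brain diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainsig)
```

## The model

`brainsig` treats a brain disease as a set of risk genes and asks two
questions about that set's normative expression: *where* in the brain the
genes co-express (the anatomic signature) and *in which cell types* they
concentrate (the cellular signature). Both signatures are averages over the
gene set, so they describe the transcriptomic context of genetic risk in
the neurotypical brain — not expression changes in diseased tissue. The
underlying assumption is the co-expression hypothesis: genes that share a
spatial or cellular expression pattern are more likely to interact, so
diseases whose gene sets share a pattern plausibly share mechanism.

### Anatomic signatures

For disease $d$ with measured genes $G_d$ and subject $s$ with
structure-by-gene matrix $X^{(s)}$, the profile at structure $t$ is the
(optionally weighted) mean $\frac{1}{|G_d|}\sum_{g \in G_d} X^{(s)}_{tg}$.
Per-structure means are averaged across subjects first and z-scored across
structures last, giving one representative row per disease in z units. The
ordering matters: averaging before normalization matches the convention of
producing a single representative matrix per cohort and keeps subject
profiles comparable; the per-subject matrices retained for holdout analyses
are instead z-scored within subject, since they are only ever compared row
against row.

Weighted profiles replace the plain mean by weights from the
gene–disease-association (GDA) evidence score
$C(N_1)+M(N_2)+I(N_3)+L(N_4)$: a step function of the number of curated
sources (0, 0.3, 0.5, 0.6 for 0, 1, 2, >2), 0.2 for any animal-model
report, 0.1 for any inferred source, and 0.01 per supporting publication
capped at 0.1. The score lives in $[0,1]$ and is monotone in each count.

Diseases are grouped by agglomerative hierarchical clustering with Ward
linkage on the correlation distance $1-\rho$ between profile rows. The
`ward.D2` convention (squared distances inside the update) is used so that
results match the R `hclust` implementation most analyses of this kind
cite. Ties in nearest-neighbour searches break to the lowest disease index,
making every clustering and identifiability result deterministic.

### Identifiability and the signature code

Cross-subject identifiability asks: if I take disease $d$'s profile in
subject $s$, which disease in subject $s' \ne s$ is nearest? Tallying
nearest neighbours over all ordered subject pairs yields the frequency
that the exact disease, the same anatomic group, or the same phenotypic
class is recovered. Pearson similarity is the default metric; Euclidean
distance is available, and a mode excluding the same disease probes which
*other* disease a signature resembles. Because profiles are z-scored rows,
Pearson proximity is invariant to per-subject affine rescaling.

At a fixed structure, the rank order of the five group means (lowest = 1)
is encoded as $2^{r_1} 3^{r_2} 5^{r_3} 7^{r_4} 11^{r_5}$; unique
factorization makes the code injective over the 120 permutations, so
repeatable differential signatures can be tabulated as integers. The
largest code ($2\cdot3^2\cdot5^3\cdot7^4\cdot11^5$) exceeds 32-bit range,
so codes are returned as exact doubles. Exact ties error by default; a
stable-order policy resolves them by first occurrence when requested.

### Differential stability and module association

Differential stability (DS) of a gene is the unweighted mean, over all
subject pairs, of the Pearson correlation between the gene's regional
profiles in the two subjects, computed over the structures observed in
both. Pairs sharing fewer than three structures are skipped (two points
always correlate perfectly); if no pair remains the DS is reported as
undefined rather than silently extreme. DS is invariant to per-subject
affine transforms of expression, so platform-level scaling between donors
does not masquerade as instability.

Module association correlates each gene with each canonical eigengene
within subject, stabilizes with Fisher's $z=\operatorname{atanh}(\rho)$,
averages $z$ across subjects, and standardizes each module column to mean
0, sd 1 over all scored genes. Correlations are clipped to
$|\rho| \le 1-10^{-6}$ before the transform because $\operatorname{atanh}$
diverges at $\pm 1$ — a noise-free synthetic gene would otherwise produce
an infinite score. Standardization uses *all* scored genes, not only
disease genes, so a disease's module score is interpretable as an average
of corpus-wide z units. Disease rows are exact arithmetic means of their
member genes' standardized scores.

### Cell-type statistics

Cell-type matrices are counts-per-million (each cell-type row scaled to
$10^6$). Tau specificity,
$\tau = \sum_i (1 - x_i/\max x)/(N-1)$, is 0 for uniform expression and 1
for single-type expression, and is invariant to positive rescaling.

EWCE (expression-weighted cell-type enrichment) scores a gene set's summed
specificity — expression normalized per gene across cell types — in each
cell type against `n_perm` random background sets of the same size drawn
from all measured genes excluding the target set. p-values carry the
pseudocount $(1+k)/(B+1)$ so they are never zero, folds are observed over
null mean, and Benjamini–Hochberg FDR is applied across cell types within
each disease. Expression is CPM-normalized internally before specificity,
which makes folds and p-values invariant to library-size rescaling of the
input. Aggregation levels `class`, `subclass`, and `type` average the
expression matrix by taxonomy group before scoring. The reference
parameter for production use is 100,000 permutations; desk-scale runs and
the test suite use 1,000–2,000, which bounds the p-value floor at
$1/(B+1)$ and is the dominant Monte-Carlo error term.

Covariation maps measure, per disease, the absolute cosine similarity
between cell types over the disease's *unique* genes. Genes are
max-normalized by default so a single highly expressed gene cannot
dominate the cosine; the raw option preserves magnitudes. Each disease's
matrix is thresholded independently at mean + 1.5 sd of its off-diagonal
entries — "1.5 σ" is read as per-matrix, not pooled across diseases, since
the matrices differ in location; the multiplier and the normalization are
both configurable. Cell types with all-zero expression over the gene set
get zero rows with a warning rather than NaN.

The consensus representation is the element-wise mean of the structural
and cellular disease–disease correlation matrices. Its 2-D embedding is
delegated to a pluggable embedder; the deterministic default is classical
metric scaling (`stats::cmdscale`) on $1-r$, and any nonlinear embedder
with the same signature (e.g. UMAP) can be passed instead. The GBD ratio
of a disease — mean embedded distance to same-class diseases over mean
distance to different-class diseases — is reported as missing when a
disease has no same-class partner.

### Cross-species comparison

Human and mouse disease-by-cell-type signatures are aligned by averaging,
within species, the columns mapped to the same consensus type; consensus
types present in only one species are dropped, not zero-filled, because a
zero column would be read as biological absence of signal. The aligned
matrices are stacked and clustered jointly, and the headline statistic is
the fraction of diseases whose nearest cross-species signature (Pearson)
is the same disease. Distribution-level comparisons use the two-sample
Kolmogorov–Smirnov test with the asymptotic p-value.

## The synthetic-data generator

The generator produces the three inputs the analysis consumes, with the
study's dimensions as defaults: 6 subjects × 104 structures in 15 parent
regions; 32 modules; 40 diseases in 5 planted groups; 75 cell types in 3
classes and 20 subclasses (class/subclass levels of 7 and 20 are used
where the cross-species taxonomy is exercised).

- **Subject expression.** Each of 32 eigengenes is an independent z-scored
  random pattern over structures. A module gene's profile in each subject
  is its eigengene plus independent Gaussian noise (default sd 0.3 in
  pattern units, the level at which planted-group recovery is still
  expected to be essentially perfect); unstable genes get a fresh random
  pattern per subject, making their expected DS zero. Modules carry 120
  genes each (desk-scale; enough that disease sets of 10–14 genes can be
  drawn disjointly within a group), plus 384 unstable genes. A per-subject
  structure-dropout probability (default 0) masks whole structure rows as
  NA, never as zero, to exercise the pairwise-overlap contracts of DS and
  the profile averaging.
- **Disease sets.** Each planted group is anchored to a home module;
  members draw 90% of their genes disjointly from it and the remainder
  from a member-specific secondary module, which is what keeps same-group
  diseases mutually distinguishable at low noise — without it their
  expected profiles would be identical and exact-disease identification
  would be impossible by construction. A configurable overlap fraction
  then replaces random genes with a same-group peer's genes, planting the
  within-group sharing observed in real catalogs. Evidence counts are
  Poisson with configurable means; the curated count is shifted by +1 so
  every synthetic record has curated support.
- **Cell expression.** Every gene has a home cell type derived from its
  module; it places weight `marker_specificity` (default 0.8) there and
  spreads the rest uniformly, after which a lognormal per-(gene, type)
  jitter (sd 0.15) makes the matrix continuous — real cell-type means are
  never exactly uniform, and without the jitter permutation statistics sit
  on a coarse lattice that distorts p-value calibration checks. Setting
  the jitter to zero restores the exact boundary cases (uniform
  expression, tau exactly 0). The mouse matrix shares the base weights up
  to a lognormal species perturbation (sd 0.1); at 0 the species are
  identical on homologous types.
- **Streams.** Each generator derives its own seed from the master seed,
  so adding or dropping one generator call never perturbs another's draws.

A separate deterministic builder, `synth_study_gda()`, emulates the
*composition* of a curated study-scale catalog — 40 diseases in 7
phenotypic classes, 1,646 genes in the union, fixed class unions, unique
fractions, and two planted class intersections, with set sizes from 11 to
733 — using entirely synthetic gene identifiers. It exists so the parsing,
filtering, and set-arithmetic machinery can be exercised at realistic
scale and so overlap statistics have a rich, near-continuous pairwise
lattice; it contains no real biological content.

What the generator does **not** emulate: probe-level microarray noise,
UMI/read-count sampling, correlated module eigengenes, spatial
autocorrelation between neighbouring structures, heavy-tailed set-size
distributions within a group, or genes associated with multiple diseases
across groups. Passing recovery tests on this generator therefore
demonstrates correctness of the statistics and pipeline plumbing, not
robustness to every failure mode of real atlas data.

## Numerical and design choices

- Permutation p-values always use $(1+k)/(B+1)$, never $k/B$, so no test
  reports an exactly-zero p.
- The "percent shared genes" statistic for a phenotypic class is the mean
  pairwise Jaccard × 100 by default; intersection over the smaller set is
  available (`shared_metric = "min"`) because the normalization of the
  published percentage is ambiguous. The class-size correction shuffles
  disease-to-class labels preserving class sizes.
- One-way ANOVA at a structure uses disease-level rows (one observation
  per disease, as displayed in signature heatmaps), not subject × disease
  observations; with identical group means the F statistic is 0 and p is
  1 by convention. BH families are: across structures for ANOVA, across
  structure × group-pair for t tests.
- The DS high/low split takes a configurable quantile (default median)
  with a strict inequality; quantile 0 keeps every gene. The published
  atlas threshold (DS > 0.5284) is a corpus median, so it is a parameter
  here, not a constant.
- Zero-variance profiles error loudly and name the offending entity;
  correlation against a constant vector is undefined and silently
  propagating NaN into a linkage matrix would corrupt the tree.
- Test and acceptance problem sizes are desk-scale by design: 1,000 null
  sets × 2,000 permutations for EWCE calibration, 10–20 generator seeds
  for recovery checks, 104 × 4,224 expression matrices. These are the
  package's own choices of scale for routine verification.

## Limitations

- The statistics describe normative co-expression of risk genes; they say
  nothing about differential expression in diseased tissue.
- EWCE results depend on the cell-type taxonomy level; class-level
  aggregation can hide subclass-specific enrichment.
- The permutation tests assume gene sets are exchangeable with random
  background sets of equal size; GC-content-, length-, or
  expression-matched backgrounds are not implemented.
- With very small universes the exclusion of target genes from the EWCE
  background measurably biases the null; calibration holds at
  genome-like universe sizes.
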