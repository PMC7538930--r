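---
title: "Inferring cell-to-cell communication networks with lrnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-to-cell communication networks with lrnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrnet)
```

## The inference problem

A ligand–receptor pair database asserts which signalling proteins bind
which receptors; an annotated expression matrix says which genes each
cell type expresses. `lrnet` combines the two into a directed multigraph:
an edge (sender, ligand, receptor, receiver) claims that the sender
population can signal to the receiver population through that pair. The
inference is deliberately simple and transparent — expression of both
partners above thresholds — and makes no claim about binding kinetics,
protein abundance, spatial proximity or downstream pathway activation.
Edges are *potential* communication, to be ranked and then confirmed by a
domain expert.

Two modelling assumptions matter most. First, the unit of analysis is the
annotated cell type: the quality of upstream clustering and annotation
bounds the quality of every downstream edge. Second, communication
potential is read from mRNA, so ligands regulated post-transcriptionally
are invisible. Heteromeric ligand or receptor complexes are not modelled;
each database row is one gene to one gene.

## Summarisation and edge weights

Raw counts are normalised to counts per million per cell
(`normalise_cpm()`), with the library size computed over all genes in the
matrix — sequencing depth is a property of the cell, not of the
ligand/receptor subset. Per gene and cell type the package keeps the mean
expression, the total expression (mean × number of cells) and the
detection fraction, i.e. the share of the type's cells with a strictly
positive value (`summarise_cell_types()`).

Three per-edge weights serve different questions:

* the **mean-expression weight** (product of the two means) ranks by
  abundance and keeps housekeeping interactions;
* the **specificity weight** (product of the two specificities, each a
  mean divided by the sum of that gene's means over *all* cell types)
  ranks by exclusivity, is confined to [0, 1], and reaches 1 only when
  ligand and receptor are each expressed in a single cell type. Because
  the denominator runs over the cell types of the current dataset —
  including types failing the detection filter — specificities are
  dataset-local and not comparable across datasets;
* the **total-expression weight** (product of the two totals) folds in
  population abundance and assumes the sampling of cells is
  representative, which droplet capture and FACS gating often violate; it
  is provided but not used by the higher-level analyses.

A gene silent in every cell type would make the specificity 0/0; it is
defined as 0, which is harmless because such genes never pass the
detection filter anyway.

## Tunable parameters

`filter_settings()` bundles the thresholds:

| parameter | unit | default | role |
|---|---|---|---|
| `detection_threshold` | fraction of cells | 0.20 | a gene counts as expressed in a type when detected in at least this share of its cells |
| `expression_threshold` | expression units (CPM) | 0 | additionally require the mean expression to reach this level |
| `specificity_threshold` | dimensionless, [0, 1] | 0 | drop edges below this specificity weight |
| `strict_detection` | logical | `FALSE` | use strict `>` instead of `>=` at the detection boundary |

The 20% detection default reflects common practice for droplet-based
single-cell data; datasets with low capture efficiency warrant lowering
it, well-sampled plate-based data can take 10 CPM expression thresholds.
Whether a gene detected in *exactly* 20% of cells passes is genuinely
ambiguous in common usage; this package includes it (`>=`) and exposes
`strict_detection` so the boundary convention can be swept when
reconciling edge counts with other implementations.

## Database handling

`read_lr_pairs()` accepts the curated-database layout (ligand, receptor,
ligand location, literature evidence, source) and a minimal two-column
user dialect. Duplicated pairs are merged with their evidence unioned —
multi-source tables legitimately repeat pairs, and rejecting them would
punish the merge. An exclusion table (reviewed-and-rejected pairs) is
parsed for provenance but never enters the database. Ligands annotated as
existing in both secreted and membrane-bound forms participate in both
the secreted and the plasma-membrane analysis; consequently the two
location-filtered subsets jointly cover the database.

Cross-species projection maps each partner through homology groups and
expands one-to-many orthology to **all** combinations rather than picking
a canonical hit. The expansion is lossless — a wrong combination is
simply never expressed — whereas any canonical choice silently discards
candidates; pairs with no ortholog for either partner are dropped and
counted. Symbol matching is case-insensitive throughout (human symbols
are uppercase, mouse capitalised), while outputs keep the casing of the
input matrix.

## Summary, delta and rank analyses

Summary networks are directed cell-type × cell-type matrices, rows =
sender. Edge counting re-applies the filter settings; summed specificity
and summed expression sum their weight without a hard threshold.
Autocrine (diagonal) entries are kept in every scheme and compete in the
same pool as the off-diagonal entries when the top-k edges are taken;
ranking ties are broken lexicographically by (sender, receiver) so runs
are reproducible.

Two-condition comparisons treat the 4-tuple key as edge identity —
"present in both conditions" is presence/absence language, so weights
play no part in the matching. The label sets must be identical, because a
population present in only one condition would masquerade as biology.
Delta networks always carry both quantifications (signed difference and
log2 fold change). Fold changes are exact where both entries are
positive; where one is zero, a pseudocount of half the smallest positive
weight in either network keeps the value finite while leaving it extreme
enough to be flagged. Twofold flags (`up_in_ref` / `up_in_target`) fire
at |log2 FC| ≥ 1. The same zero-handling rule applies to per-gene
fold changes.

Rank analyses ask whether some class of summary edge (autocrine,
intra-organ, inter-organ) is more specific than the rest. Within each
cell type, its outgoing (or incoming) entries are ranked descending —
rank 1 is the most specific partner, so enrichment shows as a *smaller*
mean rank — with average ranks for ties. Ranks are pooled raw rather than
percentile-normalised: every cell type faces the same candidate partner
set, so rank ranges coincide. The null (`permutation_rank_null()`)
shuffles the ligand→receptor assignment while preserving both degree
multisets, rebuilds the summed-specificity network per shuffle, and
averages the class mean ranks; this is the conservative null in which
expression structure is kept and only the pairing knowledge is destroyed.
Hierarchical clustering of cell types uses the concatenated
outgoing-and-incoming weight vectors under 1 − Pearson correlation with
average linkage — correlation so that partner *profile*, not signal
strength, drives the grouping; both the distance and linkage are exposed
as arguments, and identical vectors are forced to distance exactly 0.

## The synthetic generator

`generate_fixture()` draws sparse non-negative count matrices with
cell-type structure: negative-binomial background (default mean 5,
dispersion 2) with independent dropout (default 0.3), defaults chosen as
an unremarkable droplet-like regime — detection fractions around 0.6 for
background genes, so the default filters neither pass nor reject
everything. Planted edges dedicate a pair whose ligand is expressed
exclusively in the sender and receptor exclusively in the receiver at
`effect_size` (default 10) times baseline, making the planted edge's
specificity weight exactly 1; planting the same gene exclusively into two
types is rejected as contradictory. Planted co-detections set a fixed
positive count in an exact fraction of one type's cells — in these small
synthetic libraries any positive count is far above realistic CPM
thresholds, so the target fraction is met exactly.

The generator emulates sparsity, cell-type-structured means, controllable
detection fractions and exclusive signal. It does **not** emulate gene–gene
correlation, batch effects, ambient contamination, doublets or realistic
library-size variation. Passing tests therefore demonstrate correctness
of the bookkeeping — filters, weights, set operations, rank statistics —
under a known truth, not robustness to real-data artefacts.

## Numerical choices and problem sizes

Weights are kept at full double precision in memory; file outputs round
to 6 significant digits. Oracle-agreement tests compare weights at 1e-12.
The test suite and the acceptance script run on fixtures of 3–8 cell
types, 20–50 cells per type, 40–120 genes and 6–12 pairs, with 20 seeds
for the recovery and agreement sweeps and 100 permutations for the null —
sizes at which every quantity can also be recomputed by the brute-force
reference implementations the tests carry.

## Limitations

Beyond the modelling assumptions above: no statistical significance is
attached to edges or to network differences (the two-condition design has
no replicates, so the comparison is descriptive); specificity weights are
not comparable across datasets; the database ships as-is and its curation
quality bounds precision; and the permutation null preserves degrees but
not any higher-order structure of the pairing graph.
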