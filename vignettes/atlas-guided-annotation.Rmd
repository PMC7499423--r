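---
title: "Atlas-guided annotation of single-cell RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-guided annotation of single-cell RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atlastype)
```

## The problem

Annotating a new single-cell RNA-seq dataset by unsupervised clustering is
laborious and unstable: clustering is unaware of existing cell-type
annotations, so reference cell types routinely split into subclusters or
merge into superclusters, and every re-run reshuffles the map.  Classifiers
that only assign known labels have the opposite problem: everything
unfamiliar lands in one undifferentiated "unknown" bin, which is exactly
the wrong behavior for tumor samples where the interesting biology is the
substructure of the unfamiliar cells.

`atlastype` threads this needle.  It compresses an annotated cell atlas
into *landmarks* — per-type average expression profiles, or a small labeled
subsample of cells per type — merges the landmarks with the new dataset,
and clusters the joint k-nearest-neighbor similarity graph with a
constrained variant of Leiden community detection in which the atlas nodes
are immutable.  Atlas cell types can then neither split nor merge, by
construction; every new cell ends up either in an atlas community
(inheriting its label) or in a community containing no atlas node, reported
as a novel cluster.

## Pipeline and model

Given a new counts table and an atlas (counts + annotation, or precomputed
landmarks), `annotate()` runs:

1. **Harmonization.** Genes are intersected (only genes present on both
   sides are retained, in the new dataset's order) and each cell is
   normalized to counts per million (CPM).  An optional raw-count QC drops
   cells below a total-count threshold (plate-based tumor data is commonly
   filtered at 1e5 reads).
2. **Landmark compression.** Either the arithmetic average of the
   CPM profiles per cell type (with the number of cells averaged), or a
   uniform random subsample of up to `n_per_type` cells per type (20 by
   default).  Ambiguous labels ("unknown", "hybrid") are excluded before
   compression.  Averages storage grows with types x genes only,
   independent of atlas size.
3. **Feature selection.** For each atlas type, the
   `n_markers_per_type = 30` genes with the largest
   `log10(mean_type + eps) - log10(max over other types + eps)` contrast —
   a marker must beat *every* other type, which prevents one dominant type
   from flooding the marker set.  To these, the `n_overdispersed = 500`
   genes with the largest Fano factor (variance/mean of CPM) in the new
   dataset are added, so types absent from the atlas still contribute
   informative features.
4. **Merge, standardize, reduce.** Landmarks and new cells are merged on
   the feature set, transformed by a zero-preserving shifted log
   (`log10(x + 0.1) - log10(0.1)`), z-scored per feature jointly across
   atlas and new columns, clipped to ±10, and reduced to `n_pcs = 20`
   principal components (deterministic SVD with a fixed sign convention).
5. **Graph.** Each *new* cell is connected to its `k_neighbors = 10`
   nearest columns — other new cells or atlas nodes — under the chosen
   metric (Pearson correlation of PC coordinates by default, weight
   `(1 + r)/2` thresholded at 0.6; euclidean with unit weights as a fully
   auditable alternative).  Atlas nodes acquire edges only through new
   cells' neighbor lists, so the graph never contains an atlas–atlas edge.
6. **Constrained clustering.** See below.
7. **Labels.** New cells in a labeled community inherit the label;
   unlabeled communities become `novel_1, novel_2, ...` in decreasing size
   order.

## The constrained Leiden step

The quality function is the constant Potts model (CPM) with node sizes:

$$Q = \sum_{c} \left[ W_c - \gamma \frac{N_c (N_c - 1)}{2} \right]$$

where $W_c$ is the intra-community edge weight and $N_c$ the summed node
sizes of community $c$.  CPM was chosen over modularity because its
resolution $\gamma$ has absolute density semantics — a community is worth
its keep only if its internal density per size-pair exceeds $\gamma$ —
which is what a very small default ($\gamma = 0.001$, useful regime below
0.01) implies.  The objective is computed by `cpm_objective()` and is
independently checkable by edge-by-edge summation.

Optimization is by greedy local-move sweeps restricted to new nodes: atlas
nodes of each type start in one frozen seed community per type, each new
cell starts as a singleton, and in seeded random order each new node moves
to the neighboring community (or a fresh singleton) with the best gain.
When node-level sweeps converge, communities are aggregated into
super-nodes and the sweeps repeat at the aggregated level, so a cohesive
group of new cells can join an atlas community as a unit; any super-node
containing atlas nodes is frozen.  The loop alternates levels until no
move improves the objective.  Because frozen communities never move, and a
move never fuses two frozen communities (there are also no atlas–atlas
edges to reward it), *no reachable state* splits an atlas type or places
two atlas labels in one community — the guarantee is structural, not
statistical, and is asserted on every run.

The refinement phase of textbook Leiden is not needed here: atlas seed
communities are frozen super-nodes, movable communities are re-aggregated
at every level, and termination is by single-move optimality, which the
test suite audits exhaustively on small graphs.  On graphs small enough to
enumerate every label-respecting partition (9 nodes, 3 labels), the sweeps
reach ≥ 99% of the exact constrained optimum in ≥ 95% of trials; the
residual gap is the usual local-optimum behavior of greedy community
detection.

**Node sizes.** An atlas *average* stands for a population, not a cell.
Each average node therefore carries size `atlas_node_size = 20` in the
size-weighted CPM objective, making one average behave like a small
population (the same scale as a 20-cell subsample).  This is the most
consequential constant that the underlying method description leaves
unstated, which is why it is an explicit, prominent parameter rather than
a buried default.

## Differential expression for novel clusters

For each novel cluster, one-vs-rest means are computed on CPM values, the
50 genes with the highest fold change
`(mean_in + 0.1)/(mean_out + 0.1)` are shortlisted, and each shortlisted
gene is scored by the two-sample Kolmogorov–Smirnov statistic
$D = \max_t |F_{in}(t) - F_{out}(t)|$ on per-cell CPM expression.  Genes
are ranked by $D$; no p-values are computed, because the ranking — not
significance — is the deliverable, so no multiple-testing machinery is
included.  $D$ is symmetric and invariant under monotone transforms, both
of which are property-tested.

## The simulator

`simulate_dataset()` generates paired (atlas, new) count matrices with
known ground truth: a shared log-normal baseline expression profile
(housekeeping structure), disjoint marker blocks per type multiplied by an
effect size and renormalized to proportions, per-cell library sizes drawn
uniformly from 5e4–1.5e5 (plate-scale depth), and negative-binomial counts
with dispersion 0.1 (variance $= \mu + 0.1\mu^2$, a typical plate-based
value).  Novel types have zero atlas cells.  The default study conditions
used by the acceptance checks are 5 known + 2 novel types, 2,000 genes,
400 new cells, 10 markers per type at 20x effect, and an atlas of 100
cells per known type subsampled to 20.

What the simulator does *not* emulate: batch effects between atlas and new
data, doublets, ambient RNA, per-gene dispersion, or gradual/continuous
cell states.  Passing tests therefore demonstrate the algorithm's
correctness and its behavior under clean type structure, not robustness to
cross-study batch effects — for those, the standalone clustering entry
point accepts a similarity graph built by an external harmonization
method (`write_graph()`/`read_graph()` TSV interchange,
`cluster_with_annotations()` on top).

`score_assignment()` reports exact-label accuracy on cells whose true type
is in the atlas and the adjusted Rand index (via `mclust`) on cells of
novel types, where predicted names are arbitrary and only the grouping can
be scored.

## Numerical and design choices

* **Marker contrast denominator**: max over other types, not the mean —
  strict upregulation, robust to dominant types.
* **Overdispersion statistic**: plain Fano factor on CPM, no mean-binning
  or loess trend; one transparent statistic, stable across library sizes.
* **Log transform**: the shifted log10 with pseudocount 0.1 CPM preserves
  zeros and sparsity while taming high-expression genes before z-scoring;
  it is configurable and applied uniformly to landmarks and new cells
  after merging, never before averaging (averages are means of CPM, not of
  log-CPM).
* **Subsampling**: uniform without replacement per type; geometry-aware
  subsampling is a known alternative but uniform is unbiased and
  reproducible with one seed.
* **Ties**: kNN ties break by column index, marker/Fano/fold-change ties
  break lexicographically by gene id, move ties prefer staying put — every
  path is deterministic given the seed.
* **Degenerate inputs**: all-zero cells are dropped with a warning after
  gene intersection; all-zero columns pass through CPM unchanged (warned);
  duplicate gene ids fail fast; a graph with no new cells returns the
  atlas seed communities unchanged.
* **Landmark files**: a TSV matrix plus JSON sidecar, values written as
  fixed-width `%.17e` so the file size depends only on the matrix shape
  (types x genes — the compression property) and doubles survive the
  round-trip exactly.
* **Problem sizes in tests**: the exhaustive-enumeration oracle runs on
  9-node graphs (3 labels + 6 new nodes, every label-respecting partition
  enumerated in canonical form); structural fidelity is checked over 200
  (graph, seed) pairs; the end-to-end study conditions above are averaged
  over 10 seeds.  These sizes were chosen so each property is tested at
  the largest scale at which its oracle is exact.

## Known limitations

* No batch-effect correction is built in; strong technical differences
  between atlas and new data will distort the joint PCA (use the custom
  graph entry point with an external harmonization).
* Cell-type labels are opaque strings; no ontology or hierarchy awareness.
* A novel cluster is any community without an atlas node — very small
  novel clusters can be noise; `min_novel_cluster_size` can flag them as
  unassigned, off by default.
* The greedy sweeps are node-optimal but not globally optimal; on adversarial
  graphs the partition can sit in a local optimum (quantified above).
* HDF5-based single-cell containers are not read directly; export to
  CSV/TSV or MatrixMarket first.
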