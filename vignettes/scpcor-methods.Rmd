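---
title: "Joint chromatin-occupancy and RNA profiling: models and methods"
author: "scpcor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint chromatin-occupancy and RNA profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The assay and the problem

scPCOR-seq measures two molecular layers in the same single cell: chromatin
occupancy — antibody-guided Protein A–MNase cleavage fragments marking a
histone modification (e.g. H3K4me3) or a chromatin-bound protein (e.g. RNA
polymerase II) — and polyadenylated plus randomly primed RNA.  Both layers
come out of one sequencing library and are distinguished purely by read
structure:

* **read2** starts with an 8-nt inline **cell barcode**, immediately
  followed by the 19-nt linker `AGAACCATGTCGTCAGTGT`, then genomic
  sequence;
* **read1** of an **RNA** pair starts with a 6-nt **UMI**, then a primer
  linker: `GAGCG` at bases 7–11 for not-so-random (NSR) primers or
  `CCTGCAGG` at bases 7–14 for oligo-dT;
* **read1** of a **chromatin (DNA)** pair is bare genomic sequence.

`scpcor` implements the complete computational workflow downstream of
sequencing: demultiplexing this read structure, deduplicating alignments
into per-cell count matrices (UMI × gene for RNA; unique fragments × peak
for chromatin), per-cell QC and two-species collision analysis, the
feature/cell inclusion rules, normalization and dimension reduction, joint
clustering of the two layers by multiplex-modularity Louvain, and the
downstream statistics (hypergeometric overlap, differential features,
CV–CV correlation, TSS-enrichment and gene-body profiles).  Read alignment
itself is out of scope: the package consumes alignment records (BED6 or
SAM/BAM) whose read names carry the demultiplexed metadata.

# Demultiplexing rules

A pair is **valid** iff read2 carries a whitelisted barcode at its 5' end
followed by the *exact* linker — matching is position-anchored, because an
unanchored substring search would make barcode extraction ambiguous.
Validated pairs are classified RNA–NSR, RNA–dT or DNA by the read1 motif
spans above; NSR is checked first and takes precedence on the (never
observed by construction, but possible in principle) event both motifs
match.  A DNA read whose bases 7–11 coincidentally spell `GAGCG` is
misclassified as RNA; this is inherent to the published rule and occurs at
the analytic rate $4^{-5} \approx 9.8\times10^{-4}$ on uniform sequence —
a property test checks exactly that rate.  One subtlety in the protocol
description: the oligo-dT primer itself is printed as
`NNNNNNGAGCGTTTT...`, which contains `GAGCG`, while the pre-processing
rule assigns `CCTGCAGG` to oligo-dT reads; the package (and its simulator)
follow the pre-processing rule, which is the self-consistent one.

Barcode sequences of the original 96-adaptor plate are not published, so
`defaultWhitelist()` generates a deterministic 96 × 8-nt whitelist at
pairwise Hamming distance ≥ 3; distance 3 makes the optional 1-mismatch
rescue (`mismatchTolerance = 1`) unambiguous.  Any user whitelist file can
be supplied instead.

# Deduplication and quantification

Chromatin reads carry no UMI, so DNA duplicates are collapsed by mapping
position: one fragment per `(cell, chrom, start, end, strand)`.  RNA reads
are assigned to genes by longest overlap (ties to the lexicographically
smallest gene id, so the result is order-independent; strand is ignored
because NSR priming produces both orientations), and collapsed to one
molecule per `(cell, gene, UMI)` regardless of position.  Reads
overlapping no gene count toward a cell's *total* UMI (deduplicated by
`(cell, UMI, position)`) but not its *useful* UMI — the useful-UMI count
equals the RNA matrix column sum by construction.  A fragment touching two
peaks counts once for the fraction-of-reads-in-peaks metric (it *is* in
peaks) but is assigned to its single longest-overlap peak in the matrix,
keeping matrix totals unit-preserving.  UMI error-correction networks
(directional collapsing of near-identical UMIs) are deliberately out of
scope.

# Barnyard collision analysis

In a deliberate two-species mixture, a barcode containing material from
both genomes is a collision (doublet).  The original analysis reports
collision rates (0.08 for RNA, 0.118 for H3K4me3 in the cell-line
experiment) without stating the calling rule, so the package makes the
rule explicit: a cell is called a species when that species holds at least
a `purity` fraction (default 0.9) of its reads, otherwise it is mixed; the
collision rate is the mixed fraction of called cells, always reported
together with the threshold, and `barnyardSweep()` exposes the
sensitivity.  Note the rate is monotone **non-decreasing** in the purity
threshold — raising the bar can only move cells into the mixed class.

# Filtering

The inclusion rules, applied feature-filter first: genes and peak regions
with reads in fewer than 30 cells are excluded; then cells need ≥ 1000 RNA
and ≥ 1000 chromatin units and non-zero counts in at least
`minNonzeroRegions` genes *and* peaks, with presets 100 (RNAPII cell-line
runs), 450 (H3K4me3 cell-line runs) and 50 (CD34/CD36 differentiation
runs).  Breadth is computed after feature filtering; the boundary
semantics ("less than 30", "at least 1000") are tested explicitly at
29/30 and 999/1000.  Whether "1000 RNA reads" means raw or deduplicated
units is not stated in the protocol; the package uses deduplicated totals
and lets the caller pass any totals table.

# Transformation and reduction

The RNA UMI matrix is transformed entrywise by $\log_2(x + 1)$; the
chromatin matrix is first library-size normalized (every cell scaled to
the **median** library size) and then log2-transformed.  Only the
chromatin matrix is depth-normalized by default because the protocol
applies library-size normalization to the read-count (DNA) matrices only;
`normalizeRna = TRUE` is available.  The pseudocount (1) is the package's
choice — a log of zero is undefined and 1 preserves sparsity structure.
PCA is computed on cells with feature centering (unit-variance scaling off
by default, flag available); 30 components by default.  The 2-D embedding
(UMAP via `uwot`, seeded, single-threaded) is a *visualization contract*
only: deterministic under a fixed seed, with no analysis result depending
on its geometry; `embedding = "pca"` substitutes the first two PCs.

# Correlation networks and the z threshold

For each modality a cell–cell Pearson correlation matrix is computed over
the PC coordinates, transformed to z scores, and edges with $z \ge 3.2$
are kept, with the z score as the edge weight.  The z transformation
deserves care.  Standardizing all off-diagonal correlations by their
global mean and SD *cannot* produce $z \ge 3.2$ for the pairs that matter
when clusters are balanced: if a fraction $p$ of pairs are within-cluster,
a clean two-mode correlation distribution bounds the largest attainable z
at $\sqrt{(1-p)/p}$ (1.41 for three balanced clusters), and by Chebyshev
at most $1/3.2^2 \approx 9.8\%$ of values can ever exceed 3.2.  The
package therefore defaults to the standard significance z score of a
Pearson correlation, the Fisher transform
$z = \operatorname{atanh}(r)\sqrt{n_{\mathrm{PC}} - 3}$, under which the
3.2 threshold corresponds to $r \ge 0.55$ at 30 PCs — a sensible edge
criterion that behaves correctly for any cluster balance.  Correlations
are clamped to $|r| \le 1 - 10^{-12}$ so numerically identical cells get a
large finite weight.  `zscoreScope = "global_offdiagonal"` and
`"per_row"` remain available for comparison.

# Multiplex-modularity Louvain

The two layers share one node set (cells).  For a partition $c$ the
package maximizes the **multiplex modularity**

$$Q = \sum_l \frac{1}{2m_l} \sum_{ij}
  \Bigl[A^l_{ij} - \gamma_l \frac{k^l_i k^l_j}{2m_l}\Bigr]
  \delta(c_i, c_j),$$

the unweighted sum of per-layer weighted Newman modularities at per-layer
resolution $\gamma_l = 1$ by default.  The optimizer is an adapted
Louvain: greedy single-node moves (gain summed across layers,
$\Delta_b \propto \sum_l [w^l_{i\to b}/m_l - \gamma_l k^l_i
\Sigma^l_b/(2m_l^2)]$), ties to the lowest community index, then
aggregation of communities into super-nodes carrying self-loops, repeated
to convergence, and a final single-node refinement pass on the original
graph so the returned partition is **single-move locally optimal** — a
property asserted exhaustively on small graphs.  Node order is shuffled
from a seeded substream, and the algorithm is restarted `restarts` times
(default 5) with derived seeds, keeping the best-Q partition; on random
≤ 8-node multiplexes this reaches the brute-force optimum (enumeration
over all set partitions) on ≥ 95% of instances.  Empty layers contribute
zero with a warning.  Leiden-style refinement and consensus clustering are
out of scope.

# Downstream statistics

* **Set overlaps** between cluster-specific features and reference
  signatures use the upper-tail hypergeometric test
  $P(X \ge k)$ with the universe fixed to the features surviving
  filtering (the testable population), reported as $-\log_{10} p$.
* **Differential features** per cluster: one-vs-rest two-sided Wilcoxon
  rank-sum on normalized values, Benjamini–Hochberg, $q < 0.05$ and
  higher mean in the cluster.  The original analysis does not state its
  differential method; this conventional default is fully parameterized.
* **CV–CV correlation** relates cell-to-cell variability across layers:
  per matched gene–peak pair, the coefficient of variation (SD/mean over
  cells, features with zero mean dropped) in each modality, then Pearson
  correlation of the paired CV vectors.  CV is scale-free, so the result
  is invariant to per-feature scaling — a property test checks this.
* **TSS enrichment**: fragment midpoints binned across ±2000 bp around
  TSSs (strand-oriented, 100 bins), each cell's curve normalized by its
  mean coverage in the outermost 5 bins per side, then averaged.  The
  window/bin/flank choices follow common chromatin-QC practice since only
  the resulting fold-enrichment is published.
* **Gene-body coverage**: each read's 5' end mapped to its gene's
  percentile position (5'→3' in transcript orientation), per-cell density
  over 100 bins normalized to sum 1, averaged over cells; uniform reads
  give a flat curve at 1/100, and genes shorter than the bin count scale
  proportionally rather than being dropped.
* **Group shifts** use the two-sided Wilcoxon rank-sum test: exact
  enumeration when the combined n ≤ 20 without ties, otherwise the
  tie-corrected normal approximation; all values tied gives p = 1.

# The simulator: what it emulates and what it does not

`simulateRun()` emits reads with exactly the read architecture above from
a pair of toy genomes (`makeToyGenomes()`: random ACGT chromosomes,
non-overlapping gene and peak models) with planted cell-type structure in
*both* modalities (`cellTypeProfiles()`: disjoint marker sets per type,
up-weighted 30× over a marker fraction of 25%).  Defaults describe the
desk-scale study conditions: 1000 barcodes, three cell types, a 0.10
doublet rate (one barcode emitting reads from two independently sampled
latent cells — the standard barnyard model, since the protocol does not
state its doublet mechanism), a 50/50 two-species mix, 100 RNA molecules
and 100 chromatin fragments per latent cell, 50/50 NSR/oligo-dT priming,
35% intergenic RNA background, 70% of chromatin fragments inside peaks,
and sequencing-error rate 0 so that every downstream oracle is exact.
Each molecule can emit Poisson-distributed PCR duplicates.  Chromatin
fragments whose read1 would coincidentally carry an RNA primer motif at
the diagnostic positions are re-sampled, so on error-free output
demultiplexing reproduces the truth for 100% of pairs, and the truth
table's feature assignments use the same longest-overlap geometry as the
quantifier, making the count matrices exactly reproducible from truth.

The simulator does **not** model realistic error profiles, PCR bias,
fragment-size distributions (a single configurable length), chimeras,
ambient RNA, or batch effects; passing tests therefore demonstrate the
correctness of the *rules* (demultiplexing, deduplication, counting,
filtering, clustering) under the assay's read structure, not robustness
to real-data noise.  Batch correction for multi-batch designs is likewise
out of scope: the reduction step accepts a pre-corrected matrix.

# Problem sizes and numerical choices

The bundled test and acceptance runs use 60–1000 cells, ~40–220k read
pairs, genomes of 2 × 200 kb per species with 60 genes and 80 peaks, and
30 PCs — sizes chosen so the full suite exercises every stage end-to-end
in a couple of minutes on one CPU while keeping all counting oracles
exact.  Degenerate inputs are contract errors rather than silent results:
zero-depth cells in normalization, constant PC vectors or a degenerate
correlation matrix in network construction, fewer than 3 defined CV
pairs, no fragment near any TSS.  Modularity comparisons use a 1e-12
move-gain tolerance; determinism everywhere comes from a single seed with
named substreams (`withSeed` restores the caller's RNG state, so package
calls never perturb user scripts).

# Known limitations

* The collision rate depends on the declared purity threshold; the
  published rates come without one, so numeric agreement with them is not
  a well-posed target — the package instead validates recovery of the
  *planted* mixed fraction.
* Gene assignment is interval-based (no splice awareness); reads are
  assigned to at most one gene.
* The exact trimming parameters behind the original multi-pass mapping
  are not published; `mergePasses()` implements the stated
  first-mapped-wins combination over any user-supplied passes.
* With very sparse layers the Fisher-z threshold can isolate low-depth
  cells, which then form singleton communities; the filtering step is the
  intended guard.
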