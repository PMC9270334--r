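# scpcor

Processing and joint analysis of **scPCOR-seq** data — an assay that
profiles chromatin occupancy (ChIC-style Protein A–MNase cleavage
fragments marking a histone modification such as H3K4me3, or a
chromatin-bound protein such as RNA polymerase II) *and* RNA from the
same single cell, in one sequencing library.

The two modalities are separated purely by read structure: read2 carries
an 8-nt cell barcode followed by the linker `AGAACCATGTCGTCAGTGT`; RNA
read1 starts with a 6-nt UMI and a primer motif (`GAGCG` at bases 7–11
for not-so-random primers, `CCTGCAGG` at bases 7–14 for oligo-dT), while
chromatin read1 is bare genomic sequence. `scpcor` implements the
complete workflow downstream of sequencing, for analysts working with
this class of joint single-cell assays:

* **demux** — validate pairs (anchored exact linker, whitelisted
  barcode), classify RNA vs DNA, extract UMIs, write per-barcode FASTQ
  sets;
* **quantify** — deduplicate alignments (DNA by position per cell; RNA
  by cell × gene × UMI) into sparse UMI × gene and fragment × peak
  matrices (`FeatureMatrix`, a `RangedSummarizedExperiment`);
* **qc** — per-cell metrics (total/useful UMI, fraction of reads in
  peaks, features detected) and the two-species barnyard collision rate
  at an explicit purity threshold;
* **filters** — the published inclusion rules (features in ≥ 30 cells;
  cells with ≥ 1000 units per modality and enough non-zero regions, with
  presets 100/450/50);
* **transform/embed** — log2(x+1), median library-size normalization for
  the chromatin layer, PCA, seeded UMAP;
* **multiplex clustering** — cell–cell Pearson correlation networks on
  PC coordinates, Fisher r-to-z scores thresholded at z ≥ 3.2, and a
  from-scratch **multiplex-modularity Louvain** that jointly clusters
  the RNA and chromatin layers by maximizing
  `Q = Σ_l Q_l` (sum of per-layer weighted Newman modularities of one
  shared partition);
* **stats** — hypergeometric overlap heatmaps, one-vs-rest Wilcoxon
  differential features (BH, q < 0.05), CV–CV correlation across
  modalities, TSS-enrichment and gene-body coverage profiles;
* **simulate** — a first-class synthetic-read generator with complete
  truth tables (two species, planted cell types in both modalities,
  configurable doublet rate, exact read architecture), so every stage is
  testable without external data.

Read alignment itself is out of scope: the package consumes BED6 or
SAM/BAM records whose read names carry the demultiplexed metadata
(`<pairid>:BC:<barcode>:UMI:<umi|->:MOD:<RNA|DNA>`), and
`truthAlignments()` provides aligner-free records for simulated runs.

## Worked example

```r
library(scpcor)

genomes <- makeToyGenomes(seed = 1)            # two toy species
cfg <- SimConfig(nCells = 300L, seed = 1L)     # 10% doublets, 2 x 100 units/cell
res <- runPipeline("readme_run", cfg, genomes = genomes)

s <- res$manifest$stage_summary
cat("valid pairs:", s$valid_pairs, "/", s$total_pairs, "\n")
cat("cells retained:", s$cells_retained, "\n")
cat("clusters:", s$n_clusters, " multiplex Q:", round(s$multiplex_Q, 3), "\n")
cat("collision rate at purity 0.9:", s$collision_rate, "\n")
res$matrices$rna
res$partition
```

```
valid pairs: 66800 / 66800
cells retained: 300
clusters: 6  multiplex Q: 1.587
collision rate at purity 0.9: 0.04333333
FeatureMatrix (RNA): 120 features x 300 cells, 8909 non-zero entries
Partition: 300 cells in 6 communities
  multiplex Q = 1.58725 ( per layer: 0.7968, 0.7904 )
```

All 66,800 simulated pairs validate (error-free simulation), the joint
Louvain finds the 6 planted (species × cell-type) groups with a multiplex
modularity of 1.59 summed over the RNA and chromatin layers, and the
barnyard call at purity 0.9 flags 4.3% of barcodes as cross-species
collisions — the simulation's true mixed fraction under a 10% doublet
rate with a 50/50 species mix. The run directory holds the per-barcode
FASTQ sets, MatrixMarket matrices, QC tables, edge lists, cluster
assignments, profile curves and a manifest with seeds and checksums;
reruns with the same config are bit-identical.

A thin CLI over the same functions ships in `inst/scripts/scpcor.R`
(`simulate`, `demux`, `barnyard`, `run` subcommands).

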