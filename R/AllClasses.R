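#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#' @importFrom BiocGenerics strand<-
#' @importFrom Biostrings DNAStringSet
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

## ---------------------------------------------------------------------------
## ToyGenome
## ---------------------------------------------------------------------------

#' Toy genome for simulation
#'
#' A miniature genome for one species: chromosome sequences plus gene and
#' peak annotations.  Used by the read simulator so that the whole pipeline
#' can be exercised without a reference genome.
#'
#' @slot speciesLabel single species name, e.g. `"speciesA"`.
#' @slot chromosomes a [Biostrings::DNAStringSet] of chromosome sequences.
#' @slot genes a [GenomicRanges::GRanges] with metadata column `gene_id`;
#'   strand is meaningful (transcript orientation).
#' @slot peaks a [GenomicRanges::GRanges] with metadata column `peak_id`.
#'
#' @export
setClass("ToyGenome",
    representation(
        speciesLabel = "character",
        chromosomes  = "DNAStringSet",
        genes        = "GRanges",
        peaks        = "GRanges"
    )
)

setValidity("ToyGenome", function(object) {
    msg <- character()
    if (length(object@speciesLabel) != 1L)
        msg <- c(msg, "speciesLabel must be a single string")
    freq <- Biostrings::alphabetFrequency(object@chromosomes, baseOnly = TRUE)
    if (length(object@chromosomes) && any(freq[, "other"] > 0))
        msg <- c(msg, "chromosome sequences must contain only A, C, G, T")
    lens <- stats::setNames(Biostrings::width(object@chromosomes),
                            names(object@chromosomes))
    checkBounds <- function(gr, what) {
        if (!length(gr)) return(NULL)
        chr <- as.character(seqnames(gr))
        if (!all(chr %in% names(lens)))
            return(sprintf("%s reference unknown chromosomes", what))
        if (any(start(gr) < 1L) || any(end(gr) > lens[chr]))
            return(sprintf("%s extend beyond chromosome bounds", what))
        NULL
    }
    msg <- c(msg, checkBounds(object@genes, "genes"),
                  checkBounds(object@peaks, "peaks"))
    if (length(msg)) msg else TRUE
})

setMethod("show", "ToyGenome", function(object) {
    cat("ToyGenome:", object@speciesLabel, "\n",
        " ", length(object@chromosomes), "chromosome(s),",
        sum(Biostrings::width(object@chromosomes)), "bp total\n",
        " ", length(object@genes), "genes,",
        length(object@peaks), "peaks\n")
})

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Parameters of the synthetic scPCOR-seq run.  Defaults describe a
#' desk-scale two-species mixture: 1000 barcodes, three planted cell types,
#' a 10\% doublet rate (one barcode carrying material from two independent
#' cells), 100 RNA molecules and 100 chromatin fragments per cell, 6-nt
#' UMIs, and error-free reads so downstream oracles are exact.
#'
#' @slot nCells number of cell barcodes emitted.
#' @slot nCellTypes number of planted cell types.
#' @slot doubletRate probability a barcode is a doublet.
#' @slot rnaPerCell RNA molecules per latent cell.
#' @slot dnaPerCell chromatin fragments per latent cell.
#' @slot barcodeLength inline barcode length (default 8).
#' @slot umiLength UMI length; fixed at 6 by the primer design
#'   (`NNNNNN` preceding the primer linker).
#' @slot readLen1,readLen2 read lengths.
#' @slot seed integer seed; all randomness derives from it.
#' @slot speciesMix fraction of latent cells drawn from species 2.
#' @slot nsrFraction fraction of RNA molecules primed by not-so-random
#'   primers (`GAGCG` linker); the rest are oligo-dT (`CCTGCAGG`).
#' @slot meanDuplicates mean number of extra (PCR-duplicate) read pairs
#'   per molecule/fragment (Poisson).
#' @slot fragmentLength simulated insert length.
#' @slot fripTarget probability a chromatin fragment falls in a peak.
#' @slot rnaBackground fraction of RNA molecules sampled from intergenic
#'   background (these count toward total but usually not useful UMI).
#' @slot errorRate per-base substitution rate injected into reads
#'   (default 0 so demultiplexing oracles are exact).
#'
#' @export
setClass("SimConfig",
    representation(
        nCells = "integer", nCellTypes = "integer", doubletRate = "numeric",
        rnaPerCell = "integer", dnaPerCell = "integer",
        barcodeLength = "integer", umiLength = "integer",
        readLen1 = "integer", readLen2 = "integer",
        seed = "integer", speciesMix = "numeric", nsrFraction = "numeric",
        meanDuplicates = "numeric", fragmentLength = "integer",
        fripTarget = "numeric", rnaBackground = "numeric",
        errorRate = "numeric"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@umiLength != 6L)
        msg <- c(msg, "umiLength is fixed at 6 by the primer design")
    for (s in c("doubletRate", "speciesMix", "nsrFraction", "fripTarget",
                "rnaBackground", "errorRate")) {
        v <- slot(object, s)
        if (v < 0 || v > 1) msg <- c(msg, paste(s, "must lie in [0, 1]"))
    }
    if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
    if (object@nCellTypes < 1L) msg <- c(msg, "nCellTypes must be >= 1")
    if (object@readLen2 < object@barcodeLength + 19L + 1L)
        msg <- c(msg, "readLen2 too short for barcode + linker + insert")
    if (object@readLen1 < 15L)
        msg <- c(msg, "readLen1 too short for UMI + primer linker + insert")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class constructor with study-condition defaults.
#' @param nCells,nCellTypes,doubletRate,rnaPerCell,dnaPerCell,barcodeLength
#'   see slots.
#' @param umiLength,readLen1,readLen2,seed,speciesMix,nsrFraction see slots.
#' @param meanDuplicates,fragmentLength,fripTarget,rnaBackground,errorRate
#'   see slots.
#' @export
SimConfig <- function(nCells = 1000L, nCellTypes = 3L, doubletRate = 0.1,
                      rnaPerCell = 100L, dnaPerCell = 100L,
                      barcodeLength = 8L, umiLength = 6L,
                      readLen1 = 50L, readLen2 = 75L, seed = 1L,
                      speciesMix = 0.5, nsrFraction = 0.5,
                      meanDuplicates = 0, fragmentLength = 150L,
                      fripTarget = 0.7, rnaBackground = 0.35,
                      errorRate = 0) {
    new("SimConfig",
        nCells = as.integer(nCells), nCellTypes = as.integer(nCellTypes),
        doubletRate = doubletRate, rnaPerCell = as.integer(rnaPerCell),
        dnaPerCell = as.integer(dnaPerCell),
        barcodeLength = as.integer(barcodeLength),
        umiLength = as.integer(umiLength),
        readLen1 = as.integer(readLen1), readLen2 = as.integer(readLen2),
        seed = as.integer(seed), speciesMix = speciesMix,
        nsrFraction = nsrFraction, meanDuplicates = meanDuplicates,
        fragmentLength = as.integer(fragmentLength), fripTarget = fripTarget,
        rnaBackground = rnaBackground, errorRate = errorRate)
}

#' Demultiplexing configuration
#'
#' Read-structure constants of the assay and the barcode whitelist.  A read
#' pair is valid when read2 carries a whitelisted barcode at its 5' end
#' followed immediately by the exact 19-nt linker.  Valid pairs are RNA if
#' read1 bases 7-11 equal the not-so-random primer linker `GAGCG`, or bases
#' 7-14 equal the oligo-dT linker `CCTGCAGG`; all remaining valid pairs are
#' chromatin (DNA).  RNA UMIs are read1 bases 1-6.
#'
#' @slot read2Linker linker expected right after the barcode on read2.
#' @slot nsrLinker,dtLinker RNA primer motifs on read1.
#' @slot nsrSpan,dtSpan,umiSpan 1-based inclusive spans on read1.
#' @slot whitelist character vector of equal-length barcodes.
#' @slot mismatchTolerance allowed barcode mismatches (0 or 1).
#'
#' @export
setClass("DemuxConfig",
    representation(
        read2Linker = "character", nsrLinker = "character",
        dtLinker = "character", nsrSpan = "integer", dtSpan = "integer",
        umiSpan = "integer", whitelist = "character",
        mismatchTolerance = "integer"
    )
)

setValidity("DemuxConfig", function(object) {
    msg <- character()
    if (diff(object@nsrSpan) + 1L != nchar(object@nsrLinker))
        msg <- c(msg, "nsrSpan length must equal nsrLinker length")
    if (diff(object@dtSpan) + 1L != nchar(object@dtLinker))
        msg <- c(msg, "dtSpan length must equal dtLinker length")
    wl <- object@whitelist
    if (length(wl)) {
        if (length(unique(nchar(wl))) != 1L)
            msg <- c(msg, "whitelist barcodes must be equal length")
        if (anyDuplicated(wl))
            msg <- c(msg, "whitelist barcodes must be unique")
    }
    if (!object@mismatchTolerance %in% c(0L, 1L))
        msg <- c(msg, "mismatchTolerance must be 0 or 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn DemuxConfig-class constructor with assay defaults.
#' @param read2Linker,nsrLinker,dtLinker,nsrSpan,dtSpan,umiSpan see slots.
#' @param whitelist barcode whitelist; defaults to [defaultWhitelist()].
#' @param mismatchTolerance see slots.
#' @export
DemuxConfig <- function(whitelist = defaultWhitelist(),
                        read2Linker = "AGAACCATGTCGTCAGTGT",
                        nsrLinker = "GAGCG", dtLinker = "CCTGCAGG",
                        nsrSpan = c(7L, 11L), dtSpan = c(7L, 14L),
                        umiSpan = c(1L, 6L), mismatchTolerance = 0L) {
    new("DemuxConfig", read2Linker = read2Linker, nsrLinker = nsrLinker,
        dtLinker = dtLinker, nsrSpan = as.integer(nsrSpan),
        dtSpan = as.integer(dtSpan), umiSpan = as.integer(umiSpan),
        whitelist = whitelist,
        mismatchTolerance = as.integer(mismatchTolerance))
}

#' Cell and feature filtering configuration
#'
#' Inclusion rules applied before clustering: a feature (gene or peak) is
#' kept when it has reads in at least `minCellsPerFeature` cells; a cell is
#' kept when it has at least `minRnaReads` RNA and `minDnaReads` chromatin
#' units and non-zero counts in at least `minNonzeroRegions` genes and
#' `minNonzeroRegions` peaks (computed after feature filtering).
#'
#' @slot minCellsPerFeature integer, default 30.
#' @slot minRnaReads,minDnaReads integer, default 1000.
#' @slot minNonzeroRegions integer; presets: 100 (RNAPII cell-line runs),
#'   450 (H3K4me3 cell-line runs), 50 (CD34/CD36 differentiation runs).
#'
#' @export
setClass("FilterConfig",
    representation(minCellsPerFeature = "integer", minRnaReads = "integer",
                   minDnaReads = "integer", minNonzeroRegions = "integer"))

setValidity("FilterConfig", function(object) {
    v <- c(object@minCellsPerFeature, object@minRnaReads,
           object@minDnaReads, object@minNonzeroRegions)
    if (any(v < 0L)) "all thresholds must be >= 0" else TRUE
})

#' @describeIn FilterConfig-class constructor.
#' @param minCellsPerFeature,minRnaReads,minDnaReads,minNonzeroRegions
#'   see slots; `preset` overrides `minNonzeroRegions`.
#' @param preset one of `"rnapii"` (100), `"h3k4me3"` (450), `"cd34_cd36"`
#'   (50), or `NULL` to use `minNonzeroRegions` as given.
#' @export
FilterConfig <- function(minCellsPerFeature = 30L, minRnaReads = 1000L,
                         minDnaReads = 1000L, minNonzeroRegions = 100L,
                         preset = NULL) {
    if (!is.null(preset)) {
        preset <- match.arg(preset, c("rnapii", "h3k4me3", "cd34_cd36"))
        minNonzeroRegions <- switch(preset, rnapii = 100L, h3k4me3 = 450L,
                                    cd34_cd36 = 50L)
    }
    new("FilterConfig", minCellsPerFeature = as.integer(minCellsPerFeature),
        minRnaReads = as.integer(minRnaReads),
        minDnaReads = as.integer(minDnaReads),
        minNonzeroRegions = as.integer(minNonzeroRegions))
}

#' Transformation and embedding configuration
#'
#' @slot pseudocount added before log2 (default 1).
#' @slot nPcs number of principal components (default 30).
#' @slot seed seed for the 2-D embedding.
#' @slot embedding `"umap"` or `"pca"` (first two PCs).
#' @slot scaleFeatures scale features to unit variance before PCA.
#' @slot normalizeRna also depth-normalize the RNA matrix (default FALSE;
#'   by default only the chromatin matrix is library-size normalized).
#'
#' @export
setClass("EmbedConfig",
    representation(pseudocount = "numeric", nPcs = "integer",
                   seed = "integer", embedding = "character",
                   scaleFeatures = "logical", normalizeRna = "logical"))

setValidity("EmbedConfig", function(object) {
    msg <- character()
    if (object@pseudocount <= 0) msg <- c(msg, "pseudocount must be > 0")
    if (object@nPcs < 2L) msg <- c(msg, "nPcs must be >= 2")
    if (!object@embedding %in% c("umap", "pca"))
        msg <- c(msg, "embedding must be 'umap' or 'pca'")
    if (length(msg)) msg else TRUE
})

#' @describeIn EmbedConfig-class constructor.
#' @param pseudocount,nPcs,seed,embedding,scaleFeatures,normalizeRna see
#'   slots.
#' @export
EmbedConfig <- function(pseudocount = 1, nPcs = 30L, seed = 1L,
                        embedding = "umap", scaleFeatures = FALSE,
                        normalizeRna = FALSE) {
    new("EmbedConfig", pseudocount = pseudocount, nPcs = as.integer(nPcs),
        seed = as.integer(seed), embedding = embedding,
        scaleFeatures = scaleFeatures, normalizeRna = normalizeRna)
}

#' Multiplex clustering configuration
#'
#' @slot zThreshold minimum z-scored correlation kept as an edge
#'   (default 3.2).
#' @slot zscoreScope `"fisher"` (default: Fisher r-to-z significance
#'   score, `atanh(r) * sqrt(nPcs - 3)`), `"global_offdiagonal"`
#'   (standardize all off-diagonal correlations of a layer jointly), or
#'   `"per_row"`.
#' @slot resolution per-layer resolution gamma (recycled; default 1).
#' @slot seed Louvain node-order seed.
#' @slot maxPasses cap on aggregation levels.
#' @slot restarts independent Louvain restarts with derived node orders;
#'   the best-modularity partition is returned (default 5).
#' @slot binaryWeights use weight 1 instead of the z-score on kept edges.
#'
#' @export
setClass("ClusterConfig",
    representation(zThreshold = "numeric", zscoreScope = "character",
                   resolution = "numeric", seed = "integer",
                   maxPasses = "integer", restarts = "integer",
                   binaryWeights = "logical"))

setValidity("ClusterConfig", function(object) {
    msg <- character()
    if (is.na(object@zThreshold))
        msg <- c(msg, "zThreshold must not be NA")
    if (!object@zscoreScope %in% c("fisher", "global_offdiagonal",
                                   "per_row"))
        msg <- c(msg, "invalid zscoreScope")
    if (any(object@resolution <= 0)) msg <- c(msg, "resolution must be > 0")
    if (object@restarts < 1L) msg <- c(msg, "restarts must be >= 1")
    if (length(msg)) msg else TRUE
})

#' @describeIn ClusterConfig-class constructor.
#' @param zThreshold,zscoreScope,resolution,seed,maxPasses,restarts,binaryWeights
#'   see slots.
#' @export
ClusterConfig <- function(zThreshold = 3.2,
                          zscoreScope = "fisher",
                          resolution = 1, seed = 1L, maxPasses = 50L,
                          restarts = 5L, binaryWeights = FALSE) {
    new("ClusterConfig", zThreshold = zThreshold, zscoreScope = zscoreScope,
        resolution = resolution, seed = as.integer(seed),
        maxPasses = as.integer(maxPasses), restarts = as.integer(restarts),
        binaryWeights = binaryWeights)
}

## ---------------------------------------------------------------------------
## FeatureMatrix
## ---------------------------------------------------------------------------

#' Per-cell feature count matrix
#'
#' A [SummarizedExperiment::RangedSummarizedExperiment] holding one sparse
#' non-negative integer assay `"counts"` (features x cells) plus the
#' modality it quantifies: `"RNA"` (UMI molecules per gene) or `"DNA"`
#' (unique chromatin fragments per peak).  Feature coordinates live in
#' `rowRanges`, cell IDs in `colnames`.
#'
#' @slot modality `"RNA"` or `"DNA"`.
#'
#' @export
setClass("FeatureMatrix",
    contains = "RangedSummarizedExperiment",
    representation(modality = "character"))

setValidity("FeatureMatrix", function(object) {
    msg <- character()
    if (!object@modality %in% c("RNA", "DNA"))
        msg <- c(msg, "modality must be 'RNA' or 'DNA'")
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        m <- SummarizedExperiment::assay(object, "counts")
        if (length(m) && min(m) < 0) msg <- c(msg, "counts must be >= 0")
    }
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids must be unique")
    if (length(msg)) msg else TRUE
})

#' @describeIn FeatureMatrix-class constructor.
#' @param counts sparse or dense non-negative matrix, features x cells.
#' @param features [GenomicRanges::GRanges] of feature coordinates, one per
#'   row of `counts`, with a `gene_id` or `peak_id` column (used as
#'   rownames when `counts` has none).
#' @param modality `"RNA"` or `"DNA"`.
#' @export
FeatureMatrix <- function(counts, features, modality) {
    counts <- methods::as(methods::as(counts, "CsparseMatrix"),
                          "generalMatrix")
    idcol <- intersect(c("gene_id", "peak_id"),
                       colnames(S4Vectors::mcols(features)))
    if (is.null(rownames(counts)) && length(idcol))
        rownames(counts) <- S4Vectors::mcols(features)[[idcol[1L]]]
    names(features) <- rownames(counts)
    methods::new("FeatureMatrix",
        SummarizedExperiment::SummarizedExperiment(
            assays = list(counts = counts), rowRanges = features),
        modality = modality)
}

#' @describeIn FeatureMatrix-class modality accessor.
#' @param object,x a `FeatureMatrix`.
#' @export
setMethod("modality", "FeatureMatrix", function(object) object@modality)

#' @describeIn FeatureMatrix-class counts accessor.
#' @export
setMethod("counts", "FeatureMatrix",
    function(object) SummarizedExperiment::assay(object, "counts"))

setMethod("show", "FeatureMatrix", function(object) {
    cat("FeatureMatrix (", object@modality, "): ",
        nrow(object), " features x ", ncol(object), " cells, ",
        Matrix::nnzero(SummarizedExperiment::assay(object, "counts")),
        " non-zero entries\n", sep = "")
})

## ---------------------------------------------------------------------------
## MultiplexNetwork and Partition
## ---------------------------------------------------------------------------

#' Multiplex cell-cell network
#'
#' An ordered set of weighted undirected graph layers (e.g. an RNA layer
#' and a chromatin layer) over one shared node set of cells.  Each layer is
#' stored as a symmetric sparse adjacency matrix with zero diagonal and
#' strictly positive edge weights.
#'
#' @slot nodes character vector of cell IDs.
#' @slot layers named list of symmetric `dgCMatrix` adjacencies.
#'
#' @export
setClass("MultiplexNetwork",
    representation(nodes = "character", layers = "list"))

setValidity("MultiplexNetwork", function(object) {
    msg <- character()
    n <- length(object@nodes)
    for (nm in names(object@layers)) {
        A <- object@layers[[nm]]
        if (!methods::is(A, "sparseMatrix") || nrow(A) != n || ncol(A) != n)
            msg <- c(msg, sprintf("layer '%s' must be %d x %d sparse", nm, n, n))
        else {
            if (!Matrix::isSymmetric(A))
                msg <- c(msg, sprintf("layer '%s' must be symmetric", nm))
            if (any(Matrix::diag(A) != 0))
                msg <- c(msg, sprintf("layer '%s' must have no self-loops", nm))
            if (length(A@x) && any(A@x < 0))
                msg <- c(msg, sprintf("layer '%s' must have positive weights", nm))
        }
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn MultiplexNetwork-class constructor.
#' @param layers named list of symmetric adjacency matrices sharing one
#'   node set (rownames used as node IDs when present).
#' @export
MultiplexNetwork <- function(layers) {
    stopifnot(length(layers) >= 1L)
    if (is.null(names(layers)))
        names(layers) <- paste0("layer", seq_along(layers))
    layers <- lapply(layers, function(A)
        methods::as(methods::as(Matrix::drop0(A), "CsparseMatrix"),
                    "generalMatrix"))
    nodes <- rownames(layers[[1L]])
    if (is.null(nodes)) nodes <- as.character(seq_len(nrow(layers[[1L]])))
    methods::new("MultiplexNetwork", nodes = nodes, layers = layers)
}

setMethod("show", "MultiplexNetwork", function(object) {
    cat("MultiplexNetwork:", length(object@nodes), "cells,",
        length(object@layers), "layer(s)\n")
    for (nm in names(object@layers))
        cat(sprintf("  %s: %d edges\n", nm,
                    length(object@layers[[nm]]@x) / 2L))
})

#' Community partition of a multiplex network
#'
#' @slot membership named integer vector, cell -> community label
#'   (labels are 1..K by first appearance).
#' @slot modularityPerLayer weighted Newman modularity of the partition on
#'   each layer.
#' @slot modularity multiplex modularity: the sum over layers.
#'
#' @export
setClass("Partition",
    representation(membership = "integer", modularityPerLayer = "numeric",
                   modularity = "numeric"))

setValidity("Partition", function(object) {
    msg <- character()
    if (is.null(names(object@membership)))
        msg <- c(msg, "membership must be named by cell")
    if (anyNA(object@membership)) msg <- c(msg, "membership must be complete")
    if (abs(object@modularity - sum(object@modularityPerLayer)) > 1e-8)
        msg <- c(msg, "modularity must equal the sum of per-layer values")
    if (length(msg)) msg else TRUE
})

#' @describeIn Partition-class membership accessor.
#' @param object a `Partition`.
#' @export
setMethod("membership", "Partition", function(object) object@membership)

#' @describeIn Partition-class multiplex modularity accessor.
#' @param perLayer return the per-layer vector instead of the sum.
#' @export
setMethod("modularity", "Partition", function(object, perLayer = FALSE)
    if (perLayer) object@modularityPerLayer else object@modularity)

setMethod("show", "Partition", function(object) {
    k <- length(unique(object@membership))
    cat("Partition:", length(object@membership), "cells in", k,
        "communities\n  multiplex Q =", format(object@modularity, digits = 6),
        "( per layer:",
        paste(format(object@modularityPerLayer, digits = 4), collapse = ", "),
        ")\n")
})
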