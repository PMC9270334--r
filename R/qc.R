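#' Per-cell quality metrics
#'
#' For the RNA modality: number of UMI, number of useful UMI (within
#' genes), fraction of useful UMI, number of genes detected.  For the
#' chromatin modality: number of unique reads, number of reads in peaks,
#' fraction of reads in peaks, number of peaks detected.
#'
#' @param fm a [FeatureMatrix-class] (defines in-feature counts and
#'   features detected per cell).
#' @param totals data.table with columns `cell`, `n_total` and optionally
#'   `n_in_feature` (RNA: `n_useful` from [dedupRna()]; DNA: `n_in_peak`
#'   from [countInPeaks()]).  When `n_in_feature` is absent the matrix
#'   column sums are used.
#' @param genomeCounts optional data.table `cell`, `n_reads_genome1`,
#'   `n_reads_genome2` from [speciesCounts()] for barnyard designs.
#' @return [S4Vectors::DataFrame], one row per matrix cell: `cell`,
#'   `modality`, `n_total`, `n_in_feature`, `fraction_in_feature`,
#'   `n_features_detected` (+ per-genome counts when supplied).
#' @export
computeCellQC <- function(fm, totals = NULL, genomeCounts = NULL) {
    cellIds <- colnames(fm)
    m <- counts(fm)
    inFeat <- Matrix::colSums(m)
    detected <- Matrix::colSums(m > 0)
    nTotal <- inFeat
    if (!is.null(totals)) {
        totals <- data.table::as.data.table(totals)
        idx <- match(cellIds, totals$cell)
        nTotal <- ifelse(is.na(idx), 0, totals$n_total[idx])
        infcol <- intersect(c("n_in_feature", "n_useful", "n_in_peak"),
                            names(totals))
        if (length(infcol))
            inFeat <- ifelse(is.na(idx), 0, totals[[infcol[1L]]][idx])
    }
    out <- S4Vectors::DataFrame(
        cell = cellIds, modality = modality(fm),
        n_total = as.integer(nTotal), n_in_feature = as.integer(inFeat),
        fraction_in_feature = ifelse(nTotal > 0, inFeat / nTotal, 0),
        n_features_detected = as.integer(detected))
    if (!is.null(genomeCounts)) {
        gidx <- match(cellIds, genomeCounts$cell)
        out$n_reads_genome1 <- ifelse(is.na(gidx), 0L,
                                      genomeCounts$n_reads_genome1[gidx])
        out$n_reads_genome2 <- ifelse(is.na(gidx), 0L,
                                      genomeCounts$n_reads_genome2[gidx])
    }
    out
}

#' Per-cell read counts by species
#'
#' Splits alignment counts by genome of origin using a chromosome-name
#' prefix map, as obtained from mapping to a combined two-species
#' reference.
#'
#' @param aln tagged alignments (GRanges with `barcode`), or a data.table
#'   with `cell`/`barcode` and `chrom` columns.
#' @param genomes list of two [ToyGenome-class] objects, or a named list
#'   mapping species label to its chromosome names.
#' @return data.table `cell`, `n_reads_genome1`, `n_reads_genome2`.
#' @export
speciesCounts <- function(aln, genomes) {
    chromSets <- lapply(genomes, function(g)
        if (methods::is(g, "ToyGenome")) names(g@chromosomes) else g)
    if (methods::is(aln, "GRanges"))
        dt <- data.table::data.table(cell = aln$barcode,
                                     chrom = as.character(seqnames(aln)))
    else {
        dt <- data.table::as.data.table(aln)
        if (!"cell" %in% names(dt))
            data.table::setnames(dt, "barcode", "cell")
    }
    dt[, genome := ifelse(chrom %in% chromSets[[1L]], 1L,
                   ifelse(chrom %in% chromSets[[2L]], 2L, NA_integer_))]
    if (anyNA(dt$genome))
        stop("alignment on a chromosome of neither genome: ",
             dt$chrom[which(is.na(dt$genome))[1L]])
    dt[, .(n_reads_genome1 = sum(genome == 1L),
           n_reads_genome2 = sum(genome == 2L)), by = cell]
}

#' Barnyard (two-species) collision analysis
#'
#' Calls each barcode as species 1, species 2, or mixed: a cell is
#' assigned to a species when that species holds at least a `purity`
#' fraction of its reads, and is otherwise mixed (a collision).  The
#' collision rate is the mixed fraction of called cells.  Zero-count cells
#' are excluded from calling and reported separately.
#'
#' @param genomeCounts data.table `cell`, `n_reads_genome1`,
#'   `n_reads_genome2` (see [speciesCounts()]).
#' @param purity purity threshold in (0.5, 1].
#' @return list with `calls` (data.table `cell`, `n_reads_genome1`,
#'   `n_reads_genome2`, `call`), `collision_rate`, `purity`, `n_called`,
#'   `n_zero`.
#' @export
barnyard <- function(genomeCounts, purity = 0.9) {
    stopifnot(purity > 0.5, purity <= 1)
    dt <- data.table::as.data.table(genomeCounts)
    tot <- dt$n_reads_genome1 + dt$n_reads_genome2
    f1 <- ifelse(tot > 0, dt$n_reads_genome1 / tot, NA_real_)
    call <- rep("mixed", nrow(dt))
    call[!is.na(f1) & f1 >= purity] <- "species1"
    call[!is.na(f1) & (1 - f1) >= purity] <- "species2"
    call[tot == 0] <- "no_reads"
    dt[, call := call]
    nCalled <- sum(tot > 0)
    list(calls = dt,
         collision_rate = if (nCalled) sum(call == "mixed") / nCalled
                          else NA_real_,
         purity = purity, n_called = nCalled, n_zero = sum(tot == 0))
}

#' Collision-rate sensitivity to the purity threshold
#'
#' @param genomeCounts as in [barnyard()].
#' @param purities thresholds to sweep.
#' @return data.table `purity`, `collision_rate`.
#' @export
barnyardSweep <- function(genomeCounts,
                          purities = seq(0.6, 0.95, by = 0.05)) {
    data.table::data.table(
        purity = purities,
        collision_rate = vapply(purities, function(p)
            barnyard(genomeCounts, p)$collision_rate, numeric(1)))
}
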