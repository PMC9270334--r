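#' Deduplicate chromatin (DNA) alignments
#'
#' Chromatin reads carry no UMI; duplicates are collapsed by mapping
#' position: one fragment is retained per key `(cell, chrom, start, end,
#' strand)`.
#'
#' @param aln tagged alignments ([GenomicRanges::GRanges] with `barcode`
#'   and `modality` columns); all records must be DNA.
#' @return data.table of unique fragments: `cell`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @export
dedupDna <- function(aln) {
    if (length(aln) && any(aln$modality != "DNA"))
        stop("RNA record in DNA stream (pair ",
             aln$pair_id[which(aln$modality != "DNA")[1L]], ")")
    dt <- data.table::data.table(
        cell = aln$barcode, chrom = as.character(seqnames(aln)),
        start = start(aln), end = end(aln),
        strand = as.character(strand(aln)))
    unique(dt, by = c("cell", "chrom", "start", "end", "strand"))
}

#' Deduplicate RNA alignments into UMI molecules
#'
#' Each read is assigned to its overlapping gene (longest overlap,
#' lexicographic gene id on ties); one molecule is retained per
#' `(cell, gene, UMI)` regardless of position.  Reads overlapping no gene
#' count toward the per-cell total UMI (deduplicated by
#' `(cell, UMI, chrom, start)`) but not toward useful UMI.
#'
#' @param aln tagged RNA alignments (GRanges with `barcode`, `umi`).
#' @param genes [GenomicRanges::GRanges] with a `gene_id` column.
#' @return list with `molecules` (data.table `cell`, `feature_id`, `umi` —
#'   genic molecules only) and `totals` (data.table `cell`, `n_total`,
#'   `n_useful`).
#' @export
dedupRna <- function(aln, genes) {
    if (length(aln) && any(aln$modality == "DNA"))
        stop("DNA record in RNA stream (pair ",
             aln$pair_id[which(aln$modality == "DNA")[1L]], ")")
    if (length(aln) && anyNA(aln$umi))
        stop("RNA alignment without UMI")
    dt <- data.table::data.table(
        cell = aln$barcode, umi = aln$umi,
        chrom = as.character(seqnames(aln)), start = start(aln),
        feature_id = assignFeature(aln, genes, "gene_id"))
    genic <- unique(dt[!is.na(feature_id)],
                    by = c("cell", "feature_id", "umi"))
    nongenic <- unique(dt[is.na(feature_id)],
                       by = c("cell", "umi", "chrom", "start"))
    molecules <- genic[, c("cell", "feature_id", "umi"), with = FALSE]
    counts <- merge(genic[, .(n_useful = .N), by = cell],
                    nongenic[, .(n_bg = .N), by = cell],
                    by = "cell", all = TRUE)
    counts[is.na(n_useful), n_useful := 0L]
    counts[is.na(n_bg), n_bg := 0L]
    counts[, n_total := n_useful + n_bg]
    list(molecules = molecules,
         totals = counts[, c("cell", "n_total", "n_useful"), with = FALSE])
}

#' Build a per-cell feature count matrix
#'
#' Entry `(f, c)` is the number of deduplicated units of cell `c` assigned
#' to feature `f`.  RNA molecules arrive pre-assigned (`feature_id`);
#' chromatin fragments are assigned to the longest-overlap peak
#' (lexicographic peak id on ties) and fragments overlapping no peak are
#' dropped from the matrix.
#'
#' @param units data.table of deduplicated units: RNA `molecules` from
#'   [dedupRna()] (with `feature_id`), or fragments from [dedupDna()].
#' @param features [GenomicRanges::GRanges] of genes (`gene_id`) or peaks
#'   (`peak_id`); fixes the row order.
#' @param cells character vector declaring the column order; a unit from a
#'   cell not in this list is an error.
#' @param modality `"RNA"` or `"DNA"`.
#' @return a [FeatureMatrix-class].
#' @export
buildMatrix <- function(units, features, cells, modality) {
    idcol <- if (modality == "RNA") "gene_id" else "peak_id"
    ids <- S4Vectors::mcols(features)[[idcol]]
    if (is.null(ids))
        stop("features must carry a '", idcol, "' column")
    units <- data.table::as.data.table(units)
    if (!"feature_id" %in% names(units)) {
        gr <- GRanges(units$chrom, IRanges::IRanges(units$start, units$end))
        units <- data.table::copy(units)
        units[, feature_id := assignFeature(gr, features, idcol)]
    }
    units <- units[!is.na(feature_id)]
    if (nrow(units)) {
        missCell <- setdiff(units$cell, cells)
        if (length(missCell))
            stop("unit from undeclared cell: ", missCell[1L])
        missFeat <- setdiff(units$feature_id, ids)
        if (length(missFeat))
            stop("unit assigned to unknown feature: ", missFeat[1L])
    }
    agg <- units[, .(n = .N), by = .(feature_id, cell)]
    m <- Matrix::sparseMatrix(
        i = match(agg$feature_id, ids), j = match(agg$cell, cells),
        x = agg$n, dims = c(length(ids), length(cells)),
        dimnames = list(ids, cells))
    FeatureMatrix(m, features, modality)
}

#' Count unique fragments overlapping peaks (any overlap)
#'
#' Used for the fraction-of-reads-in-peaks QC metric: a fragment touching
#' two peaks counts once (it is *in* peaks), while the count matrix
#' assigns it to the single longest-overlap peak.
#'
#' @param fragments data.table from [dedupDna()].
#' @param peaks [GenomicRanges::GRanges] of peak regions.
#' @return data.table `cell`, `n_total` (unique fragments), `n_in_peak`.
#' @export
countInPeaks <- function(fragments, peaks) {
    gr <- GRanges(fragments$chrom,
                  IRanges::IRanges(fragments$start, fragments$end))
    hit <- rep(FALSE, nrow(fragments))
    if (length(peaks))
        hit[unique(S4Vectors::queryHits(
            GenomicRanges::findOverlaps(gr, peaks)))] <- TRUE
    dt <- data.table::data.table(cell = fragments$cell, hit = hit)
    dt[, .(n_total = .N, n_in_peak = sum(hit)), by = cell]
}

#' Write a FeatureMatrix in MatrixMarket exchange format
#'
#' Writes `<prefix>.mtx` plus `<prefix>_features.tsv` (id, chrom,
#' 0-based start, end, strand) and `<prefix>_barcodes.tsv`.
#'
#' @param fm a [FeatureMatrix-class].
#' @param prefix output path prefix.
#' @return written paths, invisibly.
#' @export
writeFeatureMatrix <- function(fm, prefix) {
    mtx <- paste0(prefix, ".mtx")
    Matrix::writeMM(counts(fm), mtx)
    rr <- SummarizedExperiment::rowRanges(fm)
    feat <- data.table::data.table(
        id = rownames(fm), chrom = as.character(seqnames(rr)),
        start = start(rr) - 1L, end = end(rr),
        strand = as.character(strand(rr)))
    ftsv <- paste0(prefix, "_features.tsv")
    btsv <- paste0(prefix, "_barcodes.tsv")
    data.table::fwrite(feat, ftsv, sep = "\t")
    writeLines(colnames(fm), btsv)
    invisible(c(mtx, ftsv, btsv))
}
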