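#' Filter features by cell prevalence
#'
#' Retains features (genes or peak regions) with non-zero counts in at
#' least `minCells` cells; a feature seen in fewer than the threshold
#' number of cells is excluded.
#'
#' @param fm a [FeatureMatrix-class].
#' @param minCells minimum number of cells with reads in the feature
#'   (default 30).
#' @return the filtered [FeatureMatrix-class].
#' @export
filterFeatures <- function(fm, minCells = 30L) {
    keep <- Matrix::rowSums(counts(fm) > 0) >= minCells
    fm[keep, ]
}

#' Filter cells by depth and breadth
#'
#' A cell is retained when it has at least `minRnaReads` RNA units and
#' `minDnaReads` chromatin units, and non-zero counts in at least
#' `minNonzeroRegions` genes and `minNonzeroRegions` peak regions.
#' Breadth is computed on the matrices as given, i.e. after
#' [filterFeatures()] when that is applied first.
#'
#' @param rna,dna RNA and DNA [FeatureMatrix-class] objects sharing one
#'   cell axis.
#' @param rnaTotals,dnaTotals optional per-cell raw totals (data.table
#'   `cell`, `n_total`); when `NULL` the matrix column sums are used.
#' @param config a [FilterConfig-class].
#' @return character vector of retained cell IDs.
#' @export
filterCells <- function(rna, dna, rnaTotals = NULL, dnaTotals = NULL,
                        config = FilterConfig()) {
    cellsR <- colnames(rna)
    cellsD <- colnames(dna)
    if (!identical(sort(cellsR), sort(cellsD)))
        stop("RNA and DNA matrices must share the same cell set")
    getTotal <- function(fm, totals) {
        tot <- Matrix::colSums(counts(fm))
        if (!is.null(totals)) {
            totals <- data.table::as.data.table(totals)
            idx <- match(colnames(fm), totals$cell)
            tot <- ifelse(is.na(idx), 0, totals$n_total[idx])
        }
        stats::setNames(tot, colnames(fm))
    }
    rnaTot <- getTotal(rna, rnaTotals)
    dnaTot <- getTotal(dna, dnaTotals)[cellsR]
    nzGenes <- stats::setNames(Matrix::colSums(counts(rna) > 0), cellsR)
    nzPeaks <- stats::setNames(Matrix::colSums(counts(dna) > 0),
                               cellsD)[cellsR]
    keep <- rnaTot >= config@minRnaReads &
        dnaTot >= config@minDnaReads &
        nzGenes >= config@minNonzeroRegions &
        nzPeaks >= config@minNonzeroRegions
    cellsR[keep]
}

#' Apply the full inclusion rule set to a matrix pair
#'
#' Feature filter first (genes and peaks seen in fewer than
#' `minCellsPerFeature` cells are excluded), then the cell filter with
#' breadth computed on the filtered features.
#'
#' @param rna,dna [FeatureMatrix-class] pair.
#' @param rnaTotals,dnaTotals optional raw per-cell totals (see
#'   [filterCells()]).
#' @param config a [FilterConfig-class].
#' @return list `rna`, `dna` (filtered matrices restricted to retained
#'   cells), `cells` (retained IDs), `summary` (counts before/after).
#' @export
applyFilters <- function(rna, dna, rnaTotals = NULL, dnaTotals = NULL,
                         config = FilterConfig()) {
    rnaF <- filterFeatures(rna, config@minCellsPerFeature)
    dnaF <- filterFeatures(dna, config@minCellsPerFeature)
    cells <- filterCells(rnaF, dnaF, rnaTotals, dnaTotals, config)
    list(rna = rnaF[, cells], dna = dnaF[, cells], cells = cells,
         summary = data.table::data.table(
             stage = c("input", "filtered"),
             genes = c(nrow(rna), nrow(rnaF)),
             peaks = c(nrow(dna), nrow(dnaF)),
             cells = c(ncol(rna), length(cells))))
}
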