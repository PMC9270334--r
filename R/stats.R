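#' Hypergeometric overlap test
#'
#' Upper-tail hypergeometric p value for the overlap of two feature sets
#' within a declared universe: `P(X >= k)` with population `N =
#' |universe|`, `|A|` successes and `|B|` draws.  This is the test behind
#' cluster-marker versus reference-signature overlap heatmaps, reported as
#' `-log10(p)`.
#'
#' @param setA,setB character vectors of feature IDs; both must be subsets
#'   of `universe`.
#' @param universe character vector of all testable features (e.g. the
#'   features surviving [filterFeatures()]).
#' @return data.frame with `size_a`, `size_b`, `universe`, `overlap`,
#'   `p_value`, `neg_log10_p`.
#' @export
hypergeomOverlap <- function(setA, setB, universe) {
    setA <- unique(setA); setB <- unique(setB)
    universe <- unique(universe)
    if (length(setdiff(setA, universe)) || length(setdiff(setB, universe)))
        stop("setA and setB must be subsets of the universe")
    k <- length(intersect(setA, setB))
    p <- stats::phyper(k - 1L, length(setA),
                       length(universe) - length(setA), length(setB),
                       lower.tail = FALSE)
    data.frame(size_a = length(setA), size_b = length(setB),
               universe = length(universe), overlap = k, p_value = p,
               neg_log10_p = -log10(p))
}

#' Pairwise overlap matrix of feature-set collections
#'
#' @param setsA,setsB named lists of feature-ID vectors.
#' @param universe as in [hypergeomOverlap()].
#' @return matrix of `-log10(p)`, rows = `setsA`, columns = `setsB`.
#' @export
overlapHeatmap <- function(setsA, setsB, universe) {
    m <- matrix(NA_real_, length(setsA), length(setsB),
                dimnames = list(names(setsA), names(setsB)))
    for (i in seq_along(setsA))
        for (j in seq_along(setsB))
            m[i, j] <- hypergeomOverlap(setsA[[i]], setsB[[j]],
                                        universe)$neg_log10_p
    m
}

#' Cluster-specific differential features
#'
#' One-vs-rest two-sided Wilcoxon rank-sum test per feature; features with
#' Benjamini-Hochberg adjusted q below `alpha` and a higher mean in the
#' cluster form its specific set.  Clusters of fewer than 2 cells are
#' excluded with a warning.
#'
#' @param x normalized values, features x cells (e.g. [transformRna()]
#'   output), or a [FeatureMatrix-class] (log2(x+1) applied).
#' @param membership cluster labels, named by cell or in column order.
#' @param alpha BH-adjusted significance cutoff (default 0.05).
#' @return named list (one element per cluster) of data.tables
#'   `feature_id`, `p`, `q`, `delta_mean`, plus attribute `"sets"` — the
#'   significant feature-ID vectors.
#' @export
differentialFeatures <- function(x, membership, alpha = 0.05) {
    if (methods::is(x, "FeatureMatrix")) x <- transformRna(x)
    if (!is.null(names(membership))) membership <- membership[colnames(x)]
    if (length(membership) != ncol(x) || anyNA(membership))
        stop("membership must label every cell")
    cl <- unique(membership)
    if (length(cl) < 2L) stop("need at least 2 clusters")
    res <- list()
    for (cc in cl) {
        inC <- membership == cc
        if (sum(inC) < 2L) {
            warning("cluster ", cc, " has fewer than 2 cells; excluded")
            next
        }
        p <- apply(x, 1L, function(v)
            if (stats::sd(v) == 0) 1
            else suppressWarnings(
                stats::wilcox.test(v[inC], v[!inC])$p.value))
        q <- stats::p.adjust(p, method = "BH")
        delta <- rowMeans(x[, inC, drop = FALSE]) -
            rowMeans(x[, !inC, drop = FALSE])
        res[[as.character(cc)]] <- data.table::data.table(
            feature_id = rownames(x), p = p, q = q, delta_mean = delta)
    }
    attr(res, "sets") <- lapply(res, function(d)
        d$feature_id[d$q < alpha & d$delta_mean > 0])
    res
}

#' Correlation of per-feature cell-to-cell variability across modalities
#'
#' For matched gene-peak pairs, computes the coefficient of variation
#' (SD/mean over cells) of each feature in each modality and returns the
#' Pearson correlation of the paired CV vectors — the statistic linking
#' cell-to-cell variability in expression with variability in occupancy.
#' Features with zero mean in either modality are dropped.
#'
#' @param rna,dna matrices (features x cells) or [FeatureMatrix-class]
#'   objects; raw or normalized values (CV is invariant to per-feature
#'   positive scaling).
#' @param pairMap data.frame with columns `gene_id`, `peak_id`.
#' @param cells optional cell subset (e.g. one cell type).
#' @return list `r` (Pearson correlation), `n` (pairs used), `cv`
#'   (data.table `gene_id`, `peak_id`, `cv_rna`, `cv_dna`).
#' @export
cvCorrelation <- function(rna, dna, pairMap, cells = NULL) {
    getM <- function(x) if (methods::is(x, "FeatureMatrix"))
        as.matrix(counts(x)) else as.matrix(x)
    mr <- getM(rna); md <- getM(dna)
    if (!is.null(cells)) {
        mr <- mr[, cells, drop = FALSE]
        md <- md[, cells, drop = FALSE]
    }
    cv <- function(m, ids) {
        m <- m[ids, , drop = FALSE]
        mu <- rowMeans(m)
        s <- apply(m, 1L, stats::sd)
        ifelse(mu > 0, s / mu, NA_real_)
    }
    cvR <- cv(mr, pairMap$gene_id)
    cvD <- cv(md, pairMap$peak_id)
    ok <- !is.na(cvR) & !is.na(cvD)
    if (sum(ok) < 3L)
        stop("fewer than 3 gene-peak pairs with defined CV")
    if (stats::sd(cvR[ok]) == 0 || stats::sd(cvD[ok]) == 0)
        stop("CV vector is constant; correlation undefined")
    list(r = stats::cor(cvR[ok], cvD[ok]), n = sum(ok),
         cv = data.table::data.table(
             gene_id = pairMap$gene_id[ok], peak_id = pairMap$peak_id[ok],
             cv_rna = cvR[ok], cv_dna = cvD[ok]))
}

#' TSS enrichment profile
#'
#' Bins fragment midpoints into `nBins` windows across +/-`window` bp
#' around each transcription start site (strand-oriented, so upstream is
#' always left), normalizes each cell's curve by its mean coverage in the
#' outermost `flankBins` bins on each side, and averages over cells.  A
#' fold-enrichment near 1 across all bins indicates uniform background.
#'
#' @param fragments data.table (`cell`, `chrom`, `start`, `end`) from
#'   [dedupDna()], or tagged alignments (GRanges with `barcode`).
#' @param tss [GenomicRanges::GRanges] of TSS positions with strand (gene
#'   models are reduced to their 5' ends).
#' @param window half-window in bp (default 2000).
#' @param nBins number of bins (default 100).
#' @param flankBins bins per side used as the background flank (default 5).
#' @return list `positions` (bin centers, bp relative to TSS), `mean`
#'   (average fold-enrichment curve), `perCell` (matrix cells x bins),
#'   `nCellsUsed`, `nCellsEmpty`.
#' @export
tssEnrichment <- function(fragments, tss, window = 2000L, nBins = 100L,
                          flankBins = 5L) {
    if (methods::is(fragments, "GRanges"))
        fragments <- data.table::data.table(
            cell = fragments$barcode,
            chrom = as.character(seqnames(fragments)),
            start = start(fragments), end = end(fragments))
    tssPos <- ifelse(as.character(strand(tss)) == "-", end(tss),
                     start(tss))
    mid <- (fragments$start + fragments$end) %/% 2L
    binw <- 2 * window / nBins
    hits <- lapply(seq_along(tss), function(t) {
        i <- which(fragments$chrom == as.character(seqnames(tss))[t] &
                   abs(mid - tssPos[t]) <= window)
        if (!length(i)) return(NULL)
        rel <- mid[i] - tssPos[t]
        if (as.character(strand(tss))[t] == "-") rel <- -rel
        bin <- pmin(nBins, pmax(1L, floor((rel + window) / binw) + 1L))
        data.table::data.table(cell = fragments$cell[i], bin = bin)
    })
    hits <- data.table::rbindlist(hits[!vapply(hits, is.null, TRUE)])
    if (nrow(hits) == 0L)
        stop("no fragment overlaps any TSS window")
    allCells <- unique(fragments$cell)
    cnt <- hits[, .N, by = .(cell, bin)]
    perCell <- matrix(0, length(allCells), nBins,
                      dimnames = list(allCells, NULL))
    perCell[cbind(match(cnt$cell, allCells), cnt$bin)] <- cnt$N
    flank <- c(seq_len(flankBins), nBins - seq_len(flankBins) + 1L)
    flankMean <- rowMeans(perCell[, flank, drop = FALSE])
    used <- flankMean > 0
    norm <- perCell[used, , drop = FALSE] / flankMean[used]
    list(positions = seq(-window + binw / 2, window - binw / 2,
                         length.out = nBins),
         mean = colMeans(norm), perCell = norm,
         nCellsUsed = sum(used),
         nCellsEmpty = length(allCells) - sum(used))
}

#' Gene body coverage profile
#'
#' Maps each RNA read to the percentile position of its 5' end within its
#' gene (5' to 3' in transcript orientation), builds a per-cell density
#' over `nBins` bins normalized to sum 1, and averages across cells.
#' Uniform reads give a flat curve near `1/nBins`.
#'
#' @param reads tagged RNA alignments (GRanges with `barcode`) or a
#'   data.table (`cell`, `chrom`, `start`, `end`).
#' @param genes [GenomicRanges::GRanges] gene models with strand; genes
#'   shorter than `nBins` bp are scaled proportionally, never dropped.
#' @param nBins number of percentile bins (default 100).
#' @return list `positions` (percentile bin midpoints 0-100), `mean`,
#'   `perCell` (matrix cells x bins), `nCellsUsed`.
#' @export
geneBodyCoverage <- function(reads, genes, nBins = 100L) {
    if (methods::is(reads, "GRanges"))
        dt <- data.table::data.table(
            cell = reads$barcode, chrom = as.character(seqnames(reads)),
            start = start(reads), end = end(reads))
    else dt <- data.table::as.data.table(reads)
    gr <- GRanges(dt$chrom, IRanges::IRanges(dt$start, dt$end))
    hits <- GenomicRanges::findOverlaps(gr, genes, select = "first")
    ok <- !is.na(hits)
    if (!any(ok)) stop("no read overlaps any gene")
    g <- hits[ok]
    neg <- as.character(strand(genes))[g] == "-"
    pos5 <- ifelse(neg, dt$end[ok], dt$start[ok])
    frac <- (pos5 - start(genes)[g]) / width(genes)[g]
    frac[neg] <- 1 - frac[neg]
    frac <- pmin(pmax(frac, 0), 1 - 1e-9)
    bin <- floor(frac * nBins) + 1L
    cnt <- data.table::data.table(cell = dt$cell[ok], bin = bin)[,
        .N, by = .(cell, bin)]
    cellsUsed <- unique(cnt$cell)
    perCell <- matrix(0, length(cellsUsed), nBins,
                      dimnames = list(cellsUsed, NULL))
    perCell[cbind(match(cnt$cell, cellsUsed), cnt$bin)] <- cnt$N
    perCell <- perCell / rowSums(perCell)
    list(positions = (seq_len(nBins) - 0.5) * (100 / nBins),
         mean = colMeans(perCell), perCell = perCell,
         nCellsUsed = length(cellsUsed))
}

#' Two-sided Wilcoxon rank-sum test between two groups
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; otherwise the normal approximation with tie correction.
#' Returns p = 1 when all values are tied across both groups.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return two-sided p value.
#' @export
wilcoxonGroupShift <- function(a, b) {
    stopifnot(length(a) > 0, length(b) > 0)
    if (length(unique(c(a, b))) == 1L) return(1)
    n <- length(a) + length(b)
    exact <- n <= 20L && !anyDuplicated(c(a, b))
    p <- suppressWarnings(
        stats::wilcox.test(a, b, alternative = "two.sided",
                           exact = exact, correct = FALSE)$p.value)
    min(1, p)
}

#' Write a profile curve as TSV
#'
#' @param profile output of [tssEnrichment()] or [geneBodyCoverage()].
#' @param path output TSV (`position`, `mean`).
#' @return the path, invisibly.
#' @export
writeProfile <- function(profile, path) {
    data.table::fwrite(data.table::data.table(
        position = profile$positions, mean = profile$mean),
        path, sep = "\t")
    invisible(path)
}
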