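#' Log-transform an RNA UMI matrix
#'
#' Entrywise `log2(count + pseudocount)`.  The RNA matrix is not
#' library-size normalized by default (only the chromatin matrix is);
#' set `normalize = TRUE` to scale cells to the median depth first.
#'
#' @param fm a [FeatureMatrix-class] (RNA) or a matrix of counts.
#' @param pseudocount added before the log (default 1).
#' @param normalize depth-normalize to the median library size first.
#' @return dense numeric matrix, features x cells.
#' @export
transformRna <- function(fm, pseudocount = 1, normalize = FALSE) {
    m <- if (methods::is(fm, "FeatureMatrix")) counts(fm) else fm
    m <- as.matrix(m)
    if (normalize) m <- normalizeDepth(m)
    log2(m + pseudocount)
}

#' Normalize and log-transform a chromatin matrix
#'
#' Per-cell counts are scaled so every library size equals the median
#' library size, then transformed entrywise by `log2(x + pseudocount)`.
#'
#' @param fm a [FeatureMatrix-class] (DNA) or a matrix of counts.
#' @param pseudocount added before the log (default 1).
#' @return dense numeric matrix, features x cells.
#' @export
transformDna <- function(fm, pseudocount = 1) {
    m <- if (methods::is(fm, "FeatureMatrix")) counts(fm) else fm
    log2(normalizeDepth(as.matrix(m)) + pseudocount)
}

normalizeDepth <- function(m) {
    depth <- colSums(m)
    if (any(depth == 0))
        stop("zero-depth cell(s): ",
             paste(utils::head(colnames(m)[depth == 0], 3L),
                   collapse = ", "),
             " (filter cells before normalizing)")
    sweep(m, 2L, stats::median(depth) / depth, `*`)
}

#' Reduce a transformed matrix to principal components and a 2-D embedding
#'
#' PCA over cells (features centered; optionally unit-variance scaled),
#' followed by a seeded 2-D embedding of the PC coordinates — UMAP by
#' default, or the first two PCs (`embedding = "pca"`).  The embedding is
#' a visualization contract only: deterministic under a fixed seed, but no
#' analysis result depends on its geometry.
#'
#' @param x dense transformed matrix, features x cells.
#' @param nPcs number of principal components (default 30; must not
#'   exceed either matrix dimension).
#' @param seed embedding seed.
#' @param embedding `"umap"` or `"pca"`.
#' @param scaleFeatures scale features to unit variance before PCA.
#' @return list with `pcs` (cells x nPcs), `embedding` (cells x 2),
#'   `varExplained` (fraction per PC).
#' @export
reduceDims <- function(x, nPcs = 30L, seed = 1L,
                       embedding = c("umap", "pca"),
                       scaleFeatures = FALSE) {
    embedding <- match.arg(embedding)
    nPcs <- as.integer(nPcs)
    if (nPcs > min(dim(x)))
        stop("nPcs (", nPcs, ") exceeds matrix dimension ",
             paste(dim(x), collapse = " x "))
    if (ncol(x) < nPcs)
        stop("fewer cells (", ncol(x), ") than requested PCs")
    xc <- t(x)                       # cells x features
    if (scaleFeatures) {
        sds <- apply(xc, 2L, stats::sd)
        keep <- sds > 0
        xc <- scale(xc[, keep, drop = FALSE])
    }
    pca <- stats::prcomp(xc, center = TRUE, scale. = FALSE, rank. = nPcs)
    pcs <- pca$x
    rownames(pcs) <- colnames(x)
    emb <- if (embedding == "umap") {
        nn <- min(15L, nrow(pcs) - 1L)
        withSeed(seed, uwot::umap(pcs, n_neighbors = nn, n_threads = 1L,
                                  n_sgd_threads = 0L))
    } else pcs[, 1:2, drop = FALSE]
    rownames(emb) <- colnames(x)
    colnames(emb) <- c("dim1", "dim2")
    list(pcs = pcs, embedding = emb,
         varExplained = (pca$sdev^2 / sum(pca$sdev^2))[seq_len(nPcs)])
}
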