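#' Cell-cell correlation network for one modality
#'
#' Computes the Pearson correlation between every pair of cells over their
#' principal-component coordinates, standardizes the correlations to z
#' scores, and keeps edges with z at or above the threshold (default 3.2).
#' Edge weights are the z scores (or 1 with `binaryWeights`).
#'
#' The default `"fisher"` scope uses the Fisher r-to-z significance
#' transform, `z = atanh(r) * sqrt(nPcs - 3)` (the standard z score of a
#' Pearson correlation; at 30 PCs the default threshold 3.2 keeps
#' `r >= 0.55`); correlations are clamped to `|r| <= 1 - 1e-12` so
#' numerically identical cells get a large finite weight.  With
#' `"global_offdiagonal"` all off-diagonal correlations of the layer are
#' standardized jointly by their mean and SD; `"per_row"` standardizes
#' each cell's correlation vector and averages the two directed z scores.
#' Note the global scope bounds the attainable z by `sqrt((1-p)/p)` for a
#' same-cluster pair fraction `p`, so with few balanced clusters it cannot
#' reach 3.2.
#'
#' @param pcs numeric matrix, cells x PCs (rownames = cell IDs).
#' @param config a [ClusterConfig-class].
#' @return symmetric sparse adjacency matrix (`dgCMatrix`) of retained
#'   edges, zero diagonal.
#' @export
correlationNetwork <- function(pcs, config = ClusterConfig()) {
    n <- nrow(pcs)
    if (n < 3L) stop("need at least 3 cells")
    sds <- apply(pcs, 1L, stats::sd)
    if (any(sds == 0))
        stop("constant PC coordinates for cell(s): ",
             paste(utils::head(rownames(pcs)[sds == 0], 3L),
                   collapse = ", "))
    r <- stats::cor(t(pcs))
    off <- r[row(r) != col(r)]
    if (config@zscoreScope == "fisher") {
        if (ncol(pcs) < 4L)
            stop("Fisher z scoring needs at least 4 PC dimensions")
        z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) *
            sqrt(ncol(pcs) - 3)
    } else if (config@zscoreScope == "global_offdiagonal") {
        s <- stats::sd(off)
        if (s == 0)
            stop("degenerate correlation matrix: all off-diagonal ",
                 "correlations identical")
        z <- (r - mean(off)) / s
    } else {
        zd <- r
        for (i in seq_len(n)) {
            v <- r[i, -i]
            s <- stats::sd(v)
            if (s == 0)
                stop("degenerate correlation row for cell ",
                     rownames(pcs)[i])
            zd[i, ] <- (r[i, ] - mean(v)) / s
        }
        z <- (zd + t(zd)) / 2
    }
    keep <- z >= config@zThreshold
    diag(keep) <- FALSE
    w <- if (config@binaryWeights) (keep * 1) else (z * keep)
    w[!keep] <- 0
    A <- methods::as(methods::as(Matrix::Matrix(w, sparse = TRUE),
                                 "CsparseMatrix"), "generalMatrix")
    dimnames(A) <- list(rownames(pcs), rownames(pcs))
    A
}

#' Build the multiplex network from per-modality PC coordinates
#'
#' @param pcsList named list of PC coordinate matrices (cells x PCs),
#'   e.g. `list(rna = ..., dna = ...)`; all must share the same cells in
#'   the same order.
#' @param config a [ClusterConfig-class].
#' @return a [MultiplexNetwork-class] with one layer per modality.
#' @export
buildMultiplexNetwork <- function(pcsList, config = ClusterConfig()) {
    cells <- rownames(pcsList[[1L]])
    for (p in pcsList)
        if (!identical(rownames(p), cells))
            stop("all layers must share one cell set in the same order")
    MultiplexNetwork(lapply(pcsList, correlationNetwork, config = config))
}

# Per-layer (weighted Newman) modularity of `membership` on adjacency A.
# A may carry self-loops (aggregated levels); diag(A)[c] is the full
# within-weight contribution of the collapsed community.
layerModularity <- function(A, membership, gamma = 1) {
    twoM <- sum(A)
    if (twoM == 0) {
        warning("empty layer contributes 0 to multiplex modularity")
        return(0)
    }
    k <- Matrix::rowSums(A)
    comm <- unique(membership)
    tri <- Matrix::summary(A)
    same <- membership[tri$i] == membership[tri$j]
    sIn <- sum(tri$x[same])                 # == sum_{c} sum_{i,j in c} A_ij
    sTot <- tapply(k, membership, sum)
    sIn / twoM - gamma * sum((sTot / twoM)^2)
}

#' Multiplex modularity of a partition
#'
#' The multiplex modularity is the sum over layers of the weighted Newman
#' modularity of one shared partition,
#' \deqn{Q = \sum_l \frac{1}{2m_l} \sum_{ij}
#'   \left[A^l_{ij} - \gamma_l \frac{k^l_i k^l_j}{2m_l}\right]
#'   \delta(c_i, c_j),}
#' the quantity greedily optimized by the multiplex Louvain algorithm.
#'
#' @param net a [MultiplexNetwork-class].
#' @param membership integer/character vector of community labels, one per
#'   node (in node order, or named by node).
#' @param resolutions per-layer resolution gamma (recycled; default 1).
#' @return list with `total` and `perLayer`.
#' @export
multiplexModularity <- function(net, membership, resolutions = 1) {
    n <- length(net@nodes)
    if (!is.null(names(membership))) membership <- membership[net@nodes]
    if (length(membership) != n || anyNA(membership))
        stop("membership must label every node of the network")
    membership <- as.integer(factor(membership))
    gammas <- rep_len(resolutions, length(net@layers))
    perLayer <- vapply(seq_along(net@layers), function(l)
        layerModularity(net@layers[[l]], membership, gammas[l]),
        numeric(1))
    names(perLayer) <- names(net@layers)
    list(total = sum(perLayer), perLayer = perLayer)
}

# Adjacency list representation of one layer: for each node, integer
# neighbor vector and weight vector (self-loops kept separately).
asAdjList <- function(A) {
    n <- nrow(A)
    tri <- Matrix::summary(A)
    off <- tri[tri$i != tri$j, , drop = FALSE]
    nb <- split(off$j, factor(off$i, levels = seq_len(n)))
    wt <- split(off$x, factor(off$i, levels = seq_len(n)))
    list(nb = nb, wt = wt, k = Matrix::rowSums(A),
         selfw = Matrix::diag(A), twoM = sum(A))
}

# One local-move phase of multiplex Louvain: greedy single-node moves
# maximizing the summed modularity gain until no move improves.  Node
# order is fixed by `ord`.  Returns the membership vector.
localMovePhase <- function(adj, gammas, membership, ord, tol = 1e-12) {
    n <- length(membership)
    L <- length(adj)
    sTot <- lapply(seq_len(L), function(l)
        as.numeric(tapply(adj[[l]]$k, factor(membership, levels = seq_len(n)),
                          sum, default = 0)))
    repeat {
        moved <- FALSE
        for (i in ord) {
            a <- membership[i]
            # candidate communities: neighbors across layers + current
            candSet <- integer(0)
            for (l in seq_len(L)) {
                nbl <- adj[[l]]$nb[[i]]
                if (length(nbl))
                    candSet <- c(candSet, membership[nbl])
            }
            candSet <- unique(c(a, candSet))
            # remove i from its community
            for (l in seq_len(L))
                sTot[[l]][a] <- sTot[[l]][a] - adj[[l]]$k[i]
            g <- numeric(length(candSet))
            for (l in seq_len(L)) {
                m2 <- adj[[l]]$twoM
                if (m2 == 0) next
                nbl <- adj[[l]]$nb[[i]]
                wl <- adj[[l]]$wt[[i]]
                wib <- numeric(length(candSet))
                if (length(nbl)) {
                    agg <- rowsum(wl, match(membership[nbl], candSet))
                    idx <- as.integer(rownames(agg))
                    ok <- !is.na(idx)
                    wib[idx[ok]] <- agg[ok]
                }
                ki <- adj[[l]]$k[i]
                g <- g + 2 * wib / m2 -
                    gammas[l] * 2 * ki * sTot[[l]][candSet] / (m2 * m2)
            }
            best <- which(g >= max(g) - 1e-15)
            b <- candSet[best[which.min(candSet[best])]]
            curIdx <- match(a, candSet)
            if (b != a && g[match(b, candSet)] > g[curIdx] + tol) {
                membership[i] <- b
                moved <- TRUE
            }
            b <- membership[i]
            for (l in seq_len(L))
                sTot[[l]][b] <- sTot[[l]][b] + adj[[l]]$k[i]
        }
        if (!moved) break
    }
    membership
}

# Collapse communities into super-nodes; B_cd = sum of A over (c, d)
# blocks, diagonal keeping full within-community weight.
aggregateLayers <- function(layers, membership) {
    k <- max(membership)
    lapply(layers, function(A) {
        tri <- Matrix::summary(A)
        B <- Matrix::sparseMatrix(
            i = membership[tri$i], j = membership[tri$j], x = tri$x,
            dims = c(k, k))
        methods::as(methods::as(B, "CsparseMatrix"), "generalMatrix")
    })
}

#' Multiplex-modularity Louvain clustering
#'
#' Jointly clusters the shared node set of all layers by greedily
#' maximizing the multiplex modularity (sum of per-layer Newman
#' modularities): repeated single-node moves, then aggregation of
#' communities into super-nodes, iterated to convergence, with a final
#' single-node refinement on the original graph so the returned partition
#' is single-move locally optimal.  Node order is shuffled with the
#' configured seed; gain ties go to the lowest community index.
#'
#' @param net a [MultiplexNetwork-class] with at least one non-empty
#'   layer.
#' @param config a [ClusterConfig-class] (`resolution`, `seed`,
#'   `maxPasses`).
#' @return a [Partition-class].
#' @export
louvainMultiplex <- function(net, config = ClusterConfig()) {
    n <- length(net@nodes)
    gammas <- rep_len(config@resolution, length(net@layers))
    if (all(vapply(net@layers, function(A) sum(A), 1) == 0))
        stop("all layers are empty")
    adj0 <- lapply(net@layers, asAdjList)

    best <- NULL
    bestQ <- -Inf
    for (r in seq_len(config@restarts)) {
        seedR <- deriveSeed(config@seed, paste0("restart", r))
        mem <- louvainOnce(net, adj0, gammas, seedR, config@maxPasses)
        q <- suppressWarnings(
            multiplexModularity(net, mem, gammas)$total)
        if (q > bestQ + 1e-12) {
            bestQ <- q
            best <- mem
        }
    }
    membership <- as.integer(factor(best, levels = unique(best)))
    qm <- suppressWarnings(multiplexModularity(net, membership, gammas))
    methods::new("Partition",
        membership = stats::setNames(membership, net@nodes),
        modularityPerLayer = qm$perLayer, modularity = qm$total)
}

# One full Louvain run (local moves + aggregation levels to convergence,
# then a final level-0 refinement that guarantees single-move local
# optimality of the returned partition).
louvainOnce <- function(net, adj0, gammas, seed, maxPasses) {
    n <- length(net@nodes)
    ord0 <- withSeed(seed, sample.int(n))
    membership <- seq_len(n)
    qBest <- -Inf
    for (pass in seq_len(maxPasses)) {
        # level 0 local moves from the current partition
        membership <- localMovePhase(adj0, gammas, membership, ord0)
        membership <- as.integer(factor(membership,
                                        levels = unique(membership)))
        # hierarchical aggregation
        levelMap <- membership
        layers <- aggregateLayers(net@layers, membership)
        repeat {
            nk <- nrow(layers[[1L]])
            adj <- lapply(layers, asAdjList)
            ordk <- withSeed(deriveSeed(seed, paste0("lvl", nk)),
                             sample.int(nk))
            mem <- localMovePhase(adj, gammas, seq_len(nk), ordk)
            mem <- as.integer(factor(mem, levels = unique(mem)))
            if (max(mem) == nk) break
            levelMap <- mem[levelMap]
            layers <- aggregateLayers(layers, mem)
        }
        membership <- levelMap
        q <- suppressWarnings(
            multiplexModularity(net, membership, gammas)$total)
        if (q <= qBest + 1e-12) break
        qBest <- q
    }
    # final refinement at the original resolution
    membership <- localMovePhase(adj0, gammas, membership, ord0)
    as.integer(factor(membership, levels = unique(membership)))
}

#' Write network edges and partitions as TSV
#'
#' @param A adjacency matrix from [correlationNetwork()].
#' @param path output TSV (`cell_i`, `cell_j`, `weight`, upper triangle).
#' @return the path, invisibly.
#' @export
writeEdgeList <- function(A, path) {
    tri <- Matrix::summary(methods::as(A, "TsparseMatrix"))
    up <- tri[tri$i < tri$j, , drop = FALSE]
    data.table::fwrite(data.table::data.table(
        cell_i = rownames(A)[up$i], cell_j = colnames(A)[up$j],
        weight = up$x), path, sep = "\t")
    invisible(path)
}

#' @rdname writeEdgeList
#' @param partition a [Partition-class].
#' @export
writePartition <- function(partition, path) {
    data.table::fwrite(data.table::data.table(
        cell = names(membership(partition)),
        community = as.integer(membership(partition))), path, sep = "\t")
    invisible(path)
}
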