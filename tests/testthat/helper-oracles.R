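library(data.table)

# Independent oracles and shared fixtures for the test suite.  Everything
# here is deliberately written by a different route than the package code
# it checks (dense double loops, exhaustive enumeration, direct
# combinatorial summation).

# --- exhaustive partition enumeration (restricted growth strings) --------
allPartitions <- local({
    cache <- new.env(parent = emptyenv())
    function(n) {
        key <- as.character(n)
        if (!is.null(cache[[key]])) return(cache[[key]])
        parts <- list(1L)
        for (i in seq_len(n - 1L)) {
            parts <- unlist(lapply(parts, function(p) {
                lapply(seq_len(max(p) + 1L), function(c) c(p, c))
            }), recursive = FALSE)
        }
        m <- do.call(rbind, parts)
        cache[[key]] <- m
        m
    }
})

# Dense, direct double-sum modularity of one layer (independent of the
# package's sparse implementation).
denseModularity <- function(A, mem, gamma = 1) {
    A <- as.matrix(A)
    twoM <- sum(A)
    if (twoM == 0) return(0)
    k <- rowSums(A)
    q <- 0
    for (i in seq_len(nrow(A)))
        for (j in seq_len(nrow(A)))
            if (mem[i] == mem[j])
                q <- q + A[i, j] - gamma * k[i] * k[j] / twoM
    as.numeric(q / twoM)
}

denseMultiplexQ <- function(layers, mem, gamma = 1)
    sum(vapply(layers, denseModularity, numeric(1), mem = mem,
               gamma = gamma))

# Brute-force multiplex-modularity optimum over all partitions of n nodes.
bruteForceBestQ <- function(layers, gamma = 1) {
    n <- nrow(layers[[1]])
    parts <- allPartitions(n)
    dense <- lapply(layers, as.matrix)
    ks <- lapply(dense, rowSums)
    twoMs <- vapply(dense, sum, numeric(1))
    best <- -Inf
    bestMem <- parts[1L, ]
    for (p in seq_len(nrow(parts))) {
        mem <- parts[p, ]
        S <- outer(mem, mem, "==")
        q <- 0
        for (l in seq_along(dense)) {
            if (twoMs[l] == 0) next
            q <- q + (sum(dense[[l]][S]) -
                      gamma * sum(outer(ks[[l]], ks[[l]])[S]) /
                          twoMs[l]) / twoMs[l]
        }
        if (q > best) {
            best <- q
            bestMem <- mem
        }
    }
    list(q = best, membership = bestMem)
}

# Exhaustive single-node local-optimality check: no move of one node to
# any other (or new) community may increase the multiplex Q.
isLocallyOptimal <- function(layers, mem, gamma = 1, tol = 1e-12) {
    q0 <- denseMultiplexQ(layers, mem, gamma)
    n <- length(mem)
    for (i in seq_len(n)) {
        for (cc in setdiff(unique(c(mem, max(mem) + 1L)), mem[i])) {
            m2 <- mem
            m2[i] <- cc
            if (denseMultiplexQ(layers, m2, gamma) > q0 + tol)
                return(FALSE)
        }
    }
    TRUE
}

# Random symmetric weighted adjacency for small-graph oracle tests.
randomLayer <- function(n, pEdge = 0.5) {
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    on <- up[stats::runif(length(up)) < pEdge]
    A[on] <- stats::runif(length(on), 0.2, 2)
    A + t(A)
}

# --- hypergeometric upper tail by direct combinatorial summation ---------
hyperUpperTail <- function(N, sizeA, sizeB, k) {
    jmax <- min(sizeA, sizeB)
    if (k > jmax) return(0)
    sum(vapply(k:jmax, function(j)
        choose(sizeA, j) * choose(N - sizeA, sizeB - j), numeric(1))) /
        choose(N, sizeB)
}

# --- exhaustive two-sided rank-sum p over all group assignments ----------
permutationRankSumP <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled)
    r <- rank(pooled)
    obs <- sum(r[seq_along(a)])
    idx <- utils::combn(n, length(a))
    ws <- apply(idx, 2L, function(i) sum(r[i]))
    pLe <- mean(ws <= obs)
    pGe <- mean(ws >= obs)
    min(1, 2 * min(pLe, pGe))
}

# --- adjusted Rand index (chance-corrected partition agreement) ----------
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Minimal 4-line FASTQ reader, independent of the package's I/O helpers.
readFastqOracle <- function(path) {
    ln <- readLines(path)
    data.frame(name = sub("^@", "", ln[seq(1, length(ln), 4)]),
               seq = ln[seq(2, length(ln), 4)],
               stringsAsFactors = FALSE)
}

# --- shared small simulation fixture (built once per test run) -----------
smallSim <- local({
    cache <- new.env(parent = emptyenv())
    function() {
        if (is.null(cache$sim)) {
            g <- makeToyGenomes(seed = 11, nGenes = 40L, nPeaks = 50L)
            cfg <- SimConfig(nCells = 60L, rnaPerCell = 60L,
                             dnaPerCell = 60L, meanDuplicates = 0.3,
                             seed = 11L)
            cache$genomes <- g
            cache$sim <- simulateRun(g, cfg)
        }
        list(genomes = cache$genomes, sim = cache$sim)
    }
})

# Aggregate a truth table into the expected per-(barcode, feature) count
# matrix: RNA by distinct (barcode, gene, UMI), DNA by distinct position.
truthRnaContingency <- function(truth, geneIds, cells) {
    dt <- unique(truth[modality != "DNA" & !is.na(feature_id),
                       .(barcode, feature_id, umi)])
    agg <- dt[, .N, by = .(feature_id, barcode)]
    m <- matrix(0L, length(geneIds), length(cells),
                dimnames = list(geneIds, cells))
    m[cbind(match(agg$feature_id, geneIds), match(agg$barcode, cells))] <-
        agg$N
    m
}

truthDnaContingency <- function(truth, peakIds, cells) {
    dt <- unique(truth[modality == "DNA" & !is.na(feature_id),
                       .(barcode, feature_id, chrom, start, end, strand)])
    agg <- dt[, .N, by = .(feature_id, barcode)]
    m <- matrix(0L, length(peakIds), length(cells),
                dimnames = list(peakIds, cells))
    m[cbind(match(agg$feature_id, peakIds), match(agg$barcode, cells))] <-
        agg$N
    m
}
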