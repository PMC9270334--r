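test_that("correlation networks keep planted blocks and drop the rest", {
    set.seed(8)
    # two blocks of cells sharing a strong latent signal per block
    n <- 30; d <- 20
    lat1 <- rnorm(d); lat2 <- rnorm(d)
    pcs <- rbind(
        t(replicate(n / 2, lat1 * 3 + rnorm(d, sd = 0.5))),
        t(replicate(n / 2, lat2 * 3 + rnorm(d, sd = 0.5))))
    rownames(pcs) <- sprintf("c%02d", seq_len(n))
    A <- correlationNetwork(pcs, ClusterConfig(zThreshold = 3.2))
    blk <- rep(1:2, each = n / 2)
    tri <- Matrix::summary(A)
    tri <- tri[tri$i < tri$j, ]
    expect_gt(nrow(tri), 0)
    expect_true(all(blk[tri$i] == blk[tri$j]))
    # every within-block pair is connected at this signal strength
    expect_equal(nrow(tri), 2 * choose(n / 2, 2))

    # threshold -Inf yields the complete graph
    Afull <- correlationNetwork(pcs, ClusterConfig(zThreshold = -Inf))
    expect_equal(Matrix::nnzero(Afull), n * (n - 1))

    # degenerate inputs are contract errors
    constantCell <- pcs; constantCell[3, ] <- 7
    expect_error(correlationNetwork(constantCell, ClusterConfig()),
                 "constant PC")
    ident <- matrix(rep(rnorm(10), each = 3), 3, 10, byrow = FALSE)
    rownames(ident) <- c("a", "b", "c")
    expect_error(
        correlationNetwork(ident + 0,
                           ClusterConfig(zscoreScope =
                                             "global_offdiagonal")),
        "degenerate")
})

test_that("multiplex modularity matches closed forms and a dense oracle", {
    # singleton partition closed form: Q = -sum_i (k_i / 2m)^2
    set.seed(9)
    A <- randomLayer(7, 0.6)
    rownames(A) <- colnames(A) <- letters[1:7]
    net1 <- MultiplexNetwork(list(x = Matrix::Matrix(A, sparse = TRUE)))
    qSingle <- multiplexModularity(net1, seq_len(7))
    k <- rowSums(A)
    expect_equal(qSingle$total, -sum((k / sum(A))^2), tolerance = 1e-12)

    # two disconnected equal cliques, partition = cliques: Q = 1/2
    C <- matrix(1, 4, 4) - diag(4)
    Z <- matrix(0, 4, 4)
    cliq <- rbind(cbind(C, Z), cbind(Z, C))
    rownames(cliq) <- colnames(cliq) <- paste0("n", 1:8)
    net2 <- MultiplexNetwork(
        list(a = Matrix::Matrix(cliq, sparse = TRUE),
             b = Matrix::Matrix(cliq, sparse = TRUE)))
    mem <- rep(1:2, each = 4)
    q2 <- multiplexModularity(net2, mem)
    expect_equal(unname(q2$perLayer), c(0.5, 0.5), tolerance = 1e-12)
    expect_equal(q2$total, 1, tolerance = 1e-12)
    # independent dense double-sum oracle
    expect_equal(q2$perLayer[["a"]], denseModularity(cliq, mem),
                 tolerance = 1e-12)

    # random multiplex vs dense oracle, and relabeling invariance
    B <- randomLayer(7, 0.5)
    net3 <- MultiplexNetwork(list(Matrix::Matrix(A, sparse = TRUE),
                                  Matrix::Matrix(B, sparse = TRUE)))
    mem3 <- c(1, 1, 2, 2, 2, 3, 3)
    q3 <- multiplexModularity(net3, mem3)
    expect_equal(q3$total, denseMultiplexQ(list(A, B), mem3),
                 tolerance = 1e-12)
    relab <- c(5, 5, 9, 9, 9, 2, 2)
    expect_equal(multiplexModularity(net3, relab)$total, q3$total,
                 tolerance = 1e-15)
    expect_equal(q3$total, sum(q3$perLayer))
})

test_that("louvain separates disconnected components", {
    C <- matrix(1, 4, 4) - diag(4)
    Z <- matrix(0, 4, 4)
    cliq <- rbind(cbind(C, Z), cbind(Z, C))
    rownames(cliq) <- colnames(cliq) <- paste0("n", 1:8)
    net <- MultiplexNetwork(list(Matrix::Matrix(cliq, sparse = TRUE)))
    part <- louvainMultiplex(net, ClusterConfig(seed = 1L))
    mem <- membership(part)
    expect_equal(length(unique(mem)), 2L)
    expect_equal(length(unique(mem[1:4])), 1L)
    expect_equal(length(unique(mem[5:8])), 1L)
    expect_equal(modularity(part), 0.5, tolerance = 1e-12)
})

test_that("single-layer louvain agrees with an igraph reference", {
    skip_if_not_installed("igraph")
    set.seed(10)
    # planted 3-block single-layer graph
    n <- 30
    blocks <- rep(1:3, each = 10)
    P <- ifelse(outer(blocks, blocks, "=="), 0.9, 0.05)
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    A[up] <- (runif(length(up)) < P[up]) * 1
    A <- A + t(A)
    rownames(A) <- colnames(A) <- sprintf("v%02d", 1:n)
    net <- MultiplexNetwork(list(Matrix::Matrix(A, sparse = TRUE)))
    part <- louvainMultiplex(net, ClusterConfig(seed = 2L))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                             weighted = TRUE)
    # our multiplex Q reduces to igraph's modularity for one layer
    qRef <- igraph::modularity(g, membership(part),
                               weights = igraph::E(g)$weight)
    expect_equal(modularity(part), qRef, tolerance = 1e-12)
    # and the recovered communities match the planted blocks
    expect_gte(ari(membership(part), blocks), 0.9)
})

test_that("louvain recovers planted multiplex communities", {
    set.seed(11)
    n <- 60
    blocks <- rep(1:3, each = 20)
    mkLayer <- function(pin, pout) {
        P <- ifelse(outer(blocks, blocks, "=="), pin, pout)
        A <- matrix(0, n, n)
        up <- which(upper.tri(A))
        A[up] <- (runif(length(up)) < P[up]) *
            runif(length(up), 0.5, 1.5)
        A <- A + t(A)
        rownames(A) <- colnames(A) <- sprintf("v%02d", 1:n)
        Matrix::Matrix(A, sparse = TRUE)
    }
    net <- MultiplexNetwork(list(rna = mkLayer(0.8, 0.05),
                                 dna = mkLayer(0.7, 0.08)))
    part <- louvainMultiplex(net, ClusterConfig(seed = 3L))
    expect_gte(ari(membership(part), blocks), 0.9)
    # reported Q is consistent with the standalone computation
    expect_equal(modularity(part),
                 multiplexModularity(net, membership(part))$total,
                 tolerance = 1e-12)
})

test_that("small-graph louvain reaches the brute-force optimum", {
    set.seed(12)
    agree <- 0L
    localOpt <- 0L
    nInst <- 20L
    for (inst in seq_len(nInst)) {
        n <- sample(5:6, 1)
        layers <- list(randomLayer(n, 0.5), randomLayer(n, 0.5))
        layers <- lapply(layers, function(A) {
            rownames(A) <- colnames(A) <- paste0("n", seq_len(n))
            Matrix::Matrix(A, sparse = TRUE)
        })
        if (all(vapply(layers, function(A) sum(A), 1) == 0)) next
        net <- MultiplexNetwork(layers)
        part <- louvainMultiplex(net, ClusterConfig(seed = inst))
        bf <- bruteForceBestQ(lapply(layers, as.matrix))
        if (abs(modularity(part) - bf$q) < 1e-9) agree <- agree + 1L
        if (isLocallyOptimal(lapply(layers, as.matrix),
                             as.integer(membership(part))))
            localOpt <- localOpt + 1L
    }
    expect_gte(agree / nInst, 0.9)
    expect_equal(localOpt, nInst)
})

test_that("edge lists and partitions round-trip through TSV", {
    set.seed(13)
    A <- randomLayer(6, 0.7)
    rownames(A) <- colnames(A) <- paste0("n", 1:6)
    As <- Matrix::Matrix(A, sparse = TRUE)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeEdgeList(As, f)
    back <- read.delim(f)
    expect_equal(nrow(back), Matrix::nnzero(As) / 2)
    net <- MultiplexNetwork(list(As))
    part <- louvainMultiplex(net, ClusterConfig(seed = 1L))
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writePartition(part, f2)
    back2 <- read.delim(f2)
    expect_equal(back2$cell, names(membership(part)))
})
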