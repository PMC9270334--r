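test_that("hypergeometric overlap matches direct combinatorial summation", {
    u <- sprintf("f%03d", 1:20)
    # forced complete overlap
    full <- hypergeomOverlap(u, u, u)
    expect_equal(full$p_value, 1)
    expect_equal(full$overlap, 20L)
    # disjoint sets: k = 0 has upper-tail p = 1
    expect_equal(hypergeomOverlap(u[1:10], u[11:20], u)$p_value, 1)
    # N = 20, |A| = |B| = 10, k = 10
    expect_equal(hypergeomOverlap(u[1:10], u[1:10], u)$p_value,
                 hyperUpperTail(20, 10, 10, 10), tolerance = 1e-12)
    expect_error(hypergeomOverlap(c(u[1], "zzz"), u[1:3], u), "subsets")

    # random cases across N <= 200 against the summation oracle
    set.seed(14)
    for (rep in 1:25) {
        N <- sample(20:200, 1)
        uni <- sprintf("x%04d", seq_len(N))
        a <- sample(uni, sample.int(N, 1))
        b <- sample(uni, sample.int(N, 1))
        got <- hypergeomOverlap(a, b, uni)$p_value
        want <- hyperUpperTail(N, length(a), length(b),
                               length(intersect(a, b)))
        expect_lt(abs(got - want) / want, 1e-10)
    }
})

test_that("overlap heatmaps report -log10 p per set pair", {
    u <- sprintf("f%03d", 1:50)
    sets1 <- list(s1 = u[1:10], s2 = u[21:30])
    sets2 <- list(t1 = u[1:10], t2 = u[41:50])
    h <- overlapHeatmap(sets1, sets2, u)
    expect_equal(dim(h), c(2L, 2L))
    expect_gt(h["s1", "t1"], h["s1", "t2"])
})

test_that("differential features recover planted cluster markers", {
    set.seed(15)
    nCells <- 90; nFeat <- 60
    memb <- rep(1:3, each = 30)
    x <- matrix(rpois(nFeat * nCells, 2), nFeat, nCells)
    truthSets <- split(seq_len(nFeat), rep(1:3, each = nFeat / 3))
    for (cl in 1:3)
        x[truthSets[[cl]], memb == cl] <-
            x[truthSets[[cl]], memb == cl] + rpois(sum(memb == cl) *
                                                   length(truthSets[[cl]]),
                                                   8)
    rownames(x) <- sprintf("f%03d", seq_len(nFeat))
    colnames(x) <- sprintf("c%03d", seq_len(nCells))
    res <- differentialFeatures(log2(x + 1), memb)
    sets <- attr(res, "sets")
    for (cl in 1:3) {
        want <- rownames(x)[truthSets[[cl]]]
        got <- sets[[as.character(cl)]]
        jac <- length(intersect(got, want)) / length(union(got, want))
        expect_gte(jac, 0.8)
    }
})

test_that("differential testing controls false positives under the null", {
    set.seed(16)
    x <- matrix(rnorm(200 * 60), 200, 60)
    rownames(x) <- sprintf("f%03d", 1:200)
    colnames(x) <- sprintf("c%03d", 1:60)
    memb <- rep(1:2, each = 30)
    res <- differentialFeatures(x, memb)
    rawPos <- mean(res[["1"]]$p < 0.05)
    expect_lt(abs(rawPos - 0.05), 0.05)
    expect_lte(length(attr(res, "sets")[["1"]]), 2L)
    expect_warning(differentialFeatures(x, c(rep(1, 59), 2)),
                   "fewer than 2")
})

test_that("CV-CV correlation tracks cross-modality coupling", {
    set.seed(17)
    nGenes <- 80; nCells <- 100
    pairMap <- data.frame(gene_id = sprintf("g%03d", 1:nGenes),
                          peak_id = sprintf("p%03d", 1:nGenes))
    simPair <- function(coupling) {
        disp <- exp(rnorm(nGenes, sd = 1))          # shared variability
        mkM <- function(w, ids) {
            lam <- outer(disp^w, rep(1, nCells)) *
                matrix(exp(rnorm(nGenes * nCells, sd = 0.2)),
                       nGenes)
            m <- matrix(rpois(nGenes * nCells, 5 * lam), nGenes)
            rownames(m) <- ids
            colnames(m) <- sprintf("c%03d", seq_len(nCells))
            m
        }
        list(rna = mkM(1, pairMap$gene_id),
             dna = mkM(coupling, pairMap$peak_id))
    }
    strong <- simPair(1)
    weak <- simPair(0.2)
    rStrong <- cvCorrelation(strong$rna, strong$dna, pairMap)$r
    rWeak <- cvCorrelation(weak$rna, weak$dna, pairMap)$r
    expect_gt(rStrong, 0)
    expect_gt(rStrong, rWeak)

    # permuted pairing decorrelates
    permMap <- data.frame(gene_id = pairMap$gene_id,
                          peak_id = sample(pairMap$peak_id))
    rPerm <- cvCorrelation(strong$rna, strong$dna, permMap)$r
    expect_lt(abs(rPerm), 2 / sqrt(nGenes))

    # CV is invariant to per-feature positive scaling
    scaled <- strong$rna * 7
    expect_equal(cvCorrelation(scaled, strong$dna, pairMap)$r, rStrong)

    # degenerate contract: constant features give all-zero CVs
    constR <- matrix(5, 4, 10,
                     dimnames = list(pairMap$gene_id[1:4], NULL))
    constD <- matrix(3, 4, 10,
                     dimnames = list(pairMap$peak_id[1:4], NULL))
    expect_error(cvCorrelation(constR, constD, pairMap[1:4, ]),
                 "constant")
})

test_that("TSS enrichment is flat on uniform fragments, peaked on planted", {
    set.seed(18)
    chromLen <- 200000L
    tss <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(seq(20000, 180000, by = 20000), width = 1),
        strand = rep(c("+", "-"), length.out = 9))
    uniform <- data.table(
        cell = sample(sprintf("c%02d", 1:20), 30000, replace = TRUE),
        start = sample.int(chromLen - 200L, 30000, replace = TRUE))
    uniform[, `:=`(chrom = "chrT", end = start + 150L)]
    prof <- tssEnrichment(uniform, tss, window = 2000L, nBins = 40L)
    expect_equal(mean(prof$mean), 1, tolerance = 0.1)
    expect_lt(max(abs(prof$mean - 1)), 0.5)

    # fragments planted at the TSS dominate the flanks
    planted <- data.table(
        cell = sample(sprintf("c%02d", 1:20), 6000, replace = TRUE),
        start = sample(GenomicRanges::start(tss), 6000, replace = TRUE) +
            sample(-50:50, 6000, replace = TRUE))
    planted[, `:=`(chrom = "chrT", end = start + 100L)]
    both <- rbind(uniform, planted, use.names = TRUE)
    prof2 <- tssEnrichment(both, tss, window = 2000L, nBins = 40L)
    centre <- mean(prof2$mean[19:22])
    flank <- mean(prof2$mean[c(1:3, 38:40)])
    expect_gt(centre / flank, 3)

    expect_error(tssEnrichment(uniform[1:5],
                               GenomicRanges::shift(tss, 5e6)),
                 "no fragment")
})

test_that("gene body coverage is flat for uniform reads, 3'-skewed for biased", {
    set.seed(19)
    genes <- GenomicRanges::GRanges("chrT",
        IRanges::IRanges(c(1000, 50000), width = 10000),
        strand = c("+", "-"))
    genes$gene_id <- c("gPlus", "gMinus")
    nR <- 40000
    gi <- sample(1:2, nR, replace = TRUE)
    off <- floor(runif(nR) * 9900)
    uniform <- data.table(
        cell = sample(sprintf("c%02d", 1:20), nR, replace = TRUE),
        chrom = "chrT",
        start = GenomicRanges::start(genes)[gi] + as.integer(off))
    uniform[, end := start + 99L]
    prof <- geneBodyCoverage(uniform, genes, nBins = 50L)
    expect_equal(sum(prof$mean), 1, tolerance = 1e-12)
    expect_lt(max(abs(prof$mean - 1 / 50)), 0.5 / 50)

    # reads only near 3' ends peak in the last bins (strand-aware)
    threePrime <- data.table(
        cell = "c01", chrom = "chrT",
        start = c(GenomicRanges::end(genes)[1] - 200L,
                  GenomicRanges::start(genes)[2]))
    threePrime[, end := start + 100L]
    prof3 <- geneBodyCoverage(threePrime, genes, nBins = 20L)
    expect_gt(sum(prof3$mean[19:20]), 0.99)
})

test_that("rank-sum p values match exhaustive permutation enumeration", {
    expect_equal(wilcoxonGroupShift(c(1, 2, 3), c(4, 5, 6)), 0.1,
                 tolerance = 1e-12)
    expect_equal(wilcoxonGroupShift(c(1, 2, 3), c(4, 5, 6)),
                 permutationRankSumP(c(1, 2, 3), c(4, 5, 6)),
                 tolerance = 1e-12)
    set.seed(20)
    for (rep in 1:10) {
        a <- rnorm(sample(3:6, 1))
        b <- rnorm(sample(3:6, 1), mean = runif(1, 0, 2))
        expect_equal(wilcoxonGroupShift(a, b), permutationRankSumP(a, b),
                     tolerance = 1e-12)
    }
    # all-tied contract and extreme shift
    expect_equal(wilcoxonGroupShift(rep(2, 5), rep(2, 4)), 1)
    set.seed(21)
    expect_lt(wilcoxonGroupShift(rnorm(200), rnorm(200, 5)), 1e-20)
})
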