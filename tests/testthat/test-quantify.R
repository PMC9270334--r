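mkAln <- function(chrom, start, end, barcode, modality, umi = NA,
                  strand = "+") {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        pair_id = sprintf("p%03d", seq_along(gr)), barcode = barcode,
        umi = as.character(umi), modality = modality,
        mapq = 60L)
    gr
}

mkGenes <- function() {
    g <- GenomicRanges::GRanges("chrT",
                                IRanges::IRanges(c(100, 500), c(300, 800)),
                                strand = c("+", "-"))
    g$gene_id <- c("geneA", "geneB")
    g
}

test_that("chromatin dedup collapses by position within a cell", {
    # identical fragment twice in one cell -> 1; in two cells -> 2
    aln <- mkAln("chrT", c(100, 100, 100), c(249, 249, 249),
                 c("BC1", "BC1", "BC2"), "DNA")
    u <- dedupDna(aln)
    expect_equal(nrow(u), 2L)
    expect_equal(sort(u$cell), c("BC1", "BC2"))

    # different strand or coordinates are distinct fragments
    aln2 <- mkAln("chrT", c(100, 100, 101), c(249, 249, 250),
                  c("BC1", "BC1", "BC1"), "DNA",
                  strand = c("+", "-", "+"))
    expect_equal(nrow(dedupDna(aln2)), 3L)

    # RNA contamination is an error
    expect_error(dedupDna(mkAln("chrT", 1, 50, "BC1", "RNA", "ACGTAC")),
                 "RNA record")
})

test_that("RNA dedup collapses by cell, gene and UMI", {
    genes <- mkGenes()
    # same UMI, same gene, different positions -> one molecule
    aln <- mkAln("chrT", c(110, 150), c(180, 220), "BC1", "RNA",
                 c("AAAAAA", "AAAAAA"))
    r <- dedupRna(aln, genes)
    expect_equal(nrow(r$molecules), 1L)
    # same UMI in different genes -> two molecules
    aln2 <- mkAln("chrT", c(110, 510), c(180, 580), "BC1", "RNA",
                  c("AAAAAA", "AAAAAA"))
    expect_equal(nrow(dedupRna(aln2, genes)$molecules), 2L)
    # non-genic reads count in totals but not useful
    aln3 <- mkAln("chrT", c(110, 2000), c(180, 2070), "BC1", "RNA",
                  c("AAAAAA", "CCCCCC"))
    r3 <- dedupRna(aln3, genes)
    expect_equal(r3$totals$n_total, 2L)
    expect_equal(r3$totals$n_useful, 1L)
    expect_error(dedupRna(mkAln("chrT", 1, 50, "BC1", "DNA"), genes),
                 "DNA record")
})

test_that("reads spanning two genes go to the longest overlap", {
    g <- GenomicRanges::GRanges("chrT",
                                IRanges::IRanges(c(100, 260), c(280, 500)))
    g$gene_id <- c("geneA", "geneB")
    # read 250-350: 31 bp in geneA, 91 bp in geneB -> geneB
    aln <- mkAln("chrT", 250, 350, "BC1", "RNA", "ACGTAC")
    expect_equal(dedupRna(aln, g)$molecules$feature_id, "geneB")
})

test_that("matrix construction respects declared axes and counts", {
    genes <- mkGenes()
    cells <- c("BC1", "BC2", "BC3")
    m0 <- buildMatrix(data.table(cell = character(),
                                 feature_id = character()),
                      genes, cells, "RNA")
    expect_s4_class(m0, "FeatureMatrix")
    expect_equal(dim(m0), c(2L, 3L))
    expect_equal(sum(counts(m0)), 0)

    units <- data.table(cell = "BC2", feature_id = "geneB",
                        umi = "AAAAAA")
    m1 <- buildMatrix(units, genes, cells, "RNA")
    expect_equal(as.numeric(counts(m1)["geneB", "BC2"]), 1)
    expect_equal(sum(counts(m1)), 1)
    expect_equal(modality(m1), "RNA")

    expect_error(buildMatrix(data.table(cell = "BCX",
                                        feature_id = "geneA"),
                             genes, cells, "RNA"), "undeclared cell")
})

test_that("simulated quantification equals the truth contingency table", {
    fx <- smallSim()
    sim <- fx$sim
    feats <- combinedFeatures(fx$genomes)
    cells <- sort(unique(sim$truth$barcode))
    aln <- truthAlignments(sim$truth)

    rd <- dedupRna(aln[aln$modality == "RNA"], feats$genes)
    rnaMat <- buildMatrix(rd$molecules, feats$genes, cells, "RNA")
    expected <- truthRnaContingency(sim$truth, rownames(rnaMat), cells)
    expect_equal(as.matrix(counts(rnaMat)), expected,
                 ignore_attr = TRUE)

    frag <- dedupDna(aln[aln$modality == "DNA"])
    dnaMat <- buildMatrix(frag, feats$peaks, cells, "DNA")
    expectedD <- truthDnaContingency(sim$truth, rownames(dnaMat), cells)
    expect_equal(as.matrix(counts(dnaMat)), expectedD,
                 ignore_attr = TRUE)

    # column sums equal per-cell useful-UMI totals
    useful <- rd$totals[match(cells, cell)]
    useful[is.na(n_useful), n_useful := 0L]
    expect_equal(unname(Matrix::colSums(counts(rnaMat))),
                 as.numeric(useful$n_useful))

    # dedup is idempotent and totals never exceed inputs
    frag2 <- dedupDna(truthAlignments(sim$truth)[
        truthAlignments(sim$truth)$modality == "DNA"])
    expect_equal(nrow(unique(frag2)), nrow(frag2))
    expect_lte(sum(counts(rnaMat)), sum(aln$modality == "RNA"))
    expect_lte(sum(counts(dnaMat)), sum(aln$modality == "DNA"))
})
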