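# Hand-built 20-cell fixture with controlled totals and breadth, used to
# check the inclusion rules against exhaustive enumeration.
mkFixture <- function(nGenes = 60L, nPeaks = 60L, nCells = 20L,
                      seed = 99L) {
    set.seed(seed)
    cells <- sprintf("BC%02d", seq_len(nCells))
    mkFm <- function(nFeat, prefix, target) {
        # per-cell totals straddling the 1000 boundary
        tot <- c(999L, 1000L, 1001L,
                 sample(c(50L, 500L, 999L, 1000L, 2000L, 5000L),
                        nCells - 3L, replace = TRUE))
        # per-cell breadth straddling the nonzero-region presets
        breadth <- c(49L, 50L, sample(c(20L, 49L, 50L, 60L), nCells - 2L,
                                      replace = TRUE))
        breadth <- pmin(breadth, nFeat)
        tot <- pmax(tot, breadth)
        m <- matrix(0L, nFeat, nCells, dimnames = list(NULL, cells))
        for (j in seq_len(nCells)) {
            rows <- sample.int(nFeat, breadth[j])
            m[rows, j] <- 1L
            # concentrate remaining depth on the first chosen feature
            m[rows[1L], j] <- m[rows[1L], j] + tot[j] - breadth[j]
        }
        gr <- GenomicRanges::GRanges("chrT",
            IRanges::IRanges(seq_len(nFeat) * 1000L,
                             width = 500L))
        S4Vectors::mcols(gr)[[paste0(prefix, "_id")]] <-
            sprintf("%s%03d", prefix, seq_len(nFeat))
        FeatureMatrix(m, gr, target)
    }
    list(rna = mkFm(nGenes, "gene", "RNA"),
         dna = mkFm(nPeaks, "peak", "DNA"), cells = cells)
}

test_that("feature filtering applies the prevalence boundary exactly", {
    # one feature per prevalence level 0..40 cells
    m <- matrix(0L, 41, 40)
    for (f in 1:41) if (f > 1) m[f, seq_len(f - 1L)] <- 1L
    gr <- GenomicRanges::GRanges("chrT",
                                 IRanges::IRanges(1:41 * 100L, width = 50L))
    gr$gene_id <- sprintf("g%02d", 1:41)
    fm <- FeatureMatrix(m, gr, "RNA")
    f30 <- filterFeatures(fm, 30L)
    # feature nonzero in 29 cells dropped, in 30 cells kept
    expect_false("g30" %in% rownames(f30))  # prevalence 29
    expect_true("g31" %in% rownames(f30))   # prevalence 30
    expect_equal(nrow(f30), sum(colSums(t(m) > 0) >= 30))
    # threshold 0 is the identity
    expect_equal(rownames(filterFeatures(fm, 0L)), rownames(fm))
})

test_that("cell filter survivors match exhaustive enumeration per preset", {
    fx <- mkFixture()
    rnaTot <- data.table(cell = fx$cells,
                         n_total = Matrix::colSums(counts(fx$rna)))
    dnaTot <- data.table(cell = fx$cells,
                         n_total = Matrix::colSums(counts(fx$dna)))
    for (preset in list(c(30L, 1000L, 1000L, 100L),
                        c(30L, 1000L, 1000L, 450L),
                        c(30L, 1000L, 1000L, 50L),
                        c(0L, 1000L, 1000L, 0L),
                        c(5L, 100L, 100L, 10L))) {
        cfg <- FilterConfig(preset[1], preset[2], preset[3], preset[4])
        rnaF <- filterFeatures(fx$rna, preset[1])
        dnaF <- filterFeatures(fx$dna, preset[1])
        got <- filterCells(rnaF, dnaF, rnaTot, dnaTot, cfg)
        # brute force over every cell with plain base R
        mr <- as.matrix(counts(rnaF))
        md <- as.matrix(counts(dnaF))
        keep <- vapply(seq_along(fx$cells), function(j) {
            rnaTot$n_total[j] >= preset[2] &&
            dnaTot$n_total[j] >= preset[3] &&
            sum(mr[, j] > 0) >= preset[4] &&
            sum(md[, j] > 0) >= preset[4]
        }, logical(1))
        expect_identical(got, fx$cells[keep])
    }
})

test_that("read-count boundary at 1000 is inclusive", {
    fx <- mkFixture()
    rnaTot <- data.table(cell = fx$cells,
                         n_total = Matrix::colSums(counts(fx$rna)))
    dnaTot <- data.table(cell = fx$cells,
                         n_total = Matrix::colSums(counts(fx$dna)))
    cfg <- FilterConfig(0L, 1000L, 1000L, 0L)
    kept <- filterCells(fx$rna, fx$dna, rnaTot, dnaTot, cfg)
    expect_false(fx$cells[1] %in% kept)  # 999 RNA reads
    # cells 2 and 3 have >= 1000 on RNA; kept iff DNA also passes
    expect_equal(fx$cells[2] %in% kept, dnaTot$n_total[2] >= 1000)
})

test_that("filtering is monotone and order-independent", {
    fx <- mkFixture()
    rnaTot <- data.table(cell = fx$cells,
                         n_total = Matrix::colSums(counts(fx$rna)))
    dnaTot <- data.table(cell = fx$cells,
                         n_total = Matrix::colSums(counts(fx$dna)))
    thresholds <- c(0L, 10L, 50L, 100L, 450L)
    kept <- lapply(thresholds, function(t)
        filterCells(fx$rna, fx$dna, rnaTot, dnaTot,
                    FilterConfig(0L, 100L, 100L, t)))
    for (i in seq_along(kept)[-1])
        expect_true(all(kept[[i]] %in% kept[[i - 1]]))

    # permuting the cell axis leaves the retained set unchanged
    perm <- sample(ncol(fx$rna))
    keptPerm <- filterCells(fx$rna[, perm], fx$dna[, perm],
                            rnaTot, dnaTot,
                            FilterConfig(0L, 100L, 100L, 50L))
    expect_setequal(keptPerm,
                    filterCells(fx$rna, fx$dna, rnaTot, dnaTot,
                                FilterConfig(0L, 100L, 100L, 50L)))
    expect_error(filterCells(fx$rna, fx$dna[, 1:10], rnaTot, dnaTot),
                 "share")
})

test_that("preset names map to the documented breadth thresholds", {
    expect_equal(FilterConfig(preset = "rnapii")@minNonzeroRegions, 100L)
    expect_equal(FilterConfig(preset = "h3k4me3")@minNonzeroRegions, 450L)
    expect_equal(FilterConfig(preset = "cd34_cd36")@minNonzeroRegions,
                 50L)
})
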