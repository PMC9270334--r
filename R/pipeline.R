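#' Combined feature annotation of a genome pair
#'
#' @param genomes list of [ToyGenome-class] objects.
#' @return list `genes`, `peaks` ([GenomicRanges::GRanges] over the
#'   combined reference).
#' @export
combinedFeatures <- function(genomes) {
    list(genes = suppressWarnings(
             do.call(c, lapply(genomes, function(g) g@genes))),
         peaks = suppressWarnings(
             do.call(c, lapply(genomes, function(g) g@peaks))))
}

#' Run the full pipeline on a bundled simulation
#'
#' Executes every stage in order — simulate, demultiplex, load truth
#' alignments, deduplicate and quantify, per-cell QC and barnyard calling,
#' feature/cell filtering, transform and reduce, multiplex Louvain
#' clustering, downstream statistics — writing all artifacts plus a
#' manifest (seeds, input checksums, package version) into `outDir`.
#' Reruns with the same configuration are bit-identical.
#'
#' @param outDir output directory (created; must not contain a previous
#'   manifest unless `overwrite = TRUE`).
#' @param config a [SimConfig-class]; its seed drives every stage
#'   substream.
#' @param genomes optional list of [ToyGenome-class] (default: a pair
#'   seeded from `config@seed`).
#' @param filter a [FilterConfig-class].  The default is scaled to the
#'   simulated depth (the assay-scale presets assume real sequencing
#'   depth).
#' @param embed an [EmbedConfig-class].
#' @param cluster a [ClusterConfig-class].
#' @param purity barnyard purity threshold.
#' @param overwrite allow writing over a previous run.
#' @return invisible list with the main in-memory results (`sim`, `demux`,
#'   `matrices`, `qc`, `barnyard`, `filtered`, `reduced`, `partition`,
#'   `stats`, `manifest`).
#' @export
runPipeline <- function(outDir, config = SimConfig(), genomes = NULL,
                        filter = FilterConfig(minCellsPerFeature = 5L,
                                              minRnaReads = 30L,
                                              minDnaReads = 30L,
                                              minNonzeroRegions = 10L),
                        embed = EmbedConfig(seed = deriveSeed(config@seed,
                                                              "embed")),
                        cluster = ClusterConfig(seed = deriveSeed(
                            config@seed, "louvain")),
                        purity = 0.9, overwrite = FALSE) {
    manifestPath <- file.path(outDir, "manifest.json")
    if (file.exists(manifestPath) && !overwrite)
        stop("outDir already holds a run; use overwrite = TRUE")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    ## 1. simulate
    if (is.null(genomes))
        genomes <- makeToyGenomes(seed = deriveSeed(config@seed, "genomes"))
    sim <- simulateRun(genomes, config)
    fq <- writeSimFastq(sim, outDir)
    writeTruthTable(sim$truth, file.path(outDir, "truth.tsv"))
    truthBed <- file.path(outDir, "truth_alignments.bed")
    writeTaggedBed(truthAlignments(sim$truth), truthBed)

    ## 2. demultiplex
    dx <- demuxRun(fq["r1"], fq["r2"],
                   DemuxConfig(whitelist = sim$whitelist),
                   outDir = file.path(outDir, "demux"))
    writeDemuxStats(dx$stats, file.path(outDir, "demux"))

    ## 3. alignments (truth alignments stand in for an external aligner)
    aln <- readTagged(truthBed)
    feats <- combinedFeatures(genomes)
    cellsAll <- sort(unique(sim$truth$barcode))

    ## 4. quantify
    rnaAln <- aln[aln$modality == "RNA"]
    dnaAln <- aln[aln$modality == "DNA"]
    rnaDedup <- dedupRna(rnaAln, feats$genes)
    dnaFrag <- dedupDna(dnaAln)
    rnaMat <- buildMatrix(rnaDedup$molecules, feats$genes, cellsAll, "RNA")
    dnaMat <- buildMatrix(dnaFrag, feats$peaks, cellsAll, "DNA")
    writeFeatureMatrix(rnaMat, file.path(outDir, "rna"))
    writeFeatureMatrix(dnaMat, file.path(outDir, "dna"))

    ## 5. QC + barnyard
    peakCounts <- countInPeaks(dnaFrag, feats$peaks)
    gCounts <- speciesCounts(aln, genomes)
    qcRna <- computeCellQC(rnaMat, rnaDedup$totals, gCounts)
    qcDna <- computeCellQC(dnaMat, peakCounts, gCounts)
    utils::write.table(as.data.frame(qcRna),
                       file.path(outDir, "qc_rna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(qcDna),
                       file.path(outDir, "qc_dna.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    bres <- barnyard(gCounts, purity)
    data.table::fwrite(bres$calls, file.path(outDir, "barnyard.tsv"),
                       sep = "\t")

    ## 6. filters
    flt <- applyFilters(rnaMat, dnaMat, rnaDedup$totals,
                        data.table::setnames(
                            peakCounts[, c("cell", "n_total")],
                            c("cell", "n_total")), filter)
    writeLines(flt$cells, file.path(outDir, "cells_retained.tsv"))

    ## 7. transform + reduce
    nPcsUse <- min(embed@nPcs, dim(flt$rna) - 1L, dim(flt$dna) - 1L)
    redRna <- reduceDims(transformRna(flt$rna, embed@pseudocount,
                                      embed@normalizeRna),
                         nPcsUse, embed@seed, embed@embedding,
                         embed@scaleFeatures)
    redDna <- reduceDims(transformDna(flt$dna, embed@pseudocount),
                         nPcsUse, embed@seed, embed@embedding,
                         embed@scaleFeatures)
    utils::write.table(redRna$pcs, file.path(outDir, "rna_pcs.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(redDna$pcs, file.path(outDir, "dna_pcs.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)

    ## 8. multiplex clustering
    net <- buildMultiplexNetwork(list(rna = redRna$pcs, dna = redDna$pcs),
                                 cluster)
    part <- louvainMultiplex(net, cluster)
    writeEdgeList(net@layers$rna, file.path(outDir, "edges_rna.tsv"))
    writeEdgeList(net@layers$dna, file.path(outDir, "edges_dna.tsv"))
    writePartition(part, file.path(outDir, "clusters.tsv"))

    ## 9. downstream statistics
    diffR <- differentialFeatures(transformRna(flt$rna),
                                  membership(part))
    tssGr <- feats$genes
    tssProf <- tssEnrichment(dnaFrag, tssGr)
    gbProf <- geneBodyCoverage(rnaAln, feats$genes)
    writeProfile(tssProf, file.path(outDir, "tss_enrichment.tsv"))
    writeProfile(gbProf, file.path(outDir, "gene_body_coverage.tsv"))

    manifest <- list(
        package_version = as.character(utils::packageVersion("scpcor")),
        seed = config@seed,
        n_cells = config@nCells,
        stage_summary = list(
            total_pairs = dx$stats$total_pairs,
            valid_pairs = dx$stats$valid_pairs,
            cells_retained = length(flt$cells),
            n_clusters = length(unique(membership(part))),
            multiplex_Q = modularity(part),
            collision_rate = bres$collision_rate),
        checksums = {
            cs <- tools::md5sum(c(fq, file.path(outDir, "truth.tsv"),
                                  truthBed))
            names(cs) <- basename(names(cs))
            as.list(cs)
        })
    jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(sim = sim, demux = dx,
                   matrices = list(rna = rnaMat, dna = dnaMat),
                   qc = list(rna = qcRna, dna = qcDna), barnyard = bres,
                   filtered = flt,
                   reduced = list(rna = redRna, dna = redDna),
                   network = net, partition = part,
                   stats = list(differential = diffR, tss = tssProf,
                                geneBody = gbProf),
                   manifest = manifest))
}
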