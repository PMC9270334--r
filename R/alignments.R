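#' Read tagged alignments
#'
#' Loads alignment records whose read names follow the demultiplexer's
#' scheme (`<pairid>:BC:<barcode>:UMI:<umi|->:MOD:<RNA|DNA>`) and exposes
#' the carried metadata as columns.  Supports 6-column BED (0-based
#' half-open, score column = MAPQ) and SAM/BAM (primary alignments only;
#' unmapped records are skipped and counted).
#'
#' @param path alignment file (`.bed`, `.sam`, `.bam`, optionally gzipped
#'   BED).
#' @param format `"auto"` (by extension), `"bed"`, `"sam"` or `"bam"`.
#' @return [GenomicRanges::GRanges] (1-based, inclusive) with metadata
#'   columns `pair_id`, `barcode`, `umi`, `modality`, `mapq`; the number of
#'   skipped unmapped records is in `metadata(.)$n_unmapped`.
#' @export
readTagged <- function(path, format = c("auto", "bed", "sam", "bam")) {
    format <- match.arg(format)
    if (format == "auto")
        format <- switch(tolower(tools::file_ext(sub("\\.gz$", "", path))),
                         bed = "bed", sam = "sam", bam = "bam",
                         stop("cannot guess alignment format of ", path))
    nUnmapped <- 0L
    if (format == "bed") {
        dt <- data.table::fread(path, header = FALSE,
            col.names = c("chrom", "start", "end", "name", "score",
                          "strand")[1:6])
        gr <- GRanges(dt$chrom,
                      IRanges::IRanges(dt$start + 1L, dt$end),
                      strand = dt$strand)
        names(gr) <- dt$name
        mapq <- as.integer(dt$score)
    } else {
        bam <- path
        if (format == "sam")
            bam <- Rsamtools::asBam(path,
                                    destination = tempfile(),
                                    overwrite = TRUE, indexDestination = FALSE)
        flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                        isSupplementaryAlignment = FALSE)
        aln <- GenomicAlignments::readGAlignments(
            bam, use.names = TRUE,
            param = Rsamtools::ScanBamParam(flag = flags, what = "mapq"))
        cnt <- Rsamtools::countBam(
            bam, param = Rsamtools::ScanBamParam(
                flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE)))
        nUnmapped <- cnt$records
        gr <- GRanges(GenomicAlignments::seqnames(aln),
                      IRanges::IRanges(GenomicAlignments::start(aln),
                                       GenomicAlignments::end(aln)),
                      strand = GenomicAlignments::strand(aln))
        names(gr) <- names(aln)
        mapq <- S4Vectors::mcols(aln)$mapq
    }
    meta <- decodeReadName(names(gr))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        pair_id = meta$pair_id, barcode = meta$barcode, umi = meta$umi,
        modality = meta$modality, mapq = mapq)
    S4Vectors::metadata(gr)$n_unmapped <- nUnmapped
    gr
}

#' Write tagged alignments as BED6
#'
#' Coordinates are exported 0-based half-open; the name column carries the
#' demux read-name scheme and the score column the MAPQ.
#'
#' @param gr tagged alignments ([GenomicRanges::GRanges] as produced by
#'   [truthAlignments()] or [readTagged()]).
#' @param path output `.bed` (optionally `.gz`).
#' @return the path, invisibly.
#' @export
writeTaggedBed <- function(gr, path) {
    dt <- data.table::data.table(
        chrom = as.character(seqnames(gr)),
        start = start(gr) - 1L, end = end(gr),
        name = encodeReadName(gr$pair_id, gr$barcode, gr$umi, gr$modality),
        score = gr$mapq,
        strand = as.character(strand(gr)))
    dt$strand[dt$strand == "*"] <- "+"
    data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
    invisible(path)
}

#' Merge alignment passes
#'
#' Combines mapping passes run with different trimming parameters: for
#' each pair the first mapped occurrence, in the priority order the
#' streams are given, is kept.
#'
#' @param ... tagged alignment [GenomicRanges::GRanges] streams, highest
#'   priority first.
#' @return a single tagged GRanges with at most one record per `pair_id`.
#' @export
mergePasses <- function(...) {
    streams <- list(...)
    stopifnot(length(streams) >= 1L)
    seen <- character(0)
    kept <- vector("list", length(streams))
    for (k in seq_along(streams)) {
        s <- streams[[k]]
        new <- !(s$pair_id %in% seen) & !duplicated(s$pair_id)
        kept[[k]] <- s[new]
        seen <- c(seen, s$pair_id[new])
    }
    out <- suppressWarnings(do.call(c, kept))
    S4Vectors::metadata(out) <- list()
    out
}
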