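#' Validate read pairs
#'
#' A pair is valid when read2 starts with a whitelisted cell barcode
#' followed immediately by the exact 19-nt read2 linker
#' (`AGAACCATGTCGTCAGTGT` by default).  Matching is position-anchored and,
#' by default, exact; `mismatchTolerance = 1` additionally rescues barcodes
#' one mismatch away from a whitelist entry (unambiguous for whitelists
#' built at Hamming distance >= 3).
#'
#' @param read1,read2 character vectors of read sequences (parallel).
#' @param config a [DemuxConfig-class].
#' @return data.table with columns `valid` (logical), `reason`
#'   (`"ok"`, `"too_short"`, `"linker_mismatch"`, `"barcode_unknown"`) and
#'   `barcode` (the matched whitelist entry, `NA` if invalid).
#' @export
validatePair <- function(read1, read2, config = DemuxConfig()) {
    bclen <- unique(nchar(config@whitelist))
    linker <- config@read2Linker
    need2 <- bclen + nchar(linker)
    need1 <- max(config@dtSpan[2L], config@umiSpan[2L])
    n <- length(read2)
    reason <- rep("ok", n)
    tooShort <- nchar(read2) < need2 | nchar(read1) < need1
    reason[tooShort] <- "too_short"
    linkOk <- !tooShort &
        substr(read2, bclen + 1L, bclen + nchar(linker)) == linker
    reason[!tooShort & !linkOk] <- "linker_mismatch"
    bc <- substr(read2, 1L, bclen)
    hit <- match(bc, config@whitelist)
    if (config@mismatchTolerance >= 1L) {
        miss <- which(is.na(hit) & !tooShort)
        if (length(miss)) {
            nb <- barcodeNeighbors(config@whitelist)
            hit[miss] <- nb[bc[miss]]
        }
    }
    bcOk <- !is.na(hit)
    reason[linkOk & !bcOk] <- "barcode_unknown"
    valid <- linkOk & bcOk
    data.table::data.table(
        valid = valid, reason = reason,
        barcode = ifelse(valid, config@whitelist[hit], NA_character_))
}

# Map every 1-mismatch neighbor of each whitelist barcode to its index.
barcodeNeighbors <- function(whitelist) {
    w <- nchar(whitelist[1L])
    bases <- c("A", "C", "G", "T")
    keys <- character(0)
    vals <- integer(0)
    for (p in seq_len(w)) {
        for (b in bases) {
            mut <- whitelist
            substr(mut, p, p) <- b
            keep <- mut != whitelist
            keys <- c(keys, mut[keep])
            vals <- c(vals, which(keep))
        }
    }
    dup <- keys %in% keys[duplicated(keys)] | keys %in% whitelist
    stats::setNames(vals[!dup], keys[!dup])
}

#' Classify read1 into a modality
#'
#' On validated pairs: RNA primed by not-so-random primers when read1
#' bases 7-11 equal `GAGCG`; otherwise RNA primed by oligo-dT when bases
#' 7-14 equal `CCTGCAGG`; all remaining pairs are chromatin (`DNA`).  The
#' NSR motif takes precedence if both somehow match.  RNA UMIs are bases
#' 1-6.
#'
#' @param read1 character vector of read1 sequences.
#' @param config a [DemuxConfig-class].
#' @return data.table with columns `modality` (`"RNA_NSR"`, `"RNA_DT"`,
#'   `"DNA"`) and `umi` (`NA` for DNA).
#' @export
classifyRead1 <- function(read1, config = DemuxConfig()) {
    nsr <- substr(read1, config@nsrSpan[1L], config@nsrSpan[2L]) ==
        config@nsrLinker
    dt <- substr(read1, config@dtSpan[1L], config@dtSpan[2L]) ==
        config@dtLinker
    modality <- ifelse(nsr, "RNA_NSR", ifelse(dt, "RNA_DT", "DNA"))
    umi <- ifelse(modality == "DNA", NA_character_,
                  substr(read1, config@umiSpan[1L], config@umiSpan[2L]))
    data.table::data.table(modality = modality, umi = umi)
}

#' Demultiplex a paired-end run
#'
#' Validates every pair, extracts barcode/UMI/modality, trims the
#' structural prefixes, and (optionally) writes one FASTQ set per
#' (barcode, modality) bucket with the metadata encoded in the read name
#' (`<pairid>:BC:<barcode>:UMI:<umi|->:MOD:<RNA|DNA>`).
#'
#' @param r1,r2 paths to paired FASTQ files (plain or gzip), or
#'   data.tables with columns `name`, `seq` (and optionally `qual`).
#' @param config a [DemuxConfig-class].
#' @param outDir directory for the per-barcode FASTQ sets, or `NULL` to
#'   skip writing.
#' @return list with `records` (data.table: `pair_id`, `barcode`,
#'   `modality`, `umi`, `insert1`, `insert2`), `stats` (a `DemuxStats`
#'   list: `total_pairs`, `valid_pairs`, `rna_pairs`, `dna_pairs`,
#'   `per_barcode`, `invalid_reasons`), and `files` (written paths).
#' @export
demuxRun <- function(r1, r2, config = DemuxConfig(), outDir = NULL) {
    toTable <- function(x, which) {
        if (is.character(x) && length(x) == 1L) return(readFastq(x))
        x <- data.table::as.data.table(x)
        if (!"name" %in% names(x) && "pair_id" %in% names(x))
            data.table::setnames(x, "pair_id", "name")
        cols <- intersect(c("read1", "read2"), names(x))
        if (length(cols)) data.table::setnames(x, cols[1L], "seq")
        if (!"qual" %in% names(x))
            x[, qual := strrep("I", nchar(seq))]
        x[, c("name", "seq", "qual"), with = FALSE]
    }
    t1 <- toTable(r1, "read1")
    t2 <- toTable(r2, "read2")
    if (nrow(t1) != nrow(t2))
        stop("unpaired FASTQ: ", nrow(t1), " vs ", nrow(t2), " records")
    bad <- which(t1$name != t2$name)
    if (length(bad))
        stop("desynchronized FASTQ at record ", bad[1L], ": '",
             t1$name[bad[1L]], "' vs '", t2$name[bad[1L]], "'")

    v <- validatePair(t1$seq, t2$seq, config)
    cl <- classifyRead1(t1$seq, config)
    bclen <- unique(nchar(config@whitelist))
    trim1 <- ifelse(cl$modality == "RNA_NSR", config@nsrSpan[2L],
             ifelse(cl$modality == "RNA_DT", config@dtSpan[2L], 0L))
    records <- data.table::data.table(
        pair_id = t1$name, barcode = v$barcode, modality = cl$modality,
        umi = cl$umi,
        insert1 = substr(t1$seq, trim1 + 1L, nchar(t1$seq)),
        qual1 = substr(t1$qual, trim1 + 1L, nchar(t1$qual)),
        insert2 = substr(t2$seq, bclen + nchar(config@read2Linker) + 1L,
                         nchar(t2$seq)),
        qual2 = substr(t2$qual, bclen + nchar(config@read2Linker) + 1L,
                       nchar(t2$qual)))[v$valid]

    reasons <- table(v$reason[!v$valid])
    perBarcode <- if (nrow(records))
        records[, .(pairs = .N), by = .(barcode, mod = ifelse(
            modality == "DNA", "DNA", "RNA"))]
    else data.table::data.table(barcode = character(), mod = character(),
                                pairs = integer())
    stats <- list(
        total_pairs = nrow(t1), valid_pairs = nrow(records),
        rna_pairs = sum(records$modality != "DNA"),
        dna_pairs = sum(records$modality == "DNA"),
        per_barcode = perBarcode,
        invalid_reasons = stats::setNames(as.integer(reasons),
                                          names(reasons)))

    files <- character(0)
    if (!is.null(outDir) && nrow(records)) {
        dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
        grp <- records[, .(idx = list(.I)), by = .(barcode, mod = ifelse(
            modality == "DNA", "DNA", "RNA"))]
        for (k in seq_len(nrow(grp))) {
            i <- grp$idx[[k]]
            rn <- encodeReadName(records$pair_id[i], records$barcode[i],
                                 records$umi[i], grp$mod[k])
            f1 <- file.path(outDir, sprintf("%s_%s_R1.fastq",
                                            grp$barcode[k], grp$mod[k]))
            f2 <- file.path(outDir, sprintf("%s_%s_R2.fastq",
                                            grp$barcode[k], grp$mod[k]))
            writeFastq(records$insert1[i], records$qual1[i], rn, f1)
            writeFastq(records$insert2[i], records$qual2[i], rn, f2)
            files <- c(files, f1, f2)
        }
    }
    list(records = records[, !c("qual1", "qual2")], stats = stats,
         files = files)
}

#' Write demultiplexing statistics
#'
#' @param stats the `stats` element of [demuxRun()].
#' @param prefix output path prefix; writes `<prefix>_summary.json` and
#'   `<prefix>_per_barcode.tsv`.
#' @return paths, invisibly.
#' @export
writeDemuxStats <- function(stats, prefix) {
    js <- paste0(prefix, "_summary.json")
    tsv <- paste0(prefix, "_per_barcode.tsv")
    jsonlite::write_json(
        stats[c("total_pairs", "valid_pairs", "rna_pairs", "dna_pairs",
                "invalid_reasons")],
        js, auto_unbox = TRUE)
    data.table::fwrite(stats$per_barcode, tsv, sep = "\t")
    invisible(c(js, tsv))
}
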