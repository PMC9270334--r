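#' Generate a barcode whitelist
#'
#' Greedily builds `n` DNA barcodes of the given width with pairwise
#' Hamming distance at least `minHamming`.  The default whitelist (96
#' barcodes, width 8, distance >= 3) mirrors a 96-well barcoding plate;
#' distance 3 makes single-mismatch rescue unambiguous.  Construction is
#' deterministic for a fixed `seed`.
#'
#' @param n number of barcodes.
#' @param width barcode length in nt.
#' @param minHamming minimum pairwise Hamming distance.
#' @param seed seed for the candidate stream.
#' @return character vector of `n` barcodes.
#' @export
makeWhitelist <- function(n, width = 8L, minHamming = 3L, seed = 99L) {
    withSeed(seed, {
        accepted <- matrix(0L, nrow = 0L, ncol = width)
        tries <- 0L
        maxTries <- 500L * n
        while (nrow(accepted) < n) {
            tries <- tries + 1L
            if (tries > maxTries)
                stop("cannot build ", n, " barcodes of width ", width,
                     " at Hamming distance >= ", minHamming,
                     "; use a longer width or smaller distance")
            cand <- sample.int(4L, width, replace = TRUE)
            if (nrow(accepted) == 0L ||
                min(rowSums(accepted != rep(cand, each = nrow(accepted)))) >=
                    minHamming)
                accepted <- rbind(accepted, cand)
        }
        apply(accepted, 1L, function(r)
            paste(c("A", "C", "G", "T")[r], collapse = ""))
    })
}

#' @rdname makeWhitelist
#' @export
defaultWhitelist <- function() {
    if (is.null(.whitelistCache$wl))
        .whitelistCache$wl <- makeWhitelist(96L, 8L, 3L)
    .whitelistCache$wl
}

.whitelistCache <- new.env(parent = emptyenv())

# Place n non-overlapping intervals on the given chromosomes.
placeIntervals <- function(chromLens, n, minWidth, maxWidth, prefix) {
    if (n == 0L)
        return(GRanges())
    chroms <- names(chromLens)
    placed <- lapply(chroms, function(x) IRanges::IRanges())
    names(placed) <- chroms
    out <- vector("list", n)
    for (i in seq_len(n)) {
        ok <- FALSE
        for (try in seq_len(200L)) {
            w <- sample(minWidth:maxWidth, 1L)
            chr <- sample(chroms, 1L, prob = chromLens)
            if (chromLens[chr] < w) next
            s <- sample.int(chromLens[chr] - w + 1L, 1L)
            ir <- IRanges::IRanges(s, s + w - 1L)
            if (!length(IRanges::findOverlaps(ir, placed[[chr]]))) {
                placed[[chr]] <- c(placed[[chr]], ir)
                out[[i]] <- GRanges(chr, ir)
                ok <- TRUE
                break
            }
        }
        if (!ok)
            stop("infeasible placement: could not fit ", n, " ", prefix,
                 " intervals without overlap; enlarge the chromosomes")
    }
    gr <- suppressWarnings(do.call(c, out))
    gr[order(as.character(seqnames(gr)), start(gr))]
}

#' Build a pair of toy genomes
#'
#' Creates two small synthetic genomes (one per species of a barnyard-style
#' mixture) with random ACGT sequence, non-overlapping gene models and
#' non-overlapping peak regions.  Chromosome names are prefixed by species
#' so the two references can be combined for collision analysis.
#'
#' @param seed integer seed; the result is deterministic given it.
#' @param nChrom chromosomes per genome.
#' @param chromLen chromosome length in bp.
#' @param nGenes,nPeaks features per genome.
#' @param geneWidth,peakWidth length-2 integer ranges for feature widths.
#' @return list of two [ToyGenome-class] objects (`speciesA`, `speciesB`).
#' @examples
#' g <- makeToyGenomes(seed = 1, nGenes = 10, nPeaks = 10)
#' g[[1]]
#' @export
makeToyGenomes <- function(seed = 1L, nChrom = 2L, chromLen = 200000L,
                           nGenes = 60L, nPeaks = 80L,
                           geneWidth = c(1500L, 3000L),
                           peakWidth = c(400L, 800L)) {
    withSeed(seed, {
        lapply(c("speciesA", "speciesB"), function(sp) {
            short <- if (sp == "speciesA") "spA" else "spB"
            chromNames <- sprintf("%s_chr%d", short, seq_len(nChrom))
            seqs <- DNAStringSet(randomDna(nChrom, chromLen))
            names(seqs) <- chromNames
            lens <- stats::setNames(rep(chromLen, nChrom), chromNames)
            genes <- placeIntervals(lens, nGenes, geneWidth[1L],
                                    geneWidth[2L], "gene")
            if (length(genes)) {
                strand(genes) <- sample(c("+", "-"), nGenes, replace = TRUE)
                genes$gene_id <- sprintf("%s_gene%04d", short,
                                         seq_len(nGenes))
            }
            peaks <- placeIntervals(lens, nPeaks, peakWidth[1L],
                                    peakWidth[2L], "peak")
            if (length(peaks))
                peaks$peak_id <- sprintf("%s_peak%04d", short,
                                         seq_len(nPeaks))
            methods::new("ToyGenome", speciesLabel = sp, chromosomes = seqs,
                         genes = genes, peaks = peaks)
        })
    })
}

#' Planted cell-type profiles
#'
#' For each species and cell type, builds sampling weights over genes and
#' peaks: a disjoint marker subset per type is up-weighted, so both the RNA
#' and the chromatin modality carry the planted cluster structure.
#'
#' @param genomes list of two [ToyGenome-class] objects.
#' @param nTypes number of cell types.
#' @param markerFraction fraction of features marking each type.
#' @param strength weight multiplier for marker features (non-markers get
#'   weight 1).
#' @param seed integer seed.
#' @return nested list: per species, matrices `geneWeights` and
#'   `peakWeights` (features x types).
#' @export
cellTypeProfiles <- function(genomes, nTypes = 3L, markerFraction = 0.25,
                             strength = 30, seed = 1L) {
    withSeed(seed, {
        out <- lapply(genomes, function(g) {
            mk <- function(nFeat) {
                w <- matrix(1, nrow = nFeat, ncol = nTypes)
                if (nFeat == 0L) return(w)
                nMark <- max(1L, floor(nFeat * markerFraction))
                pool <- sample.int(nFeat)
                for (t in seq_len(nTypes)) {
                    take <- pool[seq_len(min(nMark, length(pool)))]
                    pool <- setdiff(pool, take)
                    w[take, t] <- strength
                }
                w
            }
            list(geneWeights = mk(length(g@genes)),
                 peakWeights = mk(length(g@peaks)))
        })
        names(out) <- vapply(genomes, function(g) g@speciesLabel, "")
        out
    })
}

# Extract genomic subsequences as character; orientation "+" or "-".
extractSeq <- function(chromSeqs, chrom, start, width, strand = NULL) {
    res <- character(length(chrom))
    for (ch in unique(chrom)) {
        i <- chrom == ch
        s <- as.character(chromSeqs[[ch]])
        res[i] <- substring(s, start[i], start[i] + width[i] - 1L)
    }
    if (!is.null(strand) && any(neg <- strand == "-"))
        res[neg] <- as.character(
            Biostrings::reverseComplement(DNAStringSet(res[neg])))
    res
}

# Longest-overlap feature assignment (ties broken by lexicographic id).
# Strand is ignored: both modalities count reads on either strand of a
# feature.
assignFeature <- function(gr, features, idcol) {
    if (!length(features) || !length(gr))
        return(rep(NA_character_, length(gr)))
    hits <- GenomicRanges::findOverlaps(gr, features,
                                        ignore.strand = TRUE)
    if (!length(hits)) return(rep(NA_character_, length(gr)))
    ov <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(gr)[S4Vectors::queryHits(hits)],
        IRanges::ranges(features)[S4Vectors::subjectHits(hits)]))
    ids <- S4Vectors::mcols(features)[[idcol]][S4Vectors::subjectHits(hits)]
    dt <- data.table::data.table(q = S4Vectors::queryHits(hits), ov = ov,
                                 id = ids)
    data.table::setorder(dt, q, -ov, id)
    best <- dt[!duplicated(dt$q)]
    out <- rep(NA_character_, length(gr))
    out[best$q] <- best$id
    out
}

#' Simulate an scPCOR-seq run
#'
#' Emits paired reads with the assay's structure and a complete truth
#' table.  Read2 is `barcode + AGAACCATGTCGTCAGTGT + genomic fragment`.
#' RNA read1 is `6-nt UMI + GAGCG (not-so-random primer) or CCTGCAGG
#' (oligo-dT) + cDNA`; chromatin (DNA) read1 is bare genomic sequence.
#' Doublet barcodes emit reads from two independently sampled latent
#' cells.  Chromatin fragments whose read1 would coincidentally carry an
#' RNA primer motif at the diagnostic positions are re-sampled, so on
#' error-free output the demultiplexer reproduces the truth exactly.
#'
#' @param genomes list of two [ToyGenome-class] objects.
#' @param config a [SimConfig-class].
#' @param profiles output of [cellTypeProfiles()]; built automatically
#'   (seeded from `config@seed`) when `NULL`.
#' @param whitelist barcode whitelist; when `NULL` the default 96-barcode
#'   list is used (or a larger distance-2 list when `nCells > 96`).
#'   Must contain at least `nCells` barcodes.
#' @return list with elements `reads` (data.table: `pair_id`, `read1`,
#'   `read2`), `truth` (data.table, one row per read pair: `pair_id`,
#'   `barcode`, `cell`, `species`, `cell_type`, `modality`, `umi`,
#'   `molecule_id`, `chrom`, `start`, `end`, `strand`, `feature_id`;
#'   coordinates 1-based inclusive), `cells` (latent-cell table),
#'   `whitelist`, and `config`.
#' @export
simulateRun <- function(genomes, config = SimConfig(), profiles = NULL,
                        whitelist = NULL) {
    stopifnot(methods::is(config, "SimConfig"))
    if (is.null(profiles))
        profiles <- cellTypeProfiles(genomes, config@nCellTypes,
                                     seed = deriveSeed(config@seed,
                                                       "profiles"))
    if (is.null(whitelist))
        whitelist <- if (config@nCells <= 96L) defaultWhitelist()
                     else makeWhitelist(config@nCells, config@barcodeLength,
                                        2L)
    if (length(whitelist) < config@nCells)
        stop("whitelist (", length(whitelist), ") smaller than nCells (",
             config@nCells, "): collision-free assignment impossible")
    if (unique(nchar(whitelist)) != config@barcodeLength)
        stop("whitelist width does not match barcodeLength")
    species <- vapply(genomes, function(g) g@speciesLabel, "")

    withSeed(config@seed, {
        barcodes <- sample(whitelist, config@nCells)
        isDoublet <- stats::rbinom(config@nCells, 1L,
                                   config@doubletRate) == 1L
        nLatent <- ifelse(isDoublet, 2L, 1L)
        cells <- data.table::data.table(
            barcode = rep(barcodes, nLatent),
            cell = paste0(rep(barcodes, nLatent),
                          unlist(lapply(nLatent, function(k)
                              if (k == 2L) c("_a", "_b") else ""))),
            species = species[1L + stats::rbinom(sum(nLatent), 1L,
                                                 config@speciesMix)],
            cell_type = sample.int(config@nCellTypes, sum(nLatent),
                                   replace = TRUE))

        rna <- simulateRnaMolecules(cells, genomes, profiles, config)
        dna <- simulateDnaFragments(cells, genomes, profiles, config)
        mol <- data.table::rbindlist(list(rna, dna), fill = TRUE)
        mol[, molecule_id := sprintf("M%07d", seq_len(nrow(mol)))]

        # PCR duplication: each molecule yields 1 + Pois(meanDuplicates)
        # read pairs.
        reps <- 1L + stats::rpois(nrow(mol), config@meanDuplicates)
        truth <- mol[rep(seq_len(nrow(mol)), reps)]
        truth <- truth[sample.int(nrow(truth))]
        truth[, pair_id := sprintf("P%08d", seq_len(nrow(truth)))]

        reads <- buildReads(truth, genomes, config)
        if (config@errorRate > 0) {
            reads$read1 <- injectErrors(reads$read1, config@errorRate)
            reads$read2 <- injectErrors(reads$read2, config@errorRate)
        }
        cols <- c("pair_id", "barcode", "cell", "species", "cell_type",
                  "modality", "umi", "molecule_id", "chrom", "start", "end",
                  "strand", "feature_id")
        list(reads = reads, truth = truth[, cols, with = FALSE],
             cells = cells, whitelist = whitelist, config = config)
    })
}

# Sample RNA molecules for every latent cell (truth coordinates of the
# transcript-derived fragment).  A rnaBackground fraction is drawn
# uniformly from the genome instead of from gene models; the truth gene is
# always the longest-overlap assignment so it matches the quantifier rule.
simulateRnaMolecules <- function(cells, genomes, profiles, config) {
    n <- nrow(cells)
    mol <- cells[rep(seq_len(n), each = config@rnaPerCell)]
    if (nrow(mol) == 0L) return(mol)
    data.table::set(mol, j = "gene_idx", value = NA_integer_)
    isBg <- stats::runif(nrow(mol)) < config@rnaBackground
    for (g in genomes) {
        sp <- g@speciesLabel
        gw <- profiles[[sp]]$geneWeights
        for (t in seq_len(ncol(gw))) {
            i <- which(!isBg & mol$species == sp & mol$cell_type == t)
            if (length(i))
                data.table::set(mol, i = i, j = "gene_idx",
                    value = sample.int(nrow(gw), length(i), replace = TRUE,
                                       prob = gw[, t]))
        }
    }
    parts <- lapply(genomes, function(g) {
        sp <- g@speciesLabel
        m <- mol[mol$species == sp]
        if (nrow(m) == 0L) return(m)
        genes <- g@genes
        chrom <- character(nrow(m)); st <- integer(nrow(m))
        en <- integer(nrow(m)); strn <- rep("+", nrow(m))
        gi <- m$gene_idx
        ig <- which(!is.na(gi))
        if (length(ig)) {
            gx <- gi[ig]
            w <- pmin(config@fragmentLength, width(genes)[gx])
            off <- as.integer(floor(stats::runif(length(ig)) *
                                    (width(genes)[gx] - w + 1L)))
            chrom[ig] <- as.character(seqnames(genes))[gx]
            st[ig] <- start(genes)[gx] + off
            en[ig] <- st[ig] + as.integer(w) - 1L
            strn[ig] <- as.character(strand(genes))[gx]
        }
        ib <- which(is.na(gi))
        if (length(ib)) {
            lens <- stats::setNames(Biostrings::width(g@chromosomes),
                                    names(g@chromosomes))
            chr <- sample(names(lens), length(ib), replace = TRUE,
                          prob = lens)
            w <- config@fragmentLength
            chrom[ib] <- chr
            st[ib] <- 1L + as.integer(floor(stats::runif(length(ib)) *
                                            (lens[chr] - w + 1L)))
            en[ib] <- st[ib] + w - 1L
        }
        m[, `:=`(chrom = chrom, start = st, end = en, strand = strn)]
        m[, feature_id := assignFeature(
              GRanges(chrom, IRanges::IRanges(st, en)), genes, "gene_id")]
        m
    })
    mol <- data.table::rbindlist(parts[vapply(parts, nrow, 1L) > 0L])
    mol[, gene_idx := NULL]
    mol[, umi := randomDna(nrow(mol), config@umiLength)]
    mol[, modality := ifelse(stats::runif(nrow(mol)) < config@nsrFraction,
                             "RNA_NSR", "RNA_DT")]
    mol
}

# Sample chromatin fragments; a fripTarget fraction inside peaks, the rest
# uniform background.  Fragments whose read1 prefix would mimic an RNA
# primer motif are re-sampled so truth matches the classification rule.
simulateDnaFragments <- function(cells, genomes, profiles, config) {
    n <- nrow(cells)
    frag <- cells[rep(seq_len(n), each = config@dnaPerCell)]
    if (nrow(frag) == 0L) return(frag)
    parts <- lapply(genomes, function(g) {
        sp <- g@speciesLabel
        f <- frag[frag$species == sp]
        if (nrow(f) == 0L) return(f)
        pw <- profiles[[sp]]$peakWeights
        lens <- stats::setNames(Biostrings::width(g@chromosomes),
                                names(g@chromosomes))
        sampleCoords <- function(f) {
            m <- nrow(f)
            inPeak <- length(g@peaks) > 0L &
                stats::runif(m) < config@fripTarget
            chrom <- character(m); st <- integer(m); w <- integer(m)
            for (t in unique(f$cell_type)) {
                i <- which(inPeak & f$cell_type == t)
                if (!length(i)) next
                pk <- sample.int(length(g@peaks), length(i), replace = TRUE,
                                 prob = pw[, t])
                wp <- pmin(config@fragmentLength, width(g@peaks)[pk])
                off <- floor(stats::runif(length(i)) *
                             (width(g@peaks)[pk] - wp + 1L))
                chrom[i] <- as.character(seqnames(g@peaks))[pk]
                st[i] <- start(g@peaks)[pk] + as.integer(off)
                w[i] <- as.integer(wp)
            }
            i <- which(!inPeak)
            if (length(i)) {
                chr <- sample(names(lens), length(i), replace = TRUE,
                              prob = lens)
                chrom[i] <- chr
                w[i] <- config@fragmentLength
                st[i] <- 1L + as.integer(floor(stats::runif(length(i)) *
                                               (lens[chr] - w[i] + 1L)))
            }
            data.table::data.table(chrom = chrom, start = st,
                                   end = st + w - 1L)
        }
        co <- sampleCoords(f)
        # reject fragments mimicking an RNA primer motif on read1
        for (iter in seq_len(100L)) {
            r1 <- extractSeq(g@chromosomes, co$chrom, co$start,
                             pmin(config@readLen1, co$end - co$start + 1L))
            bad <- which(substr(r1, 7L, 11L) == "GAGCG" |
                         substr(r1, 7L, 14L) == "CCTGCAGG")
            if (!length(bad)) break
            if (iter == 100L)
                stop("could not sample motif-free chromatin fragments")
            nw <- sampleCoords(f[bad])
            co[bad, `:=`(chrom = nw$chrom, start = nw$start, end = nw$end)]
        }
        f[, `:=`(chrom = co$chrom, start = co$start, end = co$end,
                 strand = "+", feature_id = NA_character_)]
        f[, feature_id := assignFeature(
              GRanges(chrom, IRanges::IRanges(start, end)),
              g@peaks, "peak_id")]
        f
    })
    frag <- data.table::rbindlist(parts[vapply(parts, nrow, 1L) > 0L])
    frag[, `:=`(umi = NA_character_, modality = "DNA")]
    frag
}

# Assemble read sequences for every truth row.
buildReads <- function(truth, genomes, config) {
    chromSeqs <- do.call(c, lapply(genomes, function(g) g@chromosomes))
    l2g <- config@readLen2 - config@barcodeLength - 19L
    read2 <- paste0(truth$barcode, "AGAACCATGTCGTCAGTGT",
                    extractSeq(chromSeqs, truth$chrom, truth$start,
                               pmin(l2g, truth$end - truth$start + 1L)))
    isRna <- truth$modality != "DNA"
    motif <- ifelse(truth$modality == "RNA_NSR", "GAGCG",
             ifelse(truth$modality == "RNA_DT", "CCTGCAGG", ""))
    read1 <- character(nrow(truth))
    if (any(isRna)) {
        cdnaLen <- config@readLen1 - config@umiLength - nchar(motif[isRna])
        w <- pmin(cdnaLen, truth$end[isRna] - truth$start[isRna] + 1L)
        st <- ifelse(truth$strand[isRna] == "-",
                     truth$end[isRna] - w + 1L, truth$start[isRna])
        read1[isRna] <- paste0(truth$umi[isRna], motif[isRna],
                               extractSeq(chromSeqs, truth$chrom[isRna],
                                          st, w, truth$strand[isRna]))
    }
    if (any(!isRna))
        read1[!isRna] <- extractSeq(
            chromSeqs, truth$chrom[!isRna], truth$start[!isRna],
            pmin(config@readLen1,
                 truth$end[!isRna] - truth$start[!isRna] + 1L))
    data.table::data.table(pair_id = truth$pair_id, read1 = read1,
                           read2 = read2)
}

# Uniform per-base substitution errors.
injectErrors <- function(seqs, rate) {
    nchars <- nchar(seqs)
    nmut <- stats::rbinom(length(seqs), nchars, rate)
    hit <- which(nmut > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
        pos <- sample.int(nchars[i], nmut[i])
        s <- strsplit(seqs[i], "")[[1L]]
        s[pos] <- vapply(s[pos],
                         function(b) sample(setdiff(bases, b), 1L), "")
        seqs[i] <- paste(s, collapse = "")
    }
    seqs
}

#' Write simulated reads as paired FASTQ
#'
#' @param sim result of [simulateRun()].
#' @param dir output directory (created if needed).
#' @param gzip compress the files.
#' @return character vector `c(r1 = ..., r2 = ...)` of file paths.
#' @export
writeSimFastq <- function(sim, dir, gzip = FALSE) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    ext <- if (gzip) ".fastq.gz" else ".fastq"
    r1 <- file.path(dir, paste0("sim_R1", ext))
    r2 <- file.path(dir, paste0("sim_R2", ext))
    q1 <- strrep("I", nchar(sim$reads$read1))
    q2 <- strrep("I", nchar(sim$reads$read2))
    writeFastq(sim$reads$read1, q1, sim$reads$pair_id, r1)
    writeFastq(sim$reads$read2, q2, sim$reads$pair_id, r2)
    c(r1 = r1, r2 = r2)
}

#' Truth alignments for a simulated run
#'
#' Bypasses an external aligner: every simulated read pair is converted to
#' one alignment record at its true genomic interval, with the read name
#' carrying barcode/UMI/modality in the demultiplexer's name scheme.
#'
#' @param truth the `truth` table of [simulateRun()].
#' @return [GenomicRanges::GRanges] with metadata columns `pair_id`,
#'   `barcode`, `umi`, `modality` (`RNA` or `DNA`) and `mapq`.
#' @export
truthAlignments <- function(truth) {
    if (nrow(truth) == 0L) {
        gr <- GRanges()
        S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
            pair_id = character(), barcode = character(),
            umi = character(), modality = character(), mapq = integer())
        return(gr)
    }
    mod <- ifelse(truth$modality == "DNA", "DNA", "RNA")
    gr <- GRanges(truth$chrom,
                  IRanges::IRanges(truth$start, truth$end),
                  strand = truth$strand)
    names(gr) <- encodeReadName(truth$pair_id, truth$barcode, truth$umi,
                                mod)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        pair_id = truth$pair_id, barcode = truth$barcode,
        umi = truth$umi, modality = mod,
        mapq = rep(60L, nrow(truth)))
    gr
}

#' Write a truth table as TSV
#'
#' Coordinates are exported 0-based half-open.
#'
#' @param truth the `truth` table of [simulateRun()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
    out <- data.table::copy(truth)
    out[, start := start - 1L]
    data.table::fwrite(out, path, sep = "\t")
    invisible(path)
}
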