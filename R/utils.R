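# Internal helpers.

#' @importFrom data.table data.table := .N .SD .I set setnames fwrite fread
#'   rbindlist as.data.table copy setorder tstrsplit
#' @importFrom stats setNames
#' @importFrom utils head
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so package functions never perturb it.
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

# Derive a named substream seed from a global seed; keeps results < 2^31.
deriveSeed <- function(seed, stream) {
    h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
    as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

# Random DNA strings of a common width.
randomDna <- function(n, width) {
    if (n == 0L) return(character())
    m <- matrix(sample(c("A", "C", "G", "T"), n * width, replace = TRUE),
                nrow = n)
    do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Encode/decode the read-name scheme carrying demux metadata:
#   <pairid>:BC:<barcode>:UMI:<umi|->:MOD:<RNA|DNA>
encodeReadName <- function(pair_id, barcode, umi, modality) {
    umi[is.na(umi) | umi == ""] <- "-"
    mod <- ifelse(modality == "DNA", "DNA", "RNA")
    paste0(pair_id, ":BC:", barcode, ":UMI:", umi, ":MOD:", mod)
}

decodeReadName <- function(names) {
    parts <- data.table::tstrsplit(names, ":", fixed = TRUE)
    if (length(parts) != 7L ||
        !all(parts[[2L]] == "BC") || !all(parts[[4L]] == "UMI") ||
        !all(parts[[6L]] == "MOD")) {
        bad <- which(lengths(regmatches(names, gregexpr(":", names))) != 6L)
        stop("read name does not follow the demux scheme: ",
             names[if (length(bad)) bad[1L] else 1L])
    }
    data.table::data.table(
        pair_id = parts[[1L]], barcode = parts[[3L]],
        umi = ifelse(parts[[5L]] == "-", NA_character_, parts[[5L]]),
        modality = parts[[7L]])
}

# Write a minimal 4-line-per-record FASTQ (plain or gzip by extension).
writeFastq <- function(seqs, quals, names, path) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    if (length(seqs))
        writeLines(as.vector(rbind(paste0("@", names), seqs, "+", quals)),
                   con)
    invisible(path)
}

# Read FASTQ into a data.table(name, seq, qual).
readFastq <- function(path) {
    lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
    if (length(lines) %% 4L != 0L)
        stop("truncated FASTQ: ", path, " (", length(lines), " lines)")
    idx <- seq(1L, length(lines), by = 4L)
    data.table::data.table(
        name = sub("^@", "", sub("\\s.*$", "", lines[idx])),
        seq = lines[idx + 1L], qual = lines[idx + 3L])
}
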