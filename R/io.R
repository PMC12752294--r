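#' Read a genome FASTA
#'
#' Reads plain or gzip-compressed FASTA via Biostrings. Record ids are the
#' first whitespace-delimited token of each header; sequences are
#' uppercased. Duplicate ids, empty files and malformed input are errors.
#'
#' @param path FASTA file (optionally .gz).
#' @return a named `DNAStringSet`.
#' @export
readGenome <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    recs <- Biostrings::readDNAStringSet(path)
    if (length(recs) == 0) stop("empty FASTA: ", path)
    ids <- sub("\\s.*$", "", names(recs))
    if (anyDuplicated(ids))
        stop("duplicate sequence ids in ", path, ": ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    Biostrings::DNAStringSet(stats::setNames(toupper(as.character(recs)),
                                             ids))
}

genomeIdFromPath <- function(path)
    sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path),
        ignore.case = TRUE)

#' Write synteny blocks as a BED-like TSV
#'
#' Canonical serialization of a [SyntenyBlockSet-class]: a header line and
#' one row per (block, genome) with columns `block_id`, `genome`, `contig`,
#' `start` (0-based), `end` (exclusive), `strand`, `num_minimizers`,
#' `reason`. Rows of a block are contiguous, ordered by the input genome
#' order; blocks follow the reference genome's (contig, start) ordering.
#' The discontinuity reason appears on the last row of each block and is
#' `none` elsewhere (and on the final block). Output is byte-identical
#' across re-runs on identical input.
#'
#' @param blockset a [SyntenyBlockSet-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeSyntenyBlocks <- function(blockset, path) {
    stopifnot(is(blockset, "SyntenyBlockSet"))
    b <- blockset@blocks
    if (nrow(b)) {
        lastRow <- !duplicated(b$block_id, fromLast = TRUE)
        b$reason[!lastRow] <- "none"
        b$start <- format(b$start, scientific = FALSE, trim = TRUE)
        b$end <- format(b$end, scientific = FALSE, trim = TRUE)
    }
    data.table::fwrite(b, path, sep = "\t", eol = "\n")
    invisible(path)
}

#' Read a synteny block TSV written by [writeSyntenyBlocks()]
#'
#' @param path TSV file.
#' @param contigLengths optional named list of per-genome contig lengths to
#'   attach.
#' @return a [SyntenyBlockSet-class] (block provenance metadata is not part
#'   of the serialization and comes back empty).
#' @export
readSyntenyBlocks <- function(path, contigLengths = list()) {
    b <- as.data.frame(data.table::fread(path, sep = "\t",
                                         colClasses = list(
                                             character = c("genome",
                                                           "contig",
                                                           "strand",
                                                           "reason"))))
    gids <- unique(b$genome)
    # restore per-block reason from its last row
    if (nrow(b)) {
        lastRow <- !duplicated(b$block_id, fromLast = TRUE)
        rs <- b$reason[lastRow]
        b$reason <- rs[match(b$block_id, b$block_id[lastRow])]
    }
    meta <- data.frame(block_id = unique(b$block_id),
                       head_hash = NA_character_, tail_hash = NA_character_,
                       stringsAsFactors = FALSE)
    new("SyntenyBlockSet", blocks = b, genomeIds = gids,
        contigLengths = contigLengths, blockMeta = meta,
        indelBreaks = character(), params = list())
}

#' Write the machine-readable run report
#'
#' JSON serialization of the run report attached by [runSynteny()]
#' (per-genome coverage, block count, NG50, rejection counts, round-by-round
#' coverage).
#'
#' @param blockset a [SyntenyBlockSet-class] from [runSynteny()].
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
writeRunReport <- function(blockset, path) {
    stopifnot(is(blockset, "SyntenyBlockSet"))
    rep <- blockset@params$report
    if (is.null(rep)) stop("block set carries no run report")
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    invisible(path)
}

#' Write a truth set as a BEDPE-like TSV
#'
#' One row per simulated event: `event`, source contig/start/end,
#' destination contig/start/end, `orientation`.
#'
#' @param truth a [GenomeTruth-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTruth <- function(truth, path) {
    stopifnot(is(truth, "GenomeTruth"))
    ev <- truth@events
    out <- data.frame(event = ev$type, src_contig = ev$src_contig,
                      src_start = ev$src_start, src_end = ev$src_end,
                      dst_contig = ev$dst_contig, dst_start = ev$dst_start,
                      dst_end = ev$dst_end, orientation = ev$orientation,
                      stringsAsFactors = FALSE)
    data.table::fwrite(out, path, sep = "\t", eol = "\n")
    invisible(path)
}

#' Dump a minimizer graph in DOT format
#'
#' @param mgraph a [MinimizerGraph-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeGraphDot <- function(mgraph, path) {
    stopifnot(is(mgraph, "MinimizerGraph"))
    igraph::write_graph(mgraph@graph, path, format = "dot")
    invisible(path)
}

#' Resolve a pipeline configuration from CLI-style arguments
#'
#' Applies the divergence-tier presets ([divergencePresets()]) and then
#' overrides any preset with an explicitly supplied value, mirroring the
#' command-line contract: defaults `k = 24`, `w = 1000`, `fpr = 0.025`;
#' `wRounds` must be strictly decreasing and below `w`.
#'
#' @param fastas character vector of at least two FASTA paths (checked here;
#'   the returned config does not store them).
#' @param k,w,fpr,divergence,indel,merge,blockSize,wRounds see
#'   [syntenyConfig()]; `NULL` means use the preset/default.
#' @return a [SyntenyConfig-class].
#' @export
resolveConfig <- function(fastas = NULL, k = NULL, w = NULL, fpr = NULL,
                          divergence = NULL, indel = NULL, merge = NULL,
                          blockSize = NULL, wRounds = NULL) {
    if (!is.null(fastas) && length(fastas) < 2)
        stop("at least two FASTA paths are required")
    if (!is.null(wRounds) && length(wRounds) > 1 &&
        any(diff(wRounds) >= 0))
        stop("wRounds must be strictly decreasing")
    syntenyConfig(k = k %||% 24L, w = w %||% 1000L, fpr = fpr %||% 0.025,
                  divergence = divergence %||% 1,
                  indel = indel, merge = merge, blockSize = blockSize,
                  wRounds = wRounds)
}
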