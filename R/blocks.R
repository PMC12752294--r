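#' Break a path at contig boundaries
#'
#' Splits a minimizer path at every edge whose endpoint minimizers lie on
#' different contigs in any genome. Sub-paths retaining at least two nodes
#' are kept.
#'
#' @param path character vector of node hashes in path order.
#' @param sketches list of [GenomeSketch-class] resolving each hash to one
#'   occurrence per genome (or a prebuilt occurrence table).
#' @return list of character vectors (sub-paths of length >= 2).
#' @export
breakAtContigBoundaries <- function(path, sketches) {
    occ <- asOccTable(sketches, path)
    if (length(path) < 2) return(list())
    splitAfter <- rep(FALSE, length(path) - 1)
    for (g in unique(occ$genome)) {
        ctg <- occ[J(g, path), contig, on = c("genome", "hash")]
        splitAfter <- splitAfter | (ctg[-length(ctg)] != ctg[-1])
    }
    splitPath(path, splitAfter)
}

# Split a path after the edges flagged TRUE; keep pieces with >= 2 nodes.
splitPath <- function(path, splitAfter) {
    grp <- cumsum(c(0, as.integer(splitAfter)))
    pieces <- unname(split(path, grp))
    pieces[vapply(pieces, length, integer(1)) >= 2]
}

# Accept either a list of sketches or an occurrence data.table; restrict to
# the given hashes.
asOccTable <- function(sketches, hashes = NULL) {
    if (data.table::is.data.table(sketches)) {
        occ <- sketches
    } else {
        if (is(sketches, "GenomeSketch")) sketches <- list(sketches)
        occ <- occurrenceTable(sketches,
                               if (is.null(hashes)) unique(unlist(lapply(
                                   sketches, function(s) minimizers(s)$hash)))
                               else hashes)
    }
    occ
}

#' Orient a block extent from its minimizer positions
#'
#' Computes the fraction of consecutive position pairs that increase: `"+"`
#' when at least 90% increase, `"-"` when at least 90% decrease, otherwise
#' `NA` (unorientable).
#'
#' @param positions numeric vector of minimizer positions in path order
#'   (length >= 2).
#' @param threshold monotonicity fraction required (default 0.9).
#' @return `"+"`, `"-"`, or `NA_character_`.
#' @examples
#' orientExtent(c(10, 20, 30, 40))  # "+"
#' orientExtent(c(40, 30, 20, 10))  # "-"
#' @export
orientExtent <- function(positions, threshold = 0.9) {
    stopifnot(length(positions) >= 2)
    d <- diff(positions)
    fInc <- mean(d > 0)
    fDec <- mean(d < 0)
    if (fInc >= threshold) "+"
    else if (fDec >= threshold) "-"
    else NA_character_
}

#' Indel score of a path edge
#'
#' For each genome the interarrival distance is the absolute difference
#' between the positions of the edge's two minimizers; the indel score is the
#' spread `max - min` of the interarrival distances across genomes. A large
#' score indicates a putative insertion or deletion between the genomes.
#'
#' @param posU,posV numeric vectors of per-genome positions of the edge's two
#'   minimizers (same genome order, no missing values).
#' @return indel score in bases.
#' @examples
#' indelScore(c(100, 100), c(300, 300))    # 0
#' indelScore(c(100, 100), c(300, 1300))   # 1000
#' indelScore(c(0, 0, 0), c(50, 70, 40))   # 30
#' @export
indelScore <- function(posU, posV) {
    if (length(posU) != length(posV))
        stop("posU and posV must align one position per genome")
    if (anyNA(posU) || anyNA(posV))
        stop("missing genome position for a path edge")
    inter <- abs(posU - posV)
    max(inter) - min(inter)
}

# Per-genome position matrix for a path: rows = genomes, cols = path nodes.
pathPositions <- function(path, occ, genomes = NULL) {
    if (is.null(genomes)) genomes <- unique(occ$genome)
    mat <- vapply(genomes, function(g)
        occ[J(g, path), pos, on = c("genome", "hash")],
        numeric(length(path)))
    if (length(path) == 1) mat <- matrix(mat, nrow = 1)
    t(mat)
}

#' Break a path at putative large indels
#'
#' Removes every path edge whose [indelScore()] exceeds the threshold and
#' returns the resulting sub-paths (length >= 2). Removed edges are recorded
#' in the `brokenPairs` attribute (sorted, pipe-joined hash keys) so that
#' downstream merging never bridges a detected indel and the discontinuity
#' can be labelled `indel`.
#'
#' @param path character vector of node hashes.
#' @param sketches sketches or occurrence table resolving the positions.
#' @param indelThreshold maximum tolerated indel score (bases, > 0).
#' @return list of sub-paths with attribute `brokenPairs`.
#' @export
breakAtIndels <- function(path, sketches, indelThreshold) {
    stopifnot(indelThreshold > 0)
    occ <- asOccTable(sketches, path)
    if (length(path) < 2) {
        out <- list()
        attr(out, "brokenPairs") <- character()
        return(out)
    }
    pp <- pathPositions(path, occ)
    scores <- vapply(seq_len(length(path) - 1), function(i)
        indelScore(pp[, i], pp[, i + 1]), numeric(1))
    splitAfter <- scores > indelThreshold
    broken <- if (any(splitAfter)) {
        i <- which(splitAfter)
        pairKey(path[i], path[i + 1])
    } else character()
    out <- splitPath(path, splitAfter)
    attr(out, "brokenPairs") <- broken
    out
}

pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Convert a path to a synteny block
#'
#' Computes one extent per genome: `start` is the smaller terminal k-mer
#' start, `end` the larger terminal k-mer start plus `k` (0-based,
#' half-open), and the strand comes from [orientExtent()] on the genome's
#' positions in path order. A path that cannot be oriented in some genome is
#' rejected (`NULL`).
#'
#' @param path character vector of node hashes (length >= 2), already broken
#'   at contig boundaries.
#' @param sketches sketches or occurrence table.
#' @param k k-mer length used for the sketch.
#' @param reference genome whose orientation is normalized to `+` (the path
#'   traversal direction is arbitrary); default: first genome id in sorted
#'   order.
#' @return data.frame with one row per genome (`genome`, `contig`, `start`,
#'   `end`, `strand`, `num_minimizers`) plus attributes `head_hash` and
#'   `tail_hash`, or `NULL` when unorientable.
#' @export
pathToBlock <- function(path, sketches, k, reference = NULL) {
    occ <- asOccTable(sketches, path)
    genomes <- unique(occ$genome)
    pp <- pathPositions(path, occ, genomes)
    strands <- apply(pp, 1, orientExtent)
    if (anyNA(strands)) return(NULL)
    if (is.null(reference)) reference <- genomes[1]
    if (reference %in% genomes && strands[match(reference, genomes)] == "-") {
        path <- rev(path)
        pp <- pp[, rev(seq_len(ncol(pp))), drop = FALSE]
        strands <- ifelse(strands == "+", "-", "+")
    }
    contigs <- vapply(genomes, function(g)
        occ[J(g, path[1]), contig, on = c("genome", "hash")], character(1))
    startPos <- pmin(pp[, 1], pp[, ncol(pp)])
    endPos <- pmax(pp[, 1], pp[, ncol(pp)])
    out <- data.frame(genome = genomes, contig = unname(contigs),
                      start = unname(startPos), end = unname(endPos) + k,
                      strand = unname(strands),
                      num_minimizers = length(path),
                      stringsAsFactors = FALSE)
    attr(out, "head_hash") <- path[1]
    attr(out, "tail_hash") <- path[length(path)]
    out
}

# Assemble a SyntenyBlockSet from per-path block data.frames.
blockSetFromList <- function(blockList, genomeIds, contigLengths,
                             indelBreaks = character(), params = list()) {
    blockList <- blockList[!vapply(blockList, is.null, logical(1))]
    if (!length(blockList)) {
        empty <- data.frame(block_id = integer(), genome = character(),
                            contig = character(), start = numeric(),
                            end = numeric(), strand = character(),
                            num_minimizers = integer(), reason = character(),
                            stringsAsFactors = FALSE)
        meta <- data.frame(block_id = integer(), head_hash = character(),
                           tail_hash = character(), stringsAsFactors = FALSE)
        return(new("SyntenyBlockSet", blocks = empty, genomeIds = genomeIds,
                   contigLengths = contigLengths, blockMeta = meta,
                   indelBreaks = indelBreaks, params = params))
    }
    ref <- genomeIds[1]
    refKey <- t(vapply(blockList, function(b) {
        i <- match(ref, b$genome)
        c(b$contig[i], sprintf("%015.0f", b$start[i]))
    }, character(2)))
    ord <- order(refKey[, 1], refKey[, 2])
    blockList <- blockList[ord]
    rows <- lapply(seq_along(blockList), function(i) {
        b <- blockList[[i]]
        b$block_id <- i
        b$reason <- "none"
        b[match(genomeIds, b$genome), ]
    })
    blocks <- as.data.frame(data.table::rbindlist(rows))
    blocks <- blocks[, c("block_id", "genome", "contig", "start", "end",
                         "strand", "num_minimizers", "reason")]
    getHash <- function(b, which) {
        h <- attr(b, which)
        if (is.null(h) || is.na(h)) NA_character_ else as.character(h)
    }
    meta <- data.frame(
        block_id = seq_along(blockList),
        head_hash = vapply(blockList, getHash, character(1), "head_hash"),
        tail_hash = vapply(blockList, getHash, character(1), "tail_hash"),
        stringsAsFactors = FALSE)
    new("SyntenyBlockSet", blocks = blocks, genomeIds = genomeIds,
        contigLengths = contigLengths, blockMeta = meta,
        indelBreaks = unique(indelBreaks), params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Filter blocks by minimum size
#'
#' Keeps blocks whose smallest extent length across genomes is strictly
#' greater than `minBlockSize` (the size filter is strict: a block of exactly
#' the threshold length is dropped).
#'
#' @param blockset a [SyntenyBlockSet-class]
#' @param minBlockSize threshold in bases.
#' @return the filtered [SyntenyBlockSet-class]
#' @export
filterBySize <- function(blockset, minBlockSize) {
    stopifnot(is(blockset, "SyntenyBlockSet"))
    b <- data.table::as.data.table(blockset@blocks)
    if (nrow(b) == 0) return(blockset)
    keep <- b[, .(minLen = min(end - start)), by = block_id][
        minLen > minBlockSize, block_id]
    subsetBlocks(blockset, keep)
}

subsetBlocks <- function(blockset, keepIds) {
    b <- blockset@blocks[blockset@blocks$block_id %in% keepIds, ]
    m <- blockset@blockMeta[blockset@blockMeta$block_id %in% keepIds, ]
    # renumber consecutively, preserving order
    old <- unique(b$block_id)
    b$block_id <- match(b$block_id, old)
    m$block_id <- match(m$block_id, old)
    methods::initialize(blockset, blocks = b, blockMeta = m)
}

# Signed gap between consecutive extents along the strand: distance from the
# end of `a` to the start of `b` in reading order.
strandGap <- function(aStart, aEnd, bStart, bEnd, strand) {
    ifelse(strand == "+", bStart - aEnd, aStart - bEnd)
}

# Per-(genome, contig) rank of each block by start coordinate. Two blocks
# are genome-wise adjacent when they share a contig and their ranks differ
# by one (no third block lies between them in that genome).
genomeRanks <- function(b) {
    dt <- data.table::as.data.table(b)
    dt[, rnk := data.table::frank(start, ties.method = "first"),
       by = .(genome, contig)]
    dt[, .(block_id, genome, rnk)]
}

#' Merge collinear synteny blocks
#'
#' Blocks consecutive in the reference ordering (first genome's contig,
#' start) are merged when, in every genome, they lie on the same contig and
#' strand, are adjacent in that genome's block ordering (no other block
#' between them: "consistent positions"), follow each other in strand order,
#' are separated by at most `mergeThreshold` bases, and are not separated by
#' a recorded indel break. Merged extents span both parts; `num_minimizers`
#' is summed. Terminal k-mers of abutting blocks may overlap by up to
#' `k - 1` bases, so gaps down to `-(k - 1)` still count as order-consistent.
#'
#' @param blockset a [SyntenyBlockSet-class]
#' @param mergeThreshold maximum separation in bases.
#' @param k k-mer length (bounds the tolerated terminal overlap).
#' @return a [SyntenyBlockSet-class] with merged blocks.
#' @export
mergeCollinear <- function(blockset, mergeThreshold, k = 24L) {
    stopifnot(is(blockset, "SyntenyBlockSet"))
    b <- blockset@blocks
    ids <- unique(b$block_id)
    if (length(ids) < 2) return(blockset)
    meta <- blockset@blockMeta
    broken <- blockset@indelBreaks
    ranks <- genomeRanks(b)
    data.table::setkey(ranks, block_id, genome)
    perBlock <- split(b, b$block_id)
    perBlock <- perBlock[as.character(ids)]

    merged <- list(perBlock[[1]])
    mergedMeta <- list(meta[meta$block_id == ids[1], ])
    lastId <- ids[1]
    for (i in 2:length(ids)) {
        cur <- perBlock[[i]]
        curMeta <- meta[meta$block_id == ids[i], ]
        prev <- merged[[length(merged)]]
        prevMeta <- mergedMeta[[length(mergedMeta)]]
        adjacent <- all(abs(ranks[J(lastId), rnk] -
                            ranks[J(ids[i]), rnk]) == 1)
        if (adjacent && canMerge(prev, cur, prevMeta, curMeta, broken,
                                 mergeThreshold, k)) {
            comb <- prev
            comb$start <- pmin(prev$start, cur$start)
            comb$end <- pmax(prev$end, cur$end)
            comb$num_minimizers <- prev$num_minimizers + cur$num_minimizers
            merged[[length(merged)]] <- comb
            prevMeta$tail_hash <- curMeta$tail_hash
            mergedMeta[[length(mergedMeta)]] <- prevMeta
        } else {
            merged[[length(merged) + 1L]] <- cur
            mergedMeta[[length(mergedMeta) + 1L]] <- curMeta
        }
        lastId <- ids[i]
    }
    for (i in seq_along(merged)) {
        merged[[i]]$block_id <- i
        mergedMeta[[i]]$block_id <- i
    }
    methods::initialize(blockset,
        blocks = as.data.frame(data.table::rbindlist(merged)),
        blockMeta = as.data.frame(data.table::rbindlist(mergedMeta)))
}

canMerge <- function(prev, cur, prevMeta, curMeta, broken, mergeThreshold,
                     k) {
    if (any(prev$contig != cur$contig)) return(FALSE)
    if (any(prev$strand != cur$strand)) return(FALSE)
    gap <- strandGap(prev$start, prev$end, cur$start, cur$end, prev$strand)
    if (any(gap < -(k - 1)) || any(gap > mergeThreshold)) return(FALSE)
    if (nrow(prevMeta) && nrow(curMeta) &&
        !is.na(prevMeta$tail_hash) && !is.na(curMeta$head_hash) &&
        pairKey(prevMeta$tail_hash, curMeta$head_hash) %in% broken)
        return(FALSE)
    TRUE
}

#' Assign discontinuity reasons between consecutive blocks
#'
#' For each pair of blocks consecutive in the reference ordering, records on
#' the first block the reason it does not continue into the next: the first
#' applicable of `contig` (different contig in some genome), `strand`
#' (different orientation), `indel` (separated by a recorded indel break),
#' `position` (order inconsistent with the strand), or `merge-distance`
#' (separation beyond the merge threshold). The final block is labelled
#' `none`.
#'
#' @param blockset a [SyntenyBlockSet-class], after merging.
#' @param mergeThreshold merge distance used (for the `merge-distance`
#'   label).
#' @param k k-mer length (tolerated terminal overlap).
#' @return the [SyntenyBlockSet-class] with `reason` filled in.
#' @export
assignReasons <- function(blockset, mergeThreshold = Inf, k = 24L) {
    stopifnot(is(blockset, "SyntenyBlockSet"))
    b <- blockset@blocks
    ids <- unique(b$block_id)
    if (!length(ids)) return(blockset)
    meta <- blockset@blockMeta
    broken <- blockset@indelBreaks
    perBlock <- split(b, b$block_id)
    perBlock <- perBlock[as.character(ids)]
    ranks <- genomeRanks(b)
    data.table::setkey(ranks, block_id, genome)
    reasons <- rep("none", length(ids))
    if (length(ids) >= 2) {
        for (i in seq_len(length(ids) - 1)) {
            a <- perBlock[[i]]; d <- perBlock[[i + 1]]
            am <- meta[meta$block_id == ids[i], ]
            dm <- meta[meta$block_id == ids[i + 1], ]
            adjacent <- all(abs(ranks[J(ids[i]), rnk] -
                                ranks[J(ids[i + 1]), rnk]) == 1)
            reasons[i] <- if (any(a$contig != d$contig)) "contig"
            else if (any(a$strand != d$strand)) "strand"
            else if (nrow(am) && nrow(dm) && !is.na(am$tail_hash) &&
                     !is.na(dm$head_hash) &&
                     pairKey(am$tail_hash, dm$head_hash) %in% broken) "indel"
            else if (!adjacent ||
                     any(strandGap(a$start, a$end, d$start, d$end,
                                   a$strand) < -(k - 1))) "position"
            else "merge-distance"
        }
    }
    b$reason <- reasons[match(b$block_id, ids)]
    methods::initialize(blockset, blocks = b)
}
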