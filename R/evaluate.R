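#' Lift a rearranged-genome interval back to source coordinates
#'
#' Maps a half-open interval on the rearranged genome through the truth
#' segment map to the original (source) genome. The result has one row per
#' overlapped segment; inverted segments report `strand == "-"`, novel
#' (inserted) segments have `NA` source coordinates and `novel == TRUE`.
#'
#' @param truth a [GenomeTruth-class].
#' @param contig rearranged-genome contig id.
#' @param start,end 0-based half-open interval.
#' @return data.frame: `src_contig`, `src_start`, `src_end`, `strand`,
#'   `novel`, ordered along the query interval.
#' @export
liftToSource <- function(truth, contig, start, end) {
    stopifnot(is(truth, "GenomeTruth"), start < end)
    s <- truth@segments
    s <- s[s$dst_contig == contig & s$dst_end > start & s$dst_start < end, ]
    if (!nrow(s))
        return(data.frame(src_contig = character(), src_start = numeric(),
                          src_end = numeric(), strand = character(),
                          novel = logical(), stringsAsFactors = FALSE))
    s <- s[order(s$dst_start), ]
    oS <- pmax(s$dst_start, start)
    oE <- pmin(s$dst_end, end)
    srcS <- ifelse(s$strand == "+", s$src_start + (oS - s$dst_start),
                   s$src_end - (oE - s$dst_start))
    srcE <- ifelse(s$strand == "+", s$src_start + (oE - s$dst_start),
                   s$src_end - (oS - s$dst_start))
    data.frame(src_contig = s$src_contig, src_start = srcS, src_end = srcE,
               strand = s$strand, novel = s$novel, stringsAsFactors = FALSE)
}

#' Ground-truth breakpoints in both coordinate systems
#'
#' Every structural event boundary, in source (original genome) and
#' destination (rearranged genome) coordinates: interval events contribute
#' both boundaries, point-like sides (a deletion's destination junction, an
#' insertion's source position) contribute one.
#'
#' @param truth a [GenomeTruth-class].
#' @return list with data.frames `src` and `dst`, each with columns
#'   `contig`, `pos`, `type`.
#' @export
truthBreakpoints <- function(truth) {
    ev <- truth@events
    srcRows <- list(); dstRows <- list()
    for (i in seq_len(nrow(ev))) {
        e <- ev[i, ]
        srcPos <- if (e$type == "insertion") e$src_start else
            c(e$src_start, e$src_end)
        dstPos <- if (e$type == "deletion") e$dst_start else
            c(e$dst_start, e$dst_end)
        srcRows[[i]] <- data.frame(contig = e$src_contig, pos = srcPos,
                                   type = e$type, stringsAsFactors = FALSE)
        dstRows[[i]] <- data.frame(contig = e$dst_contig, pos = dstPos,
                                   type = e$type, stringsAsFactors = FALSE)
    }
    list(src = as.data.frame(data.table::rbindlist(srcRows)),
         dst = as.data.frame(data.table::rbindlist(dstRows)))
}

#' Synteny coverage
#'
#' Mean over genomes of the summed block extent lengths, divided by the
#' length of the smallest compared genome.
#'
#' @param blocks a [SyntenyBlockSet-class], or a block table data.frame.
#' @param genomeLengths named numeric vector of genome lengths; taken from
#'   the block set's contig lengths when omitted.
#' @return coverage fraction (0 when there are no blocks).
#' @examples
#' # extents of 90 and 80 bases over two 100-base genomes: (90+80)/2 / 100
#' @export
syntenyCoverage <- function(blocks, genomeLengths = NULL) {
    if (is(blocks, "SyntenyBlockSet")) {
        if (is.null(genomeLengths))
            genomeLengths <- vapply(blocks@contigLengths, sum, numeric(1))
        genomes <- blocks@genomeIds
        b <- blocks@blocks
    } else {
        b <- blocks
        if (is.null(genomeLengths)) stop("genomeLengths required")
        genomes <- names(genomeLengths)
    }
    if (!nrow(b)) return(0)
    tot <- vapply(genomes, function(g)
        sum(b$end[b$genome == g] - b$start[b$genome == g]), numeric(1))
    mean(tot) / min(genomeLengths)
}

#' Block NG50
#'
#' The largest length L such that blocks of length at least L together cover
#' at least half the genome. When the blocks cover less than half the genome
#' the statistic is undefined and `NA` is returned (the reporting convention
#' for sub-50% coverage).
#'
#' @param lengths numeric vector of block lengths (one genome's extents).
#' @param genomeLength genome length in bases.
#' @return NG50 in bases, or `NA_real_`.
#' @examples
#' blockNG50(c(50, 30, 20), 100)  # 50
#' blockNG50(c(30, 30, 30), 100)  # 30
#' blockNG50(c(10), 100)          # NA
#' @export
blockNG50 <- function(lengths, genomeLength) {
    if (!length(lengths) || sum(lengths) < genomeLength / 2)
        return(NA_real_)
    lengths <- sort(lengths, decreasing = TRUE)
    lengths[which(cumsum(lengths) >= genomeLength / 2)[1]]
}

# Lift one extent to source coordinates and summarize it as a single
# (contig, start, end, orientation) record, or NULL when it cannot be
# summarized (novel sequence, multiple contigs, mixed strands, or gaps
# larger than the tolerance). Pieces no longer than the tolerance are
# boundary slop (e.g. a terminal k-mer overhanging an event junction) and
# are ignored when the remaining pieces agree: boundary agreement is only
# ever asserted to within the tolerance.
liftedExtent <- function(truth, contig, start, end, strand, tolerance) {
    if (is.null(truth)) {
        return(list(contig = contig, start = start, end = end,
                    orient = strand))
    }
    m <- liftToSource(truth, contig, start, end)
    m <- m[!m$novel, ]
    if (!nrow(m)) return(NULL)
    big <- (m$src_end - m$src_start) > tolerance
    if (any(big) && !all(big)) m <- m[big, ]
    if (length(unique(m$src_contig)) != 1) return(NULL)
    if (length(unique(m$strand)) != 1) return(NULL)
    lo <- min(m$src_start); hi <- max(m$src_end)
    if ((hi - lo) - sum(m$src_end - m$src_start) > tolerance) return(NULL)
    orient <- if (m$strand[1] == strand) "+" else "-"
    list(contig = m$src_contig[1], start = lo, end = hi, orient = orient)
}

#' Fraction of synteny blocks consistent with the simulated ground truth
#'
#' A block is correct when every genome's extent, lifted through that
#' genome's truth coordinate map to the original genome, lands on the same
#' contig with the same relative orientation and with boundaries agreeing
#' within `tolerance` bases across all genomes. Genomes without a truth map
#' (the unrearranged original) lift through the identity.
#'
#' @param blockset a [SyntenyBlockSet-class].
#' @param truths named list mapping genome id to [GenomeTruth-class] or
#'   `NULL` (identity). Genomes absent from the list use the identity map.
#' @param tolerance boundary agreement tolerance in bases.
#' @return fraction of correct blocks (`NA` when there are no blocks).
#' @export
blockAccuracy <- function(blockset, truths, tolerance) {
    stopifnot(is(blockset, "SyntenyBlockSet"))
    b <- blockset@blocks
    ids <- unique(b$block_id)
    if (!length(ids)) return(NA_real_)
    ok <- vapply(ids, function(id) {
        rows <- b[b$block_id == id, ]
        lifted <- lapply(seq_len(nrow(rows)), function(i) {
            r <- rows[i, ]
            liftedExtent(truths[[r$genome]], r$contig, r$start, r$end,
                         r$strand, tolerance)
        })
        if (any(vapply(lifted, is.null, logical(1)))) return(FALSE)
        contigs <- vapply(lifted, `[[`, character(1), "contig")
        orients <- vapply(lifted, `[[`, character(1), "orient")
        starts <- vapply(lifted, `[[`, numeric(1), "start")
        ends <- vapply(lifted, `[[`, numeric(1), "end")
        length(unique(contigs)) == 1 && length(unique(orients)) == 1 &&
            (max(starts) - min(starts)) <= tolerance &&
            (max(ends) - min(ends)) <= tolerance
    }, logical(1))
    mean(ok)
}
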