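# Synthetic genomes, structural rearrangements with ground-truth coordinate
# maps, and uniform point variants.

withSeed <- function(seed, expr) {
    if (is.null(seed)) return(force(expr))
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        set.seed(NULL)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    expr
}

randomDNA <- function(n, gc = 0.5) {
    codes <- sample.int(4L, n, replace = TRUE,
                        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    rawToChar(as.raw(c(65L, 67L, 71L, 84L)[codes]))
}

#' Simulate a random genome
#'
#' I.i.d. bases at the requested GC content, split evenly across contigs
#' (remainder to the last). Deterministic under `seed`.
#'
#' @param length total genome length in bases.
#' @param nContigs number of contigs (default 1).
#' @param gc GC fraction (default 0.5).
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param path optional FASTA path; when given the genome is also written
#'   (byte-identical across re-runs at the same seed).
#' @return a named `DNAStringSet` (contig_1, contig_2, ...).
#' @export
simulateGenome <- function(length, nContigs = 1L, gc = 0.5, seed = NULL,
                           path = NULL) {
    stopifnot(length >= nContigs)
    lens <- rep(floor(length / nContigs), nContigs)
    lens[nContigs] <- lens[nContigs] + length - sum(lens)
    seqs <- withSeed(seed, vapply(lens, randomDNA, character(1), gc = gc))
    names(seqs) <- paste0("contig_", seq_len(nContigs))
    out <- Biostrings::DNAStringSet(seqs)
    if (!is.null(path)) Biostrings::writeXStringSet(out, path)
    out
}

#' Specify structural rearrangements
#'
#' Event counts and size ranges for [applyRearrangements()], plus point
#' variant rates for [applyPointVariants()]. The defaults reproduce the
#' study conditions used throughout: 2 translocations of 10--50 kbp, 20
#' inversions of 10--50 kbp, and 20 large indels of 50--100 kbp (split
#' evenly between insertions and deletions). Desk-scale fixtures pass
#' explicit smaller counts.
#'
#' @param nTranslocations,translocationSize count and size range (bases).
#' @param nInversions,inversionSize count and size range.
#' @param nInsertions,insertionSize count and size range.
#' @param nDeletions,deletionSize count and size range.
#' @param snvRate per-base substitution probability in `[0, 0.5)`.
#' @param smallIndelRate per-base small (1--10 bp) indel probability.
#' @param seed integer seed.
#' @return a list of class `RearrangementSpec`.
#' @export
rearrangementSpec <- function(nTranslocations = 2L,
                              translocationSize = c(1e4, 5e4),
                              nInversions = 20L,
                              inversionSize = c(1e4, 5e4),
                              nInsertions = 10L,
                              insertionSize = c(5e4, 1e5),
                              nDeletions = 10L,
                              deletionSize = c(5e4, 1e5),
                              snvRate = 0, smallIndelRate = 0,
                              seed = NULL) {
    stopifnot(all(c(translocationSize, inversionSize, insertionSize,
                    deletionSize) > 0),
              snvRate >= 0, snvRate < 0.5,
              smallIndelRate >= 0, smallIndelRate < 0.5)
    structure(list(nTranslocations = nTranslocations,
                   translocationSize = translocationSize,
                   nInversions = nInversions, inversionSize = inversionSize,
                   nInsertions = nInsertions, insertionSize = insertionSize,
                   nDeletions = nDeletions, deletionSize = deletionSize,
                   snvRate = snvRate, smallIndelRate = smallIndelRate,
                   seed = seed),
              class = "RearrangementSpec")
}

# Sample non-overlapping event intervals (original coordinates) by rejection.
placeEvents <- function(spec, contigLens) {
    events <- list()
    used <- lapply(contigLens, function(...) IRanges::IRanges())
    addInterval <- function(type, size) {
        for (try in 1:1000) {
            ci <- sample.int(length(contigLens), 1,
                             prob = as.numeric(contigLens))
            cn <- names(contigLens)[ci]
            if (contigLens[[ci]] <= size + 2) next
            s <- sample.int(contigLens[[ci]] - size - 1, 1)  # 1-based start
            cand <- IRanges::IRanges(s, s + size - 1)
            if (length(IRanges::findOverlaps(cand, used[[cn]])) > 0) next
            used[[cn]] <<- c(used[[cn]], cand)
            return(list(contig = cn, start = s - 1, end = s - 1 + size))
        }
        stop("could not place a ", type, " of ", size,
             " bases without overlap")
    }
    addPoint <- function(avoidContig = NULL) {
        for (try in 1:1000) {
            ci <- if (!is.null(avoidContig) && length(contigLens) > 1) {
                cand <- setdiff(seq_along(contigLens),
                                match(avoidContig, names(contigLens)))
                cand[sample.int(length(cand), 1)]
            } else sample.int(length(contigLens), 1,
                              prob = as.numeric(contigLens))
            cn <- names(contigLens)[ci]
            p <- sample.int(contigLens[[ci]] - 1, 1)  # 1-based, interior
            inside <- IRanges::findOverlaps(
                IRanges::IRanges(p + 1, p + 1), used[[cn]])
            atEdge <- IRanges::findOverlaps(IRanges::IRanges(p, p),
                                            used[[cn]])
            if (length(inside) > 0 || length(atEdge) > 0) next
            return(list(contig = cn, pos = p))  # 0-based cut position p
        }
        stop("could not place an event destination point")
    }
    sampleSize <- function(range)
        if (range[1] == range[2]) range[1] else
            sample(seq(range[1], range[2]), 1)

    for (i in seq_len(spec$nInversions))
        events[[length(events) + 1L]] <- c(
            list(type = "inversion"),
            addInterval("inversion", sampleSize(spec$inversionSize)))
    for (i in seq_len(spec$nDeletions))
        events[[length(events) + 1L]] <- c(
            list(type = "deletion"),
            addInterval("deletion", sampleSize(spec$deletionSize)))
    for (i in seq_len(spec$nTranslocations)) {
        ev <- c(list(type = "translocation"),
                addInterval("translocation",
                            sampleSize(spec$translocationSize)))
        dest <- addPoint(avoidContig = ev$contig)
        ev$dest_contig <- dest$contig
        ev$dest_pos <- dest$pos
        events[[length(events) + 1L]] <- ev
    }
    for (i in seq_len(spec$nInsertions)) {
        dest <- addPoint()
        events[[length(events) + 1L]] <- list(
            type = "insertion", contig = dest$contig, start = dest$pos,
            end = dest$pos, size = sampleSize(spec$insertionSize))
    }
    events
}

#' Apply structural rearrangements to a genome
#'
#' Inversions reverse-complement a segment in place, deletions remove a
#' segment, insertions add random sequence, and translocations move a
#' segment to another contig (or another position when the genome has a
#' single contig). Events are placed uniformly with rejection sampling
#' against overlap; placement failing after bounded retries is an error.
#' The returned [GenomeTruth-class] records every breakpoint in both
#' coordinate systems and the piecewise segment map used by
#' [liftToSource()].
#'
#' @param genome named character vector, `DNAStringSet`, or FASTA path.
#' @param spec a [rearrangementSpec()].
#' @return list with elements `genome` (named `DNAStringSet`) and `truth`
#'   (a [GenomeTruth-class]).
#' @export
applyRearrangements <- function(genome, spec) {
    stopifnot(inherits(spec, "RearrangementSpec"))
    seqs <- normalizeOneGenome(genome)
    contigLens <- stats::setNames(as.numeric(nchar(seqs)), names(seqs))

    withSeed(spec$seed, {
        events <- placeEvents(spec, contigLens)
        for (i in seq_along(events)) events[[i]]$id <- i

        # cut each source contig into atomic pieces at event boundaries
        cuts <- lapply(contigLens, function(l) c(0, l))
        for (ev in events) {
            cn <- ev$contig
            cuts[[cn]] <- c(cuts[[cn]], ev$start, ev$end)
            if (ev$type == "translocation")
                cuts[[ev$dest_contig]] <- c(cuts[[ev$dest_contig]],
                                            ev$dest_pos)
        }
        cuts <- lapply(cuts, function(x) sort(unique(x)))

        # atomic piece table in source order
        pieces <- data.table::rbindlist(lapply(names(cuts), function(cn) {
            x <- cuts[[cn]]
            data.table::data.table(src_contig = cn, src_start = x[-length(x)],
                                   src_end = x[-1])
        }))
        pieces[, strand := "+"]
        pieces[, role := "keep"]
        pieces[, event := NA_integer_]
        for (i in seq_along(events)) {
            ev <- events[[i]]
            if (ev$type == "insertion") next
            sel <- pieces$src_contig == ev$contig &
                pieces$src_start >= ev$start & pieces$src_end <= ev$end
            pieces$role[sel] <- ev$type
            pieces$event[sel] <- i
        }

        # assemble destination contigs
        novelSeqs <- character()
        outPieces <- list()
        for (cn in names(seqs)) {
            sub <- pieces[src_contig == cn][order(src_start)]
            for (j in seq_len(nrow(sub))) {
                p <- sub[j]
                insHere <- Filter(function(ev) ev$type == "insertion" &&
                                      ev$contig == cn &&
                                      ev$start == p$src_start,
                                  events)
                transHere <- Filter(function(ev)
                    ev$type == "translocation" &&
                        ev$dest_contig == cn && ev$dest_pos == p$src_start,
                    events)
                for (ev in insHere) {
                    idx <- length(novelSeqs) + 1L
                    novelSeqs[idx] <- randomDNA(ev$size)
                    outPieces[[length(outPieces) + 1L]] <-
                        data.table::data.table(
                            dst_contig = cn, src_contig = NA_character_,
                            src_start = NA_real_, src_end = NA_real_,
                            strand = "+", novel = idx,
                            len = ev$size, event = ev$id)
                }
                for (ev in transHere) {
                    src <- pieces[src_contig == ev$contig &
                                  src_start == ev$start & src_end == ev$end]
                    outPieces[[length(outPieces) + 1L]] <-
                        data.table::data.table(
                            dst_contig = cn, src_contig = src$src_contig,
                            src_start = src$src_start,
                            src_end = src$src_end, strand = "+",
                            novel = 0L, len = src$src_end - src$src_start,
                            event = ev$id)
                }
                if (p$role == "deletion" || p$role == "translocation") next
                outPieces[[length(outPieces) + 1L]] <-
                    data.table::data.table(
                        dst_contig = cn, src_contig = p$src_contig,
                        src_start = p$src_start, src_end = p$src_end,
                        strand = if (p$role == "inversion") "-" else "+",
                        novel = 0L, len = p$src_end - p$src_start,
                        event = p$event)
            }
        }
        seg <- data.table::rbindlist(outPieces)
        seg[, dst_end := cumsum(len), by = dst_contig]
        seg[, dst_start := dst_end - len]

        # materialize sequences
        outSeqs <- vapply(unique(seg$dst_contig), function(cn) {
            s <- seg[dst_contig == cn]
            parts <- vapply(seq_len(nrow(s)), function(j) {
                r <- s[j]
                if (r$novel > 0) return(novelSeqs[r$novel])
                piece <- substr(seqs[[r$src_contig]], r$src_start + 1,
                                r$src_end)
                if (r$strand == "-") revcomp(piece) else piece
            }, character(1))
            paste(parts, collapse = "")
        }, character(1))

        truth <- buildTruth(events, seg, contigLens,
                            stats::setNames(as.numeric(nchar(outSeqs)),
                                            names(outSeqs)))
        list(genome = Biostrings::DNAStringSet(outSeqs), truth = truth)
    })
}

revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

normalizeOneGenome <- function(genome) {
    if (methods::is(genome, "DNAStringSet")) {
        s <- as.character(genome)
    } else if (is.character(genome) && length(genome) == 1 &&
               is.null(names(genome)) && file.exists(genome)) {
        s <- as.character(readGenome(genome))
    } else if (is.character(genome)) {
        s <- genome
    } else stop("unsupported genome input")
    if (is.null(names(s))) names(s) <- paste0("contig_", seq_along(s))
    toupper(s)
}

buildTruth <- function(events, seg, srcLens, dstLens) {
    evRows <- lapply(seq_along(events), function(i) {
        ev <- events[[i]]
        m <- seg[seg$event %in% i, ]
        if (ev$type == "deletion") {
            # dst junction: end of the piece preceding the deleted interval
            left <- seg[!is.na(seg$src_start) &
                        seg$src_contig == ev$contig &
                        seg$src_end == ev$start, ]
            junction <- if (nrow(left)) {
                if (left$strand[1] == "+") left$dst_end[1] else
                    left$dst_start[1]
            } else 0
            dstC <- if (nrow(left)) left$dst_contig[1] else ev$contig
            data.frame(type = "deletion", src_contig = ev$contig,
                       src_start = ev$start, src_end = ev$end,
                       dst_contig = dstC, dst_start = junction,
                       dst_end = junction, orientation = "+",
                       stringsAsFactors = FALSE)
        } else if (nrow(m)) {
            data.frame(type = ev$type, src_contig = ev$contig,
                       src_start = ev$start, src_end = ev$end,
                       dst_contig = m$dst_contig[1],
                       dst_start = min(m$dst_start),
                       dst_end = max(m$dst_end),
                       orientation = if (ev$type == "inversion") "-" else
                           "+",
                       stringsAsFactors = FALSE)
        } else NULL
    })
    evRows <- evRows[!vapply(evRows, is.null, logical(1))]
    eventsDF <- if (length(evRows))
        as.data.frame(data.table::rbindlist(evRows)) else
        data.frame(type = character(), src_contig = character(),
                   src_start = numeric(), src_end = numeric(),
                   dst_contig = character(), dst_start = numeric(),
                   dst_end = numeric(), orientation = character(),
                   stringsAsFactors = FALSE)
    segDF <- as.data.frame(seg[, c("dst_contig", "dst_start", "dst_end",
                                    "src_contig", "src_start", "src_end",
                                    "strand"), with = FALSE])
    segDF$novel <- seg$novel > 0
    new("GenomeTruth", events = eventsDF, segments = segDF,
        srcLengths = srcLens, dstLengths = dstLens)
}

#' Introduce uniform SNVs and small indels
#'
#' Each base is substituted independently with probability `snvRate` (to a
#' uniformly chosen different base); small insertions/deletions of 1--10 bp
#' (uniform) are introduced at `smallIndelRate` per base. Small indels shift
#' downstream coordinates, so apply them before relying on a
#' [GenomeTruth-class] map, or restrict accuracy evaluation to fixtures
#' without them.
#'
#' @param genome named character vector, `DNAStringSet`, or FASTA path.
#' @param snvRate substitution probability per base, in `[0, 0.5)`.
#' @param smallIndelRate small-indel probability per base, in `[0, 0.5)`.
#' @param seed integer seed.
#' @return a named `DNAStringSet`.
#' @export
applyPointVariants <- function(genome, snvRate, smallIndelRate = 0,
                               seed = NULL) {
    stopifnot(snvRate >= 0, snvRate < 0.5,
              smallIndelRate >= 0, smallIndelRate < 0.5)
    seqs <- normalizeOneGenome(genome)
    out <- withSeed(seed, vapply(seqs, function(s) {
        r <- charToRaw(s)
        n <- length(r)
        if (snvRate > 0) {
            idx <- which(runif(n) < snvRate)
            if (length(idx)) {
                bases <- c(65L, 67L, 71L, 84L)  # A C G T
                cur <- match(as.integer(r[idx]), bases)
                shift <- sample.int(3L, length(idx), replace = TRUE)
                r[idx] <- as.raw(bases[((cur - 1L + shift) %% 4L) + 1L])
            }
        }
        if (smallIndelRate > 0) {
            pos <- which(runif(n) < smallIndelRate)
            if (length(pos)) {
                isIns <- runif(length(pos)) < 0.5
                lens <- sample.int(10L, length(pos), replace = TRUE)
                chunks <- list()
                prev <- 0L
                for (j in seq_along(pos)) {
                    p <- pos[j]
                    if (p <= prev) next
                    chunks[[length(chunks) + 1L]] <- r[(prev + 1L):p]
                    if (isIns[j]) {
                        chunks[[length(chunks) + 1L]] <-
                            charToRaw(randomDNA(lens[j]))
                        prev <- p
                    } else {
                        prev <- min(n, p + lens[j])
                    }
                }
                if (prev < n)
                    chunks[[length(chunks) + 1L]] <- r[(prev + 1L):n]
                r <- do.call(c, chunks)
            }
        }
        rawToChar(r)
    }, character(1)))
    Biostrings::DNAStringSet(out)
}
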