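#' Divergence-tier parameter presets
#'
#' Default block-resolution thresholds as a function of the estimated maximum
#' sequence divergence between the input genomes. The indel threshold rises
#' with divergence (50 kbp below 2.5%, 100 kbp from 2.5 to 10%, 500 kbp
#' above 10%); the merge threshold (100 kbp), minimum block size (10 kbp)
#' and refinement window schedule (`w/2`, `w/10`) are shared by all tiers.
#' Explicitly supplied parameters always override a preset.
#'
#' @param divergence estimated maximum sequence divergence, percent
#'   (0 to 100).
#' @param w the round-1 window size the schedule is derived from.
#' @return named list: `indel`, `merge`, `blockSize`, `wRounds`.
#' @export
divergencePresets <- function(divergence, w = 1000L) {
    if (divergence < 0 || divergence > 100)
        stop("divergence must be in [0, 100]")
    indel <- if (divergence < 2.5) 50000 else if (divergence <= 10)
        1e5 else 5e5
    wr <- unique(pmax(2, round(c(w / 2, w / 10))))
    wr <- wr[wr < w]
    list(indel = indel, merge = 1e5, blockSize = 1e4, wRounds = wr)
}

#' Construct a pipeline configuration
#'
#' Bundles the sketching and block-resolution parameters for [runSynteny()].
#' Anything left `NULL` is filled from [divergencePresets()] at the given
#' divergence; see [resolveConfig()] for the CLI-flavoured front end.
#'
#' @param k k-mer length (default 24).
#' @param w window size in k-mer starts (default 1000).
#' @param fpr Bloom filter false-positive rate (default 0.025).
#' @param divergence estimated maximum sequence divergence percent
#'   (default 1).
#' @param indel,merge,blockSize,wRounds thresholds; `NULL` means take the
#'   divergence preset. `wRounds = numeric(0)` disables refinement.
#' @param numHashes Bloom filter hashes per level (default 1).
#' @param iterateSimplify simplify the graph to a fixpoint (default FALSE:
#'   single pass).
#' @param mergePerRound merge collinear blocks after each refinement round
#'   (default FALSE: merge once at the end).
#' @return a [SyntenyConfig-class]
#' @export
syntenyConfig <- function(k = 24L, w = 1000L, fpr = 0.025, divergence = 1,
                          indel = NULL, merge = NULL, blockSize = NULL,
                          wRounds = NULL, numHashes = 1L,
                          iterateSimplify = FALSE, mergePerRound = FALSE) {
    preset <- divergencePresets(divergence, w)
    new("SyntenyConfig", k = as.integer(k), w = as.integer(w), fpr = fpr,
        divergence = divergence,
        indel = as.numeric(indel %||% preset$indel),
        merge = as.numeric(merge %||% preset$merge),
        blockSize = as.numeric(blockSize %||% preset$blockSize),
        wRounds = as.numeric(wRounds %||% preset$wRounds),
        numHashes = as.integer(numHashes),
        iterateSimplify = iterateSimplify, mergePerRound = mergePerRound)
}

#' Complement of block coverage within each contig
#'
#' Returns, per genome and contig, the half-open intervals not covered by
#' any block extent. Intervals shorter than `k` (too short to hold a k-mer)
#' are discarded.
#'
#' @param contigLengths named list: genome id -> named numeric vector of
#'   contig lengths.
#' @param blockset a [SyntenyBlockSet-class] (or its block table).
#' @param k minimum useful interval length.
#' @return data.frame with columns `genome`, `contig`, `start`, `end`.
#' @export
uncoveredRegions <- function(contigLengths, blockset, k = 24L) {
    b <- if (is(blockset, "SyntenyBlockSet")) blockset@blocks else blockset
    out <- list()
    for (g in names(contigLengths)) {
        cl <- contigLengths[[g]]
        for (cn in names(cl)) {
            len <- cl[[cn]]
            sel <- b$genome == g & b$contig == cn
            covered <- IRanges::IRanges()
            if (any(sel))
                covered <- IRanges::reduce(IRanges::IRanges(
                    start = b$start[sel] + 1, end = b$end[sel]))
            gaps <- IRanges::setdiff(IRanges::IRanges(1, len), covered)
            gaps <- gaps[IRanges::width(gaps) >= k]
            if (length(gaps))
                out[[length(out) + 1L]] <- data.frame(
                    genome = g, contig = cn,
                    start = IRanges::start(gaps) - 1,
                    end = IRanges::end(gaps), stringsAsFactors = FALSE)
        }
    }
    if (!length(out))
        return(data.frame(genome = character(), contig = character(),
                          start = numeric(), end = numeric(),
                          stringsAsFactors = FALSE))
    as.data.frame(data.table::rbindlist(out))
}

# ---- internal pipeline state ------------------------------------------------

# One round of path construction from an occurrence universe: build graph,
# simplify, weight-filter, extract paths, break at contig boundaries and
# (new plus remembered) indel breaks.
pathsFromUniverse <- function(occ, genomeIds, config, brokenPairs) {
    n <- length(genomeIds)
    # shared-unique within the active universe
    counts <- occ[, .N, by = .(genome, hash)]
    perGenome <- counts[N == 1L, .(ng = .N), by = hash]
    shared <- perGenome[ng == n, hash]
    bad <- unique(counts[N > 1L, hash])
    shared <- sort(setdiff(shared, bad))
    occ <- occ[hash %in% shared]
    data.table::setkey(occ, genome, hash)

    e <- adjacencyEdges(occ, genomeIds)
    g <- igraph::graph_from_data_frame(
        as.data.frame(e), directed = FALSE,
        vertices = data.frame(name = shared, stringsAsFactors = FALSE))
    mg <- new("MinimizerGraph", graph = g, nGenomes = n,
              genomeIds = genomeIds)
    mg <- simplifyGraph(mg, iterate = config@iterateSimplify)
    mg <- filterLowWeight(mg)
    paths <- suppressWarnings(extractPaths(mg))
    rejectedComponents <- attr(paths, "excluded")

    pieces <- list()
    for (p in paths)
        pieces <- c(pieces, breakAtContigBoundaries(p, occ))
    final <- list()
    newBroken <- character()
    for (p in pieces) {
        # re-apply remembered indel breaks before rescoring
        if (length(brokenPairs) && length(p) > 1) {
            keys <- pairKey(p[-length(p)], p[-1])
            p <- splitPath(p, keys %in% brokenPairs)
        } else p <- list(p)
        for (q in p) {
            sub <- breakAtIndels(q, occ, config@indel)
            newBroken <- c(newBroken, attr(sub, "brokenPairs"))
            final <- c(final, sub)
        }
    }
    list(paths = final, occ = occ,
         brokenPairs = unique(c(brokenPairs, newBroken)),
         rejectedComponents = rejectedComponents)
}

blocksFromState <- function(state, genomeIds, contigLengths, config) {
    blockList <- lapply(state$paths, pathToBlock, sketches = state$occ,
                        k = config@k, reference = genomeIds[1])
    rejected <- sum(vapply(blockList, is.null, logical(1)))
    bs <- blockSetFromList(blockList, genomeIds, contigLengths,
                           indelBreaks = state$brokenPairs,
                           params = list(k = config@k, w = config@w))
    attr(bs, "rejectedPaths") <- rejected
    bs
}

#' One refinement round with a smaller window size
#'
#' Computes minimizers at window size `wRound` (same k-mer size and common
#' Bloom filter) over the regions not covered by the current blocks, lifts
#' them to contig coordinates, and merges them into the active minimizer
#' universe (an occurrence whose hash already belongs to a retained path
#' node is dropped; the established occurrence wins). Shared-unique selection,
#' graph construction, simplification, weight filtering, contig and indel
#' breaking are re-run over the extended universe, extending paths at their
#' termini in both directions.
#'
#' @param state internal pipeline state (paths, occurrence table, recorded
#'   indel breaks).
#' @param wRound window size for this round; must be smaller than the
#'   previous round's.
#' @param filter the [CommonKmerFilter-class] of the run.
#' @param seqs named list of genomes (named character vectors of contigs).
#' @param contigLengths named list of per-genome contig length vectors.
#' @param config the [SyntenyConfig-class].
#' @return updated state.
#' @keywords internal
extendRound <- function(state, wRound, filter, seqs, contigLengths, config) {
    if (wRound >= state$wPrev)
        stop("refinement window (", wRound,
             ") must be smaller than the previous round's (", state$wPrev,
             ")")
    genomeIds <- names(seqs)
    bs <- blocksFromState(state, genomeIds, contigLengths, config)
    unc <- uncoveredRegions(contigLengths, bs, config@k)
    newOcc <- list()
    if (nrow(unc) > 0) {
        for (i in seq_len(nrow(unc))) {
            g <- unc$genome[i]; cn <- unc$contig[i]
            sq <- substr(seqs[[g]][[cn]], unc$start[i] + 1, unc$end[i])
            m <- computeMinimizers(sq, config@k, wRound, filter)
            if (nrow(m) > 0) {
                m$pos <- m$pos + unc$start[i]
                m$contig <- cn
                m$genome <- g
                newOcc[[length(newOcc) + 1L]] <- m
            }
        }
    }
    occ <- state$occ
    if (length(newOcc)) {
        add <- data.table::rbindlist(newOcc)
        data.table::setcolorder(add, c("contig", "pos", "strand", "hash",
                                       "genome"))
        retained <- unique(occ$hash)
        add <- add[!(hash %in% retained)]
        occ <- rbind(occ, add)
    }
    res <- pathsFromUniverse(occ, genomeIds, config, state$brokenPairs)
    res$wPrev <- wRound
    res
}

#' Run the full multi-genome synteny pipeline
#'
#' Executes the complete method: common Bloom filter construction, per-genome
#' minimizer sketching, shared-unique selection, minimizer graph
#' construction, simplification and weight filtering, linear path extraction,
#' contig-boundary and indel breaking, optional refinement rounds with
#' decreasing window sizes, then size filtering, collinear merging, and
#' discontinuity-reason assignment.
#'
#' @param genomes two or more genomes: FASTA paths (plain or gzip) or a
#'   named list of `DNAStringSet`/character vectors of contigs.
#' @param config a [SyntenyConfig-class] from [syntenyConfig()] or
#'   [resolveConfig()].
#' @return a [SyntenyBlockSet-class]; its `params` carry the run report
#'   (`report` element: per-genome coverage, block count, per-genome NG50,
#'   rejected path/component counts, round-by-round coverage).
#' @examples
#' \donttest{
#' g <- simulateGenome(2e5, seed = 1)
#' blocks <- runSynteny(list(a = g, b = g),
#'                      syntenyConfig(w = 100, blockSize = 1000))
#' syntenyCoverage(blocks)
#' }
#' @export
runSynteny <- function(genomes, config = syntenyConfig()) {
    stopifnot(is(config, "SyntenyConfig"))
    seqs <- normalizeGenomes(genomes)
    if (length(seqs) < 2) stop("need at least two genomes")
    genomeIds <- names(seqs)
    contigLengths <- lapply(seqs, function(s)
        stats::setNames(as.numeric(nchar(s)), names(s)))
    genomeLengths <- vapply(contigLengths, sum, numeric(1))

    stageMsg("building common Bloom filter (k=%d, fpr=%.4g)", config@k,
             config@fpr)
    filter <- buildCommonFilter(seqs, k = config@k, fpr = config@fpr,
                                numHashes = config@numHashes)

    stageMsg("sketching %d genomes (w=%d)", length(seqs), config@w)
    sketches <- lapply(genomeIds, function(g)
        sketchGenome(seqs[[g]], config@k, config@w, filter, genomeId = g))

    stageMsg("selecting shared-unique minimizers")
    shared <- selectSharedUnique(sketches)
    if (!length(shared)) {
        warning("no shared-unique minimizers; zero synteny blocks")
        bs <- blockSetFromList(list(), genomeIds, contigLengths)
        bs@params$report <- emptyReport(genomeIds)
        return(bs)
    }
    occ <- occurrenceTable(sketches, shared)

    stageMsg("building and filtering minimizer graph over %d nodes",
             length(shared))
    state <- pathsFromUniverse(occ, genomeIds, config, character())
    state$wPrev <- config@w

    roundCoverage <- numeric()
    cov0 <- syntenyCoverage(blocksFromState(state, genomeIds, contigLengths,
                                            config), genomeLengths)
    roundCoverage <- c(round0 = cov0)
    for (wr in config@wRounds) {
        stageMsg("refinement round at w=%d", as.integer(wr))
        state <- extendRound(state, wr, filter, seqs, contigLengths, config)
        if (config@mergePerRound) {
            bs <- blocksFromState(state, genomeIds, contigLengths, config)
            bs <- mergeCollinear(bs, config@merge, config@k)
        }
        covR <- syntenyCoverage(blocksFromState(state, genomeIds,
                                                contigLengths, config),
                                genomeLengths)
        roundCoverage <- c(roundCoverage,
                           stats::setNames(covR, paste0("round_w", wr)))
    }

    stageMsg("finalizing blocks (size filter, merge, reasons)")
    bs <- blocksFromState(state, genomeIds, contigLengths, config)
    rejectedPaths <- attr(bs, "rejectedPaths")
    bs <- filterBySize(bs, config@blockSize)
    bs <- mergeCollinear(bs, config@merge, config@k)
    bs <- assignReasons(bs, config@merge, config@k)
    if (length(bs) == 0)
        warning("zero synteny blocks in final output")
    assertNonOverlap(bs, config@k)

    b <- data.table::as.data.table(bs@blocks)
    perGenomeCov <- if (nrow(b)) {
        covs <- b[, sum(end - start), by = genome]
        stats::setNames(covs$V1 / genomeLengths[covs$genome] * 100,
                        covs$genome)
    } else stats::setNames(rep(0, length(genomeIds)), genomeIds)
    ng50 <- vapply(genomeIds, function(g) {
        lens <- b[genome == g, end - start]
        blockNG50(lens, genomeLengths[[g]])
    }, numeric(1))
    bs@params <- c(bs@params, list(
        config = config,
        report = list(
            genomes = genomeIds,
            genome_lengths = as.list(genomeLengths),
            n_blocks = length(bs),
            per_genome_coverage_pct = as.list(perGenomeCov),
            synteny_coverage_pct = syntenyCoverage(bs, genomeLengths) * 100,
            block_ng50 = as.list(ng50),
            rejected_paths = rejectedPaths,
            non_linear_components = state$rejectedComponents,
            indel_breaks = length(state$brokenPairs),
            round_coverage = as.list(roundCoverage * 100))))
    bs
}

emptyReport <- function(genomeIds) {
    list(genomes = genomeIds, n_blocks = 0L,
         per_genome_coverage_pct = as.list(stats::setNames(
             rep(0, length(genomeIds)), genomeIds)),
         synteny_coverage_pct = 0, block_ng50 = list(),
         rejected_paths = 0L, non_linear_components = 0L,
         indel_breaks = 0L, round_coverage = list())
}

# Output blocks must never overlap within a genome beyond the footprint of
# a terminal k-mer: minimizer uniqueness and disjoint paths keep k-mer
# *starts* distinct, but `end = last start + k` lets the terminal k-mers of
# abutting blocks share up to k - 1 bases. Checked on every pipeline run.
assertNonOverlap <- function(bs, k = 24L) {
    b <- bs@blocks
    if (!nrow(b)) return(invisible(TRUE))
    byGC <- split(b, list(b$genome, b$contig), drop = TRUE)
    for (part in byGC) {
        part <- part[order(part$start), ]
        if (nrow(part) < 2) next
        overlap <- utils::head(part$end, -1) - part$start[-1]
        if (any(overlap >= k))
            stop("internal error: overlapping block extents in genome ",
                 part$genome[1])
    }
    invisible(TRUE)
}

stageMsg <- function(fmt, ...) {
    if (isTRUE(getOption("syntfind.quiet", TRUE))) return(invisible())
    message(sprintf(paste0("[%s] ", fmt), format(Sys.time(), "%H:%M:%S"),
                    ...))
}
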