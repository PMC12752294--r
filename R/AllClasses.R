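#' CommonKmerFilter: Bloom filter of k-mers shared by all genomes
#'
#' The final level of a cascading Bloom filter: level 1 holds every canonical
#' k-mer of the first genome, and each subsequent level holds the k-mers of
#' genome i that were already present in level i-1, so the final level
#' approximates (up to false positives, never false negatives) the k-mer
#' intersection of all input genomes. Queries are strand-invariant; k-mers
#' containing non-ACGT symbols are never inserted and always reported absent.
#'
#' @slot bits raw vector backing the bit array (8 bits per byte).
#' @slot bfsize number of bits, sized by [bloomSize()] from the largest
#'   input genome and the target false-positive rate.
#' @slot k k-mer length in bases.
#' @slot fpr target per-query false-positive rate in (0, 1).
#' @slot numHashes number of hash functions per level (default 1).
#' @slot nGenomes cascade depth, i.e. number of genomes intersected.
#'
#' @seealso [buildCommonFilter()], [kmerContains()]
#' @export
setClass("CommonKmerFilter",
    representation(bits = "raw", bfsize = "numeric", k = "integer",
                   fpr = "numeric", numHashes = "integer",
                   nGenomes = "integer"))

setValidity("CommonKmerFilter", function(object) {
    msg <- NULL
    if (length(object@bfsize) != 1 || object@bfsize < 1)
        msg <- c(msg, "bfsize must be a single value >= 1")
    if (length(object@bits) != ceiling(object@bfsize / 8))
        msg <- c(msg, "bits length inconsistent with bfsize")
    if (object@fpr <= 0 || object@fpr >= 1)
        msg <- c(msg, "fpr must be in (0, 1)")
    if (object@k < 1) msg <- c(msg, "k must be >= 1")
    if (object@numHashes < 1) msg <- c(msg, "numHashes must be >= 1")
    if (object@nGenomes < 2) msg <- c(msg, "nGenomes must be >= 2")
    if (is.null(msg)) TRUE else msg
})

#' GenomeSketch: minimizer sketch of one genome
#'
#' Ordered minimizer occurrences for every contig of a genome, plus the
#' per-genome hash multiplicity map used to enforce within-genome uniqueness
#' when building the minimizer graph.
#'
#' @slot genomeId genome identifier.
#' @slot minimizers data.frame with columns `contig`, `pos` (0-based k-mer
#'   start), `strand`, `hash` (16-char hex of the reported 64-bit hash),
#'   ordered by contig then position.
#' @slot multiplicity named integer vector: hash -> occurrence count over the
#'   whole sketch.
#' @slot genomeLength total bases.
#' @slot contigLengths named numeric vector of contig lengths.
#'
#' @seealso [sketchGenome()], [computeMinimizers()]
#' @export
setClass("GenomeSketch",
    representation(genomeId = "character", minimizers = "data.frame",
                   multiplicity = "integer", genomeLength = "numeric",
                   contigLengths = "numeric"))

setValidity("GenomeSketch", function(object) {
    m <- object@minimizers
    msg <- NULL
    need <- c("contig", "pos", "strand", "hash")
    if (!all(need %in% names(m)))
        msg <- c(msg, "minimizers must have contig, pos, strand, hash")
    if (nrow(m) > 0) {
        byc <- split(m$pos, m$contig)
        if (!all(vapply(byc, function(p) all(diff(p) > 0), logical(1))))
            msg <- c(msg, "positions must strictly increase within a contig")
    }
    if (is.null(msg)) TRUE else msg
})

#' MinimizerGraph: undirected adjacency graph over shared-unique minimizers
#'
#' Nodes are minimizer hashes present in all genomes and unique within each;
#' an edge joins two minimizers adjacent in at least one genome, weighted by
#' the number of genomes supporting the adjacency (`1 <= weight <= n`).
#' Simplification may promote an edge's weight to `n` after removing a noisy
#' alternate-path node.
#'
#' @slot graph an [igraph::igraph] object; vertex names are minimizer hashes,
#'   edge attribute `weight` the genome support, `genomes` the supporting
#'   genome ids (comma-joined).
#' @slot nGenomes number of genomes the graph spans.
#' @slot genomeIds genome identifiers in input order.
#'
#' @seealso [buildMinimizerGraph()], [simplifyGraph()], [filterLowWeight()],
#'   [extractPaths()]
#' @export
setClass("MinimizerGraph",
    representation(graph = "ANY", nGenomes = "integer",
                   genomeIds = "character"))

setValidity("MinimizerGraph", function(object) {
    msg <- NULL
    if (!igraph::is_igraph(object@graph)) msg <- c(msg, "graph must be igraph")
    else {
        w <- igraph::E(object@graph)$weight
        if (length(w) && (any(w < 1) || any(w > object@nGenomes)))
            msg <- c(msg, "edge weights must lie in [1, nGenomes]")
    }
    if (object@nGenomes < 2) msg <- c(msg, "nGenomes must be >= 2")
    if (is.null(msg)) TRUE else msg
})

#' SyntenyBlockSet: multi-genome synteny blocks
#'
#' Container for the blocks produced by the pipeline (or intermediate block
#' stages). The `blocks` table holds one row per (block, genome) with 0-based
#' half-open coordinates; `reason` on a block records the cause of the
#' discontinuity to the next block along the reference ordering
#' (`contig`, `strand`, `indel`, `position`, `merge-distance`, or `none`).
#'
#' @slot blocks data.frame with columns `block_id`, `genome`, `contig`,
#'   `start`, `end`, `strand`, `num_minimizers`, `reason`.
#' @slot genomeIds genome identifiers in input order.
#' @slot contigLengths named list: genome id -> named numeric vector of
#'   contig lengths.
#' @slot blockMeta data.frame with per-block provenance (`block_id`,
#'   `head_hash`, `tail_hash`) used when merging across recorded indel
#'   breaks.
#' @slot indelBreaks character vector of recorded indel-broken node pairs
#'   (sorted, pipe-joined hash keys).
#' @slot params list of the parameters the blocks were computed with.
#'
#' @seealso [runSynteny()], [writeSyntenyBlocks()]
#' @export
setClass("SyntenyBlockSet",
    representation(blocks = "data.frame", genomeIds = "character",
                   contigLengths = "list", blockMeta = "data.frame",
                   indelBreaks = "character", params = "list"))

setValidity("SyntenyBlockSet", function(object) {
    b <- object@blocks
    msg <- NULL
    need <- c("block_id", "genome", "contig", "start", "end", "strand",
              "num_minimizers", "reason")
    if (!all(need %in% names(b)))
        msg <- c(msg, paste("blocks must have columns:",
                            paste(need, collapse = ", ")))
    if (nrow(b) > 0) {
        if (any(b$start >= b$end)) msg <- c(msg, "start must be < end")
        if (any(b$start < 0)) msg <- c(msg, "start must be >= 0")
        if (!all(b$strand %in% c("+", "-"))) msg <- c(msg, "bad strand")
    }
    if (is.null(msg)) TRUE else msg
})

#' GenomeTruth: ground truth for a simulated rearranged genome
#'
#' Records the structural events applied by [applyRearrangements()] and the
#' piecewise-affine coordinate map between the source (original) and
#' destination (rearranged) genome. The segment map is a bijection outside
#' deleted and inserted bases and drives [liftToSource()] and
#' [blockAccuracy()].
#'
#' @slot events data.frame: `type`, `src_contig`, `src_start`, `src_end`,
#'   `dst_contig`, `dst_start`, `dst_end`, `orientation`.
#' @slot segments data.frame: one row per conserved or novel segment of the
#'   rearranged genome, with `dst_contig`, `dst_start`, `dst_end`,
#'   `src_contig`, `src_start`, `src_end`, `strand`, `novel`.
#' @slot srcLengths named numeric: original contig lengths.
#' @slot dstLengths named numeric: rearranged contig lengths.
#'
#' @seealso [applyRearrangements()], [liftToSource()], [truthBreakpoints()]
#' @export
setClass("GenomeTruth",
    representation(events = "data.frame", segments = "data.frame",
                   srcLengths = "numeric", dstLengths = "numeric"))

#' SyntenyConfig: pipeline parameters
#'
#' Sketching and block-resolution parameters for [runSynteny()]. Defaults
#' mirror the method's published defaults (`k = 24`, `w = 1000`,
#' `fpr = 0.025`); the indel/merge/block-size thresholds and refinement
#' window schedule are normally filled in from the divergence presets by
#' [resolveConfig()].
#'
#' @slot k k-mer length (bases).
#' @slot w window size (number of consecutive k-mer starts per window).
#' @slot fpr Bloom filter target false-positive rate.
#' @slot divergence estimated maximum sequence divergence (percent).
#' @slot indel indel score threshold (bases).
#' @slot merge collinear-merge distance threshold (bases).
#' @slot blockSize minimum block size (bases, strict).
#' @slot wRounds strictly decreasing window sizes for refinement rounds
#'   (possibly empty).
#' @slot numHashes Bloom filter hash count.
#' @slot iterateSimplify apply graph simplification to a fixpoint rather
#'   than a single pass.
#' @slot mergePerRound merge collinear blocks after every refinement round
#'   rather than once at the end.
#'
#' @seealso [syntenyConfig()], [resolveConfig()], [divergencePresets()]
#' @export
setClass("SyntenyConfig",
    representation(k = "integer", w = "integer", fpr = "numeric",
                   divergence = "numeric", indel = "numeric",
                   merge = "numeric", blockSize = "numeric",
                   wRounds = "numeric", numHashes = "integer",
                   iterateSimplify = "logical", mergePerRound = "logical"))

setValidity("SyntenyConfig", function(object) {
    msg <- NULL
    if (object@k < 4) msg <- c(msg, "k must be >= 4")
    if (object@w < 2) msg <- c(msg, "w must be >= 2")
    if (object@fpr <= 0 || object@fpr >= 1) msg <- c(msg, "fpr not in (0,1)")
    if (object@indel <= 0) msg <- c(msg, "indel threshold must be > 0")
    if (object@merge < 0) msg <- c(msg, "merge threshold must be >= 0")
    if (object@blockSize < 0) msg <- c(msg, "blockSize must be >= 0")
    wr <- object@wRounds
    if (length(wr)) {
        if (any(wr >= object@w))
            msg <- c(msg, "wRounds must all be smaller than w")
        if (length(wr) > 1 && any(diff(wr) >= 0))
            msg <- c(msg, "wRounds must be strictly decreasing")
        if (any(wr < 2)) msg <- c(msg, "wRounds must be >= 2")
    }
    if (is.null(msg)) TRUE else msg
})
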