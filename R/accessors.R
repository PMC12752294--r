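#' @title Accessors for syntfind classes
#' @description Small accessor generics so user code never touches slots.
#' @param x an object of the documented class
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("kmerLength", function(x) standardGeneric("kmerLength"))
#' @rdname accessors
#' @export
setMethod("kmerLength", "CommonKmerFilter", function(x) x@k)
#' @rdname accessors
#' @export
setMethod("kmerLength", "SyntenyConfig", function(x) x@k)

#' @rdname accessors
#' @export
setGeneric("nGenomes", function(x) standardGeneric("nGenomes"))
#' @rdname accessors
#' @export
setMethod("nGenomes", "CommonKmerFilter", function(x) x@nGenomes)
#' @rdname accessors
#' @export
setMethod("nGenomes", "MinimizerGraph", function(x) x@nGenomes)
#' @rdname accessors
#' @export
setMethod("nGenomes", "SyntenyBlockSet", function(x) length(x@genomeIds))

#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))
#' @rdname accessors
#' @export
setMethod("genomeIds", "MinimizerGraph", function(x) x@genomeIds)
#' @rdname accessors
#' @export
setMethod("genomeIds", "SyntenyBlockSet", function(x) x@genomeIds)
#' @rdname accessors
#' @export
setMethod("genomeIds", "GenomeSketch", function(x) x@genomeId)

#' @rdname accessors
#' @export
setGeneric("minimizers", function(x) standardGeneric("minimizers"))
#' @rdname accessors
#' @export
setMethod("minimizers", "GenomeSketch", function(x) x@minimizers)

#' @rdname accessors
#' @export
setGeneric("multiplicity", function(x) standardGeneric("multiplicity"))
#' @rdname accessors
#' @export
setMethod("multiplicity", "GenomeSketch", function(x) x@multiplicity)

#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setMethod("genomeLength", "GenomeSketch", function(x) x@genomeLength)

#' @rdname accessors
#' @export
setGeneric("contigLengths", function(x) standardGeneric("contigLengths"))
#' @rdname accessors
#' @export
setMethod("contigLengths", "GenomeSketch", function(x) x@contigLengths)
#' @rdname accessors
#' @export
setMethod("contigLengths", "SyntenyBlockSet", function(x) x@contigLengths)

#' @rdname accessors
#' @export
setGeneric("blockTable", function(x) standardGeneric("blockTable"))
#' @rdname accessors
#' @export
setMethod("blockTable", "SyntenyBlockSet",
          function(x) as.data.frame(x@blocks))

#' @rdname accessors
#' @export
setGeneric("minimizerGraph", function(x) standardGeneric("minimizerGraph"))
#' @rdname accessors
#' @export
setMethod("minimizerGraph", "MinimizerGraph", function(x) x@graph)

#' @rdname accessors
#' @export
setGeneric("truthEvents", function(x) standardGeneric("truthEvents"))
#' @rdname accessors
#' @export
setMethod("truthEvents", "GenomeTruth", function(x) x@events)

#' @rdname accessors
#' @export
setGeneric("truthSegments", function(x) standardGeneric("truthSegments"))
#' @rdname accessors
#' @export
setMethod("truthSegments", "GenomeTruth", function(x) x@segments)

#' Number of blocks in a SyntenyBlockSet
#' @param object a [SyntenyBlockSet-class]
#' @return integer block count
#' @export
setMethod("length", "SyntenyBlockSet",
          function(x) length(unique(x@blocks$block_id)))

setMethod("show", "CommonKmerFilter", function(object) {
    cat(sprintf(
        "CommonKmerFilter: k=%d, fpr=%.4g, %d hash(es), %d-genome cascade\n",
        object@k, object@fpr, object@numHashes, object@nGenomes))
    cat(sprintf("  %.0f bits (%.1f MB), %.2f%% set\n", object@bfsize,
        length(object@bits) / 2^20,
        100 * sum(bitcountTable[as.integer(object@bits) + 1L]) /
            object@bfsize))
})

# bit-population lookup for show()
bitcountTable <- vapply(0:255, function(b) sum(bitwAnd(b, 2^(0:7)) > 0),
                        numeric(1))

setMethod("show", "GenomeSketch", function(object) {
    cat(sprintf("GenomeSketch of '%s': %d minimizers over %d contig(s), %s bp\n",
        object@genomeId, nrow(object@minimizers),
        length(object@contigLengths),
        format(object@genomeLength, big.mark = ",")))
})

setMethod("show", "MinimizerGraph", function(object) {
    g <- object@graph
    cat(sprintf(
        "MinimizerGraph over %d genomes: %d nodes, %d edges (%d at weight n)\n",
        object@nGenomes, igraph::vcount(g), igraph::ecount(g),
        sum(igraph::E(g)$weight == object@nGenomes)))
})

setMethod("show", "SyntenyBlockSet", function(object) {
    nb <- length(object)
    cat(sprintf("SyntenyBlockSet: %d block(s) across %d genomes\n",
                nb, length(object@genomeIds)))
    if (nb > 0) {
        b <- data.table::as.data.table(object@blocks)
        span <- b[, sum(end - start), by = genome]
        for (i in seq_len(nrow(span)))
            cat(sprintf("  %s: %s bp in blocks\n", span$genome[i],
                        format(span$V1[i], big.mark = ",")))
    }
})

setMethod("show", "GenomeTruth", function(object) {
    cat(sprintf("GenomeTruth: %d event(s), %d segment(s)\n",
                nrow(object@events), nrow(object@segments)))
})

setMethod("show", "SyntenyConfig", function(object) {
    cat(sprintf(
        "SyntenyConfig: k=%d w=%d fpr=%.4g divergence=%.3g%%\n",
        object@k, object@w, object@fpr, object@divergence))
    cat(sprintf("  indel=%.0f merge=%.0f blockSize=%.0f wRounds=[%s]\n",
        object@indel, object@merge, object@blockSize,
        paste(object@wRounds, collapse = ", ")))
})
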