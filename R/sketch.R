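#' Canonical (strand-invariant) k-mer hash
#'
#' 64-bit hash that is identical for a k-mer and its reverse complement
#' (the minimum of the forward and reverse-complement rotate-xor hashes),
#' returned as a fixed-width 16-character lowercase hex string so that
#' lexicographic order equals unsigned numeric order. K-mers containing
#' non-ACGT symbols hash to `NA`.
#'
#' @param kmers character vector of DNA strings (ACGT, case-insensitive).
#' @return character vector of 16-char hex hashes (`NA` for invalid input).
#' @examples
#' canonicalKmerHash("ACGTACGTACGTACGTACGTACGT") ==
#'     canonicalKmerHash("ACGTACGTACGTACGTACGTACGT") # revcomp of itself
#' @export
canonicalKmerHash <- function(kmers) {
    cpp_canonical_hash_hex(as.character(kmers))
}

#' Second (reporting) hash of the sketch
#'
#' splitmix64 finalizer applied to a hex-encoded 64-bit value. Minimizers are
#' *selected* by the canonical hash but *reported* under this second hash,
#' decorrelating selection from identity.
#'
#' @param hex character vector of 16-char hex values.
#' @return character vector of 16-char hex values.
#' @export
mixHash <- function(hex) {
    cpp_mix_hash_hex(as.character(hex))
}

#' Compute Bloom-filter-restricted minimizers of one sequence
#'
#' Slides a window of `w` consecutive k-mer start positions along the
#' sequence; within each window, among the k-mers that are ACGT-only and
#' (when a filter is given) present in the common Bloom filter, the one with
#' the smallest canonical hash is the window's minimizer (leftmost on ties).
#' A new sketch entry is emitted only when the selected occurrence changes.
#' Sequences holding fewer than `w` k-mers form a single window; windows with
#' no eligible k-mer contribute nothing.
#'
#' @param sequence a single DNA string (or `DNAString`).
#' @param k k-mer length.
#' @param w window size in k-mer starts (window spans `w + k - 1` bases).
#' @param filter a [CommonKmerFilter-class], or `NULL` for an all-pass
#'   filter. When supplied, its `k` must equal `k`.
#' @return data.frame with columns `pos` (0-based k-mer start), `strand`
#'   (`+` when the forward k-mer is the canonical form), and `hash`
#'   (16-char hex of the reported second hash).
#' @export
computeMinimizers <- function(sequence, k, w, filter = NULL) {
    if (methods::is(sequence, "DNAString") ||
        methods::is(sequence, "XString"))
        sequence <- as.character(sequence)
    stopifnot(is.character(sequence), length(sequence) == 1)
    k <- as.integer(k); w <- as.integer(w)
    if (k < 1 || w < 1) stop("k and w must be positive")
    if (!is.null(filter)) {
        stopifnot(is(filter, "CommonKmerFilter"))
        if (filter@k != k)
            stop("filter was built for k=", filter@k, ", not k=", k)
        cpp_minimizers(sequence, k, w, filter@bits, filter@bfsize,
                       filter@numHashes, TRUE)
    } else {
        cpp_minimizers(sequence, k, w, raw(1), 8, 1L, FALSE)
    }
}

#' Sketch a whole genome
#'
#' Applies [computeMinimizers()] to every contig independently and aggregates
#' the per-genome hash multiplicity map used downstream to enforce
#' within-genome uniqueness.
#'
#' @param genome a FASTA path, `DNAStringSet`, or named character vector of
#'   contigs.
#' @param k,w,filter see [computeMinimizers()].
#' @param genomeId identifier for the genome; defaults to the FASTA basename
#'   (without extension) for path input.
#' @return a [GenomeSketch-class]
#' @export
sketchGenome <- function(genome, k, w, filter = NULL, genomeId = NULL) {
    if (is.character(genome) && length(genome) == 1 && is.null(names(genome)) &&
        file.exists(genome)) {
        if (is.null(genomeId)) genomeId <- genomeIdFromPath(genome)
        genome <- as.character(readGenome(genome))
    } else if (methods::is(genome, "DNAStringSet")) {
        genome <- as.character(genome)
    }
    if (!is.character(genome) || length(genome) < 1 || sum(nchar(genome)) == 0)
        stop("genome must be a readable FASTA or non-empty sequence set")
    if (is.null(names(genome)))
        names(genome) <- paste0("contig_", seq_along(genome))
    if (is.null(genomeId)) genomeId <- "genome"
    genome <- toupper(genome)

    per <- lapply(names(genome), function(cn) {
        m <- computeMinimizers(genome[[cn]], k, w, filter)
        if (nrow(m) > 0) m$contig <- cn
        m
    })
    per <- per[vapply(per, nrow, integer(1)) > 0]
    if (length(per)) {
        mz <- data.table::rbindlist(per)
        data.table::setcolorder(mz, c("contig", "pos", "strand", "hash"))
        mz <- as.data.frame(mz)
    } else {
        mz <- data.frame(contig = character(), pos = integer(),
                         strand = character(), hash = character(),
                         stringsAsFactors = FALSE)
    }
    tab <- table(mz$hash)
    mult <- stats::setNames(as.integer(tab), names(tab))
    cl <- stats::setNames(as.numeric(nchar(genome)), names(genome))
    new("GenomeSketch", genomeId = genomeId, minimizers = mz,
        multiplicity = mult, genomeLength = sum(cl), contigLengths = cl)
}

#' Write a sketch to a TSV file (debugging aid)
#'
#' Tab-separated dump with a header line and columns
#' `genome_id`, `contig_id`, `pos`, `strand`, `hash`.
#'
#' @param sketch a [GenomeSketch-class]
#' @param path output file
#' @return the path, invisibly
#' @export
writeSketch <- function(sketch, path) {
    stopifnot(is(sketch, "GenomeSketch"))
    m <- sketch@minimizers
    out <- data.frame(genome_id = sketch@genomeId, contig_id = m$contig,
                      pos = m$pos, strand = m$strand, hash = m$hash)
    data.table::fwrite(out, path, sep = "\t")
    invisible(path)
}
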