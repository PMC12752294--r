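#' Bloom filter size for a target false-positive rate
#'
#' Number of bits for a single-hash Bloom filter expected to hold
#' `genomeSize` distinct k-mers at a per-query false-positive rate `fpr`:
#' `ceiling(-genomeSize / log(1 - fpr))`.
#'
#' @param genomeSize number of elements (bases of the largest input genome).
#' @param fpr target false-positive rate, strictly between 0 and 1.
#' @return number of bits (a whole number, possibly > .Machine$integer.max).
#' @examples
#' bloomSize(100, 0.5)       # 145
#' bloomSize(10, 1 - exp(-1)) # 10
#' @export
bloomSize <- function(genomeSize, fpr) {
    if (!is.numeric(genomeSize) || length(genomeSize) != 1 ||
        is.na(genomeSize) || genomeSize < 1)
        stop("genomeSize must be a single value >= 1")
    if (!is.numeric(fpr) || length(fpr) != 1 || is.na(fpr) ||
        fpr <= 0 || fpr >= 1)
        stop("fpr must be a single value in (0, 1)")
    ceiling(-genomeSize / log(1 - fpr))
}

# Accept FASTA paths, a named list of DNAStringSet, or a list of character
# vectors; return a named list of uppercase character vectors of contigs.
normalizeGenomes <- function(genomes) {
    if (is.character(genomes)) {
        ids <- genomeIdFromPath(genomes)
        if (anyDuplicated(ids))
            stop("genome identifiers (file basenames) collide: ",
                 paste(ids[duplicated(ids)], collapse = ", "))
        out <- lapply(genomes, function(p) {
            recs <- readGenome(p)
            as.character(recs)
        })
        names(out) <- ids
        return(out)
    }
    if (!is.list(genomes)) stop("genomes must be FASTA paths or a list")
    out <- lapply(genomes, function(g) {
        if (methods::is(g, "DNAStringSet")) {
            s <- as.character(g)
            if (is.null(names(s)))
                names(s) <- paste0("contig_", seq_along(s))
            toupper(s)
        } else if (is.character(g)) {
            if (is.null(names(g)))
                names(g) <- paste0("contig_", seq_along(g))
            toupper(g)
        } else stop("each genome must be a DNAStringSet or character vector")
    })
    if (is.null(names(out)) || any(names(out) == ""))
        names(out) <- paste0("genome_", seq_along(out))
    out
}

#' Build the common k-mer Bloom filter across genomes
#'
#' Constructs the cascading Bloom filter whose final level approximates the
#' set of canonical k-mers present in every input genome. Level 1 receives
#' all valid (ACGT-only) k-mers of the first genome; for each subsequent
#' genome only the k-mers already present in the previous level are inserted,
#' with at most two levels resident in memory at a time. Every level is sized
#' by [bloomSize()] using the largest input genome.
#'
#' @param genomes two or more genomes: FASTA paths (plain or gzip), a named
#'   list of `DNAStringSet`, or a named list of character vectors of contigs.
#' @param k k-mer length (default 24).
#' @param fpr per-level target false-positive rate (default 0.025).
#' @param numHashes hash functions per level (default 1, matching the
#'   single-hash sizing formula).
#' @return a [CommonKmerFilter-class]
#' @examples
#' g <- list(a = "ACGTACGTACGTACGTACGTACGTACGT",
#'           b = "ACGTACGTACGTACGTACGTACGTACGT")
#' f <- buildCommonFilter(g, k = 8)
#' kmerContains(f, "ACGTACGT")
#' @export
buildCommonFilter <- function(genomes, k = 24L, fpr = 0.025,
                              numHashes = 1L) {
    seqs <- normalizeGenomes(genomes)
    if (length(seqs) < 2) stop("need at least two genomes")
    if (fpr <= 0 || fpr >= 1) stop("fpr must be in (0, 1)")
    k <- as.integer(k)
    if (is.na(k) || k < 1) stop("k must be a positive integer")
    sizes <- vapply(seqs, function(s) sum(nchar(s)), numeric(1))
    if (any(sizes == 0)) stop("empty genome: ",
                              paste(names(seqs)[sizes == 0], collapse = ", "))
    bfsize <- bloomSize(max(sizes), fpr)
    res <- cpp_bloom_build_cascade(unname(seqs), k, bfsize,
                                   as.integer(numHashes))
    if (any(res$valid_kmers == 0))
        stop("no valid k-mer of length ", k, " in genome(s): ",
             paste(names(seqs)[res$valid_kmers == 0], collapse = ", "))
    new("CommonKmerFilter", bits = res$bits, bfsize = bfsize, k = k,
        fpr = fpr, numHashes = as.integer(numHashes),
        nGenomes = length(seqs))
}

#' Query a CommonKmerFilter
#'
#' Membership test for k-mer strings against the final cascade level. The
#' canonical (strand-invariant) form is queried, so a k-mer and its reverse
#' complement always agree. K-mers containing non-ACGT symbols return
#' `FALSE`; a query whose length differs from the filter's `k` is an error.
#'
#' @param filter a [CommonKmerFilter-class]
#' @param kmers character vector of k-mers (each of length `kmerLength(filter)`)
#' @return logical vector; `TRUE` for every inserted k-mer (no false
#'   negatives), `TRUE` with probability about `fpr` for absent ones.
#' @export
kmerContains <- function(filter, kmers) {
    stopifnot(is(filter, "CommonKmerFilter"))
    kmers <- as.character(kmers)
    bad <- nchar(kmers) != filter@k
    if (any(bad))
        stop("query k-mer length must equal ", filter@k)
    cpp_bloom_contains(filter@bits, filter@bfsize, kmers, filter@k,
                       filter@numHashes)
}
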