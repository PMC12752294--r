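# Independent oracles and fixture builders shared across the suite.

randomSeq <- function(n, gc = 0.5) {
    codes <- sample.int(4L, n, replace = TRUE,
                        prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    rawToChar(as.raw(c(65L, 67L, 71L, 84L)[codes]))
}

revcompStr <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))

allKmers <- function(seq, k) {
    n <- nchar(seq)
    if (n < k) return(character())
    substring(seq, 1:(n - k + 1), k:n)
}

# Exact canonical k-mer set of a genome (character vector of contigs),
# skipping k-mers containing non-ACGT symbols. Canonical form = the
# lexicographically smaller of the k-mer and its reverse complement.
exactCanonicalSet <- function(contigs, k) {
    km <- unlist(lapply(contigs, allKmers, k = k), use.names = FALSE)
    km <- km[grepl("^[ACGT]+$", km)]
    if (!length(km)) return(character())
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(km)))
    unique(pmin(km, rc))
}

# Brute-force per-window minimizer selection: for every window of effW
# consecutive k-mer starts, the eligible k-mer with the smallest canonical
# hash (leftmost on ties), deduplicated by occurrence. Deliberately a
# different algorithm (per-window scan over integer hash ranks) from the
# deque used by the implementation. Returns 0-based positions.
bruteMinimizerPositions <- function(seq, k, w, eligible = NULL) {
    n <- nchar(seq)
    nk <- n - k + 1
    if (nk < 1) return(integer())
    km <- allKmers(seq, k)
    h <- canonicalKmerHash(km)
    ok <- !is.na(h)
    if (!is.null(eligible)) ok <- ok & eligible
    hr <- match(h, sort(unique(h[ok])))  # integer ranks, hex order
    effW <- min(w, nk)
    sel <- integer(0)
    last <- -1L
    for (s in 1:(nk - effW + 1)) {
        idx <- s:(s + effW - 1)
        idx <- idx[ok[idx]]
        if (!length(idx)) next
        m <- idx[which.min(hr[idx])]
        if (m != last) {
            sel <- c(sel, m)
            last <- m
        }
    }
    sel - 1L
}

# Same per-window argmin semantics as bruteMinimizerPositions, derived
# independently via the block prefix/suffix cumulative-minimum construction
# (fast enough for many long sequences). Keys pack (rank, index) so the
# leftmost occurrence wins ties.
slidingArgminPositions <- function(seq, k, w, eligible = NULL) {
    n <- nchar(seq)
    nk <- n - k + 1
    if (nk < 1) return(integer())
    h <- canonicalKmerHash(allKmers(seq, k))
    ok <- !is.na(h)
    if (!is.null(eligible)) ok <- ok & eligible
    r <- match(h, sort(unique(h[ok])))
    key <- r * (nk + 1) + seq_len(nk)
    key[!ok] <- Inf
    effW <- min(w, nk)
    if (effW == nk) {
        m <- min(key)
        if (!is.finite(m)) return(integer())
        return(as.integer(m %% (nk + 1)) - 1L)
    }
    blk <- (seq_len(nk) - 1) %/% effW
    pre <- stats::ave(key, blk, FUN = cummin)
    suf <- rev(stats::ave(rev(key), rev(blk), FUN = cummin))
    s <- seq_len(nk - effW + 1)
    winMin <- pmin(suf[s], pre[s + effW - 1])
    winMin <- winMin[is.finite(winMin)]
    if (!length(winMin)) return(integer())
    idx <- as.integer(winMin %% (nk + 1))
    idx[c(TRUE, diff(idx) != 0)] - 1L
}

# Minimal GenomeSketch from a minimizer table (hash/contig/pos/strand).
makeSketch <- function(genomeId, df, contigLengths = NULL) {
    df <- df[order(df$contig, df$pos), ]
    tab <- table(df$hash)
    if (is.null(contigLengths)) {
        cl <- tapply(df$pos, df$contig, function(p) max(p) + 100)
        contigLengths <- stats::setNames(as.numeric(cl), names(cl))
    }
    new("GenomeSketch", genomeId = genomeId,
        minimizers = df[, c("contig", "pos", "strand", "hash")],
        multiplicity = stats::setNames(as.integer(tab), names(tab)),
        genomeLength = sum(contigLengths), contigLengths = contigLengths)
}

# Occurrence table (data.table keyed by genome, hash) from per-genome
# position lists: occFromPositions(list(g1 = c(A = 10, B = 20, ...), ...))
occFromPositions <- function(posLists, contigLists = NULL) {
    rows <- lapply(names(posLists), function(g) {
        p <- posLists[[g]]
        ctg <- if (!is.null(contigLists)) contigLists[[g]] else
            rep("c1", length(p))
        data.table::data.table(genome = g, contig = ctg,
                               pos = as.numeric(p), strand = "+",
                               hash = names(p))
    })
    occ <- data.table::rbindlist(rows)
    data.table::setkey(occ, genome, hash)
    occ
}

# Hand-built two-genome bubble: path a-u-v-b (weight-n outer edges), noisy
# middle z on an alternate u-z-v detour, direct u-v edge of weight 1.
# u and v are partially anchored (degree 3, one incident weight-n edge).
bubbleGraphEdges <- function(prefix = "") {
    nm <- function(x) paste0(prefix, x)
    data.frame(
        u = c(nm("a"), nm("u"), nm("u"), nm("z"), nm("v")),
        v = c(nm("u"), nm("v"), nm("z"), nm("v"), nm("b")),
        weight = c(2, 1, 1, 1, 2),
        stringsAsFactors = FALSE)
}
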