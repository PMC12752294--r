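# Canonical hashing and windowed minimizer selection.

test_that("canonical hash is strand-invariant and deterministic", {
    set.seed(51)
    km <- vapply(1:500, function(i) randomSeq(24), character(1))
    rc <- vapply(km, revcompStr, character(1))
    expect_identical(canonicalKmerHash(km), canonicalKmerHash(rc))
    expect_identical(canonicalKmerHash(km), canonicalKmerHash(tolower(km)))
    # palindromic k-mer (its own reverse complement) is well-defined
    pal <- "ACGTACGTACGTACGTACGTACGT"
    expect_identical(pal, revcompStr(pal))
    expect_match(canonicalKmerHash(pal), "^[0-9a-f]{16}$")
    expect_true(is.na(canonicalKmerHash("ACGTNCGTACGTACGTACGTACGT")))
})

test_that("distinct random k-mers essentially never collide", {
    set.seed(52)
    km <- unique(vapply(1:20000, function(i) randomSeq(24), character(1)))
    h <- canonicalKmerHash(km)
    # canonical hashing maps a k-mer and its revcomp together; none of
    # these random 24-mers are mutual revcomps
    expect_equal(anyDuplicated(h), 0)
})

test_that("windowed selection matches the brute-force oracle", {
    set.seed(53)
    for (i in 1:10) {
        s <- randomSeq(2000)
        for (w in c(5, 10, 50)) {
            got <- computeMinimizers(s, 24, w)
            expect_identical(got$pos, bruteMinimizerPositions(s, 24, w),
                             info = sprintf("seq %d, w %d", i, w))
        }
    }
})

test_that("a single-k-mer sequence sketches to that k-mer", {
    s <- "ACGTTGCAACGGTCATAGCCTGAA"  # 24 bases
    m <- computeMinimizers(s, 24, 1000)
    expect_equal(nrow(m), 1)
    expect_equal(m$pos, 0)
    expect_identical(m$hash, mixHash(canonicalKmerHash(s)))
})

test_that("sequences shorter than k and windows without eligible k-mers", {
    expect_equal(nrow(computeMinimizers("ACGT", 24, 10)), 0)
    masked <- paste0(strrep("N", 50), randomSeq(100), strrep("N", 50))
    m <- computeMinimizers(masked, 24, 10)
    expect_true(all(m$pos >= 50 & m$pos <= 150 - 24))
})

test_that("a common filter masks minimizers from the excluded region", {
    set.seed(54)
    s <- randomSeq(10000)
    other <- paste0(substr(s, 1, 4000), randomSeq(1000), substr(s, 5001,
                                                                10000))
    # region 4000-5000 differs between the genomes, so its k-mers are not
    # in the common filter; a tight fpr keeps false positives out
    f <- buildCommonFilter(list(a = c(c1 = s), b = c(c1 = other)),
                           k = 24, fpr = 1e-4)
    m <- computeMinimizers(s, 24, 10, f)
    expect_false(any(m$pos > 4000 - 24 & m$pos < 5000))
    # and the windowed result still matches the oracle under the same
    # eligibility
    eligible <- kmerContains(f, allKmers(s, 24))
    expect_identical(m$pos, bruteMinimizerPositions(s, 24, 10, eligible))
})

test_that("halving w never decreases sketch density", {
    set.seed(55)
    s <- randomSeq(20000)
    sizes <- vapply(c(200, 100, 50, 25), function(w)
        nrow(computeMinimizers(s, 24, w)), numeric(1))
    expect_true(all(diff(sizes) >= 0))
})

test_that("sketching the reverse complement preserves the hash multiset", {
    set.seed(56)
    s <- randomSeq(5000)
    m1 <- computeMinimizers(s, 24, 10)
    m2 <- computeMinimizers(revcompStr(s), 24, 10)
    expect_identical(sort(m1$hash), sort(m2$hash))
    # positions mirror within the k-mer footprint
    expect_setequal(m1$pos, nchar(s) - 24 - m2$pos)
})

test_that("sketchGenome aggregates contigs independently", {
    set.seed(57)
    c1 <- randomSeq(3000); c2 <- randomSeq(2000); c3 <- randomSeq(2500)
    ska <- sketchGenome(c(A = c1, B = c2, C = c3), 24, 10, genomeId = "g")
    skb <- sketchGenome(c(C = c3, A = c1, B = c2), 24, 10, genomeId = "g")
    for (ct in c("A", "B", "C")) {
        ma <- minimizers(ska); mb <- minimizers(skb)
        a <- ma[ma$contig == ct, c("pos", "hash")]; rownames(a) <- NULL
        b <- mb[mb$contig == ct, c("pos", "hash")]; rownames(b) <- NULL
        expect_identical(a, b)
    }
    # duplicated contigs force multiplicity >= 2 for every hash
    dup <- sketchGenome(c(A = c1, B = c1), 24, 10, genomeId = "g")
    expect_true(all(multiplicity(dup) >= 2))
    # single-contig multiplicities equal the per-contig sketch counts
    one <- sketchGenome(c(A = c1), 24, 10, genomeId = "g")
    expect_identical(multiplicity(one)[sort(unique(minimizers(one)$hash))],
                     stats::setNames(as.integer(table(minimizers(one)$hash)),
                                     sort(unique(minimizers(one)$hash))))
})
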