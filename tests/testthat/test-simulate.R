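# Genome simulator, rearrangement engine, truth maps, point variants.

test_that("simulateGenome is deterministic, GC-accurate, multi-contig", {
    f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
    simulateGenome(10000, seed = 9, path = f1)
    simulateGenome(10000, seed = 9, path = f2)
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)))
    g <- simulateGenome(1e6, gc = 0.5, seed = 10)
    gcFrac <- mean(strsplit(as.character(g[[1]]), "")[[1]] %in% c("G", "C"))
    expect_lt(abs(gcFrac - 0.5), 0.01)
    g3 <- simulateGenome(9000, nContigs = 3, seed = 11)
    expect_length(g3, 3)
    expect_equal(sum(Biostrings::width(g3)), 9000)
})

test_that("zero events is the identity with an empty truth set", {
    g <- simulateGenome(5000, seed = 12)
    spec <- rearrangementSpec(nTranslocations = 0, nInversions = 0,
                              nInsertions = 0, nDeletions = 0, seed = 1)
    res <- applyRearrangements(g, spec)
    expect_identical(as.character(res$genome), as.character(g))
    expect_equal(nrow(truthEvents(res$truth)), 0)
})

test_that("an inversion equals a manual reverse-complement splice", {
    g <- simulateGenome(60000, seed = 13)
    spec <- rearrangementSpec(nTranslocations = 0, nInversions = 1,
                              inversionSize = c(10000, 10000),
                              nInsertions = 0, nDeletions = 0, seed = 14)
    res <- applyRearrangements(g, spec)
    ev <- truthEvents(res$truth)
    s <- as.character(g[[1]])
    manual <- paste0(substr(s, 1, ev$src_start),
                     revcompStr(substr(s, ev$src_start + 1, ev$src_end)),
                     substr(s, ev$src_end + 1, nchar(s)))
    expect_identical(as.character(res$genome[[1]]), manual)
    expect_identical(ev$orientation, "-")
})

test_that("deletions and insertions conserve length bookkeeping", {
    g <- simulateGenome(2e5, seed = 15)
    spec <- rearrangementSpec(nTranslocations = 0, nInversions = 0,
                              nInsertions = 0, nDeletions = 1,
                              deletionSize = c(50000, 50000), seed = 16)
    res <- applyRearrangements(g, spec)
    expect_equal(sum(Biostrings::width(res$genome)), 2e5 - 50000)

    spec2 <- rearrangementSpec(nTranslocations = 0, nInversions = 0,
                               nInsertions = 1,
                               insertionSize = c(30000, 30000),
                               nDeletions = 0, seed = 17)
    res2 <- applyRearrangements(g, spec2)
    expect_equal(sum(Biostrings::width(res2$genome)), 2e5 + 30000)
})

test_that("translocations move segments across contigs and conserve bases", {
    g <- simulateGenome(2e5, nContigs = 2, seed = 18)
    spec <- rearrangementSpec(nTranslocations = 1,
                              translocationSize = c(20000, 20000),
                              nInversions = 0, nInsertions = 0,
                              nDeletions = 0, seed = 19)
    res <- applyRearrangements(g, spec)
    ev <- truthEvents(res$truth)
    expect_identical(ev$type, "translocation")
    expect_false(ev$src_contig == ev$dst_contig)
    expect_equal(sum(Biostrings::width(res$genome)), 2e5)
    moved <- substr(as.character(g[[ev$src_contig]]), ev$src_start + 1,
                    ev$src_end)
    landed <- substr(as.character(res$genome[[ev$dst_contig]]),
                     ev$dst_start + 1, ev$dst_end)
    expect_identical(landed, moved)
})

test_that("the truth lift map round-trips conserved coordinates", {
    g <- simulateGenome(3e5, seed = 20)
    spec <- rearrangementSpec(nTranslocations = 0, nInversions = 2,
                              inversionSize = c(10000, 20000),
                              nInsertions = 1, insertionSize = c(5000, 5000),
                              nDeletions = 1, deletionSize = c(5000, 5000),
                              seed = 21)
    res <- applyRearrangements(g, spec)
    seg <- truthSegments(res$truth)
    conserved <- seg[!seg$novel, ]
    src <- as.character(g[[1]])
    dst <- as.character(res$genome[[1]])
    for (i in seq_len(nrow(conserved))) {
        r <- conserved[i, ]
        lifted <- liftToSource(res$truth, r$dst_contig, r$dst_start,
                               r$dst_end)
        expect_equal(lifted$src_start, r$src_start)
        expect_equal(lifted$src_end, r$src_end)
        # the mapped sequence content agrees (modulo strand)
        dstPart <- substr(dst, r$dst_start + 1, r$dst_end)
        srcPart <- substr(src, r$src_start + 1, r$src_end)
        if (r$strand == "-") srcPart <- revcompStr(srcPart)
        expect_identical(dstPart, srcPart)
    }
    # sub-intervals lift consistently too
    r <- conserved[which.max(conserved$dst_end - conserved$dst_start), ]
    mid <- floor((r$dst_start + r$dst_end) / 2)
    lifted <- liftToSource(res$truth, r$dst_contig, mid, mid + 100)
    expect_equal(lifted$src_end - lifted$src_start, 100)
})

test_that("point variants hit binomial expectations and obey the seed", {
    g <- simulateGenome(1e6, seed = 22)
    v1 <- applyPointVariants(g, snvRate = 0.01, seed = 23)
    v2 <- applyPointVariants(g, snvRate = 0.01, seed = 23)
    expect_identical(as.character(v1), as.character(v2))
    a <- strsplit(as.character(g[[1]]), "")[[1]]
    b <- strsplit(as.character(v1[[1]]), "")[[1]]
    nSub <- sum(a != b)
    expect_lt(abs(nSub - 10000), 3 * sqrt(10000 * 0.99))
    # zero rates are the identity
    expect_identical(as.character(applyPointVariants(g, 0, 0, seed = 2)),
                     as.character(g))
    # small indels change the length
    vi <- applyPointVariants(g, 0, 0.001, seed = 24)
    expect_false(Biostrings::width(vi) == 1e6)
})

test_that("truth breakpoints cover both coordinate systems", {
    g <- simulateGenome(2e5, seed = 25)
    spec <- rearrangementSpec(nTranslocations = 0, nInversions = 1,
                              inversionSize = c(20000, 20000),
                              nInsertions = 0, nDeletions = 1,
                              deletionSize = c(10000, 10000), seed = 26)
    res <- applyRearrangements(g, spec)
    bp <- truthBreakpoints(res$truth)
    ev <- truthEvents(res$truth)
    inv <- ev[ev$type == "inversion", ]
    expect_true(all(c(inv$src_start, inv$src_end) %in%
                        bp$src$pos[bp$src$type == "inversion"]))
    del <- ev[ev$type == "deletion", ]
    expect_equal(sum(bp$dst$type == "deletion"), 1)  # single dst junction
    expect_equal(sum(bp$src$type == "deletion"), 2)
})
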