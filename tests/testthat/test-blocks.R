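# Path -> block conversion: breaking, orientation, scoring, size filter,
# merging, discontinuity reasons.

test_that("orientExtent applies the 90% monotonicity rule at the boundary", {
    expect_identical(orientExtent(c(10, 20, 30, 40)), "+")
    expect_identical(orientExtent(c(40, 30, 20, 10)), "-")
    # 10 steps: 9 increasing / 1 decreasing meets the threshold exactly
    nineOfTen <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 85, 95)
    expect_length(diff(nineOfTen), 10)
    expect_identical(orientExtent(nineOfTen), "+")
    eightOfTen <- c(10, 20, 30, 40, 50, 60, 70, 65, 80, 75, 95)
    expect_identical(orientExtent(eightOfTen), NA_character_)
})

test_that("indelScore is the cross-genome interarrival spread", {
    expect_equal(indelScore(c(100, 100), c(300, 300)), 0)
    expect_equal(indelScore(c(100, 100), c(300, 1300)), 1000)
    expect_equal(indelScore(c(0, 0, 0), c(50, 70, 40)), 30)
    expect_error(indelScore(c(1, 2), c(3)), "align")
    expect_error(indelScore(c(1, NA), c(3, 4)), "missing")
})

test_that("paths split at contig switches in any genome", {
    path <- c("A", "B", "C", "D", "E")
    pos <- list(g1 = c(A = 10, B = 20, C = 30, D = 40, E = 50),
                g2 = c(A = 10, B = 20, C = 30, D = 40, E = 50))
    sameCtg <- occFromPositions(pos)
    expect_identical(breakAtContigBoundaries(path, sameCtg), list(path))

    # genome 2 switches contig between B and C
    occ2 <- occFromPositions(pos, contigLists = list(
        g1 = rep("c1", 5), g2 = c("c1", "c1", "c2", "c2", "c2")))
    expect_identical(breakAtContigBoundaries(path, occ2),
                     list(c("A", "B"), c("C", "D", "E")))

    # two genomes switching at different edges -> three sub-paths
    occ3 <- occFromPositions(pos, contigLists = list(
        g1 = c("c1", "c1", "c1", "c2", "c2"),
        g2 = c("c1", "c1", "c2", "c2", "c2")))
    expect_identical(breakAtContigBoundaries(path, occ3),
                     list(c("A", "B"), c("D", "E")))
})

test_that("indel breaking removes exactly the high-spread edges", {
    path <- c("A", "B", "C", "D")
    # genome 2 has a 5 kb insertion between B and C
    occ <- occFromPositions(list(
        g1 = c(A = 0, B = 100, C = 200, D = 300),
        g2 = c(A = 0, B = 100, C = 5200, D = 5300)))
    out <- breakAtIndels(path, occ, 1000)
    expect_identical(unclass(out)[1:2], list(c("A", "B"), c("C", "D")))
    expect_identical(attr(out, "brokenPairs"), syntfind:::pairKey("B", "C"))
    # identical genomes: nothing breaks
    occ0 <- occFromPositions(list(g1 = c(A = 0, B = 100, C = 200, D = 300),
                                  g2 = c(A = 0, B = 100, C = 200, D = 300)))
    expect_identical(breakAtIndels(path, occ0, 1000)[[1]], path)
    # effectively infinite threshold: unchanged
    expect_identical(breakAtIndels(path, occ, Inf)[[1]], path)
})

test_that("pathToBlock computes extents, strands and rejections", {
    path <- c("A", "B", "C", "D")
    occ <- occFromPositions(list(
        g1 = c(A = 100, B = 200, C = 300, D = 400),
        g2 = c(A = 100, B = 200, C = 300, D = 400)))
    b <- pathToBlock(path, occ, k = 24, reference = "g1")
    expect_equal(b$start, c(100, 100))
    expect_equal(b$end, c(424, 424))
    expect_identical(b$strand, c("+", "+"))
    expect_equal(b$num_minimizers[1], 4)

    # genome 2 reversed: '-' strand, same span
    occr <- occFromPositions(list(
        g1 = c(A = 100, B = 200, C = 300, D = 400),
        g2 = c(A = 400, B = 300, C = 200, D = 100)))
    br <- pathToBlock(path, occr, k = 24, reference = "g1")
    expect_identical(br$strand, c("+", "-"))
    expect_equal(br$start, c(100, 100))
    expect_equal(br$end, c(424, 424))

    # shuffled genome-2 positions: unorientable, rejected
    occs <- occFromPositions(list(
        g1 = c(A = 100, B = 200, C = 300, D = 400),
        g2 = c(A = 300, B = 100, C = 400, D = 200)))
    expect_null(pathToBlock(path, occs, k = 24, reference = "g1"))

    # orientation is normalized to '+' in the reference genome
    bn <- pathToBlock(path, occr, k = 24, reference = "g2")
    expect_identical(bn$strand, c("-", "+"))
})

test_that("the size filter is strict on the minimum extent", {
    mk <- function(len1, len2, id) {
        data.frame(genome = c("g1", "g2"), contig = "c1",
                   start = c(0, 0), end = c(len1, len2),
                   strand = "+", num_minimizers = 5L,
                   stringsAsFactors = FALSE)
    }
    cl <- list(g1 = c(c1 = 1e6), g2 = c(c1 = 1e6))
    bs <- syntfind:::blockSetFromList(
        list(mk(10001, 10001), mk(10000, 10000), mk(20000, 5000)),
        c("g1", "g2"), cl)
    out <- filterBySize(bs, 10000)
    b <- blockTable(out)
    expect_equal(length(unique(b$block_id)), 1)
    expect_equal(unique(b$end), 10001)
})

test_that("artificially split clean paths re-merge to the original block", {
    path <- paste0("n", sprintf("%02d", 1:10))
    pos <- stats::setNames(seq(0, 900, by = 100), path)
    occ <- occFromPositions(list(g1 = pos, g2 = pos))
    whole <- pathToBlock(path, occ, k = 24, reference = "g1")
    p1 <- path[1:5]; p2 <- path[6:10]
    b1 <- pathToBlock(p1, occ, k = 24, reference = "g1")
    b2 <- pathToBlock(p2, occ, k = 24, reference = "g1")
    cl <- list(g1 = c(c1 = 2000), g2 = c(c1 = 2000))
    bs <- syntfind:::blockSetFromList(list(b1, b2), c("g1", "g2"), cl)
    merged <- mergeCollinear(bs, mergeThreshold = 1000, k = 24)
    expect_equal(length(merged), 1)
    mb <- blockTable(merged)
    expect_equal(unique(mb$start), unique(whole$start))
    expect_equal(unique(mb$end), unique(whole$end))
    expect_equal(unique(mb$num_minimizers), 10)
})

test_that("merge respects distance, strand, and indel provenance", {
    mkBlock <- function(s1, e1, s2, e2, strand2 = "+", head = NA,
                        tail = NA) {
        b <- data.frame(genome = c("g1", "g2"), contig = "c1",
                        start = c(s1, s2), end = c(e1, e2),
                        strand = c("+", strand2), num_minimizers = 5L,
                        stringsAsFactors = FALSE)
        attr(b, "head_hash") <- head
        attr(b, "tail_hash") <- tail
        b
    }
    cl <- list(g1 = c(c1 = 1e6), g2 = c(c1 = 1e6))
    # gap of exactly threshold merges; threshold + 1 does not
    near <- syntfind:::blockSetFromList(
        list(mkBlock(0, 1000, 0, 1000), mkBlock(1500, 2500, 1500, 2500)),
        c("g1", "g2"), cl)
    expect_equal(length(mergeCollinear(near, 500, 24)), 1)
    out <- assignReasons(mergeCollinear(near, 499, 24), 499, 24)
    expect_equal(length(out), 2)
    expect_identical(blockTable(out)$reason[1:2],
                     c("merge-distance", "merge-distance"))

    # opposite strand in one genome: never merged, reason strand
    flip <- syntfind:::blockSetFromList(
        list(mkBlock(0, 1000, 0, 1000),
             mkBlock(1100, 2100, 1100, 2100, strand2 = "-")),
        c("g1", "g2"), cl)
    out2 <- assignReasons(mergeCollinear(flip, 1e6, 24), 1e6, 24)
    expect_equal(length(out2), 2)
    expect_identical(blockTable(out2)$reason[1:2], c("strand", "strand"))

    # recorded indel break between tail/head hashes blocks the merge
    ind <- syntfind:::blockSetFromList(
        list(mkBlock(0, 1000, 0, 1000, head = "h1", tail = "h2"),
             mkBlock(1100, 2100, 1100, 2100, head = "h3", tail = "h4")),
        c("g1", "g2"), cl,
        indelBreaks = syntfind:::pairKey("h2", "h3"))
    out3 <- assignReasons(mergeCollinear(ind, 1e6, 24), 1e6, 24)
    expect_equal(length(out3), 2)
    expect_identical(blockTable(out3)$reason[1:2], c("indel", "indel"))
})

test_that("a single block carries reason none", {
    b <- data.frame(genome = c("g1", "g2"), contig = "c1", start = 0,
                    end = 5000, strand = "+", num_minimizers = 9L,
                    stringsAsFactors = FALSE)
    bs <- syntfind:::blockSetFromList(list(b), c("g1", "g2"),
                                      list(g1 = c(c1 = 1e4),
                                           g2 = c(c1 = 1e4)))
    out <- assignReasons(bs)
    expect_identical(unique(blockTable(out)$reason), "none")
})
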