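# Minimizer graph construction, simplification, filtering, path extraction.

test_that("selectSharedUnique keeps exactly the everywhere-unique hashes", {
    df1 <- data.frame(contig = "c1", pos = c(0, 10, 20, 30),
                      strand = "+", hash = c("h1", "h2", "h3", "h2"),
                      stringsAsFactors = FALSE)
    df2 <- data.frame(contig = "c1", pos = c(0, 10, 20),
                      strand = "+", hash = c("h1", "h2", "h3"),
                      stringsAsFactors = FALSE)
    s1 <- makeSketch("a", df1)
    s2 <- makeSketch("b", df2)
    # h2 occurs twice in genome a -> excluded; h1/h3 shared and unique
    expect_identical(selectSharedUnique(list(s1, s2)), c("h1", "h3"))
    # identical genomes: everything qualifies
    s3 <- makeSketch("c", df2)
    expect_identical(selectSharedUnique(list(s2, s3)),
                     sort(c("h1", "h2", "h3")))
    # hash absent from one genome -> excluded
    df4 <- df2[df2$hash != "h3", ]
    expect_identical(selectSharedUnique(list(s2, makeSketch("d", df4))),
                     c("h1", "h2"))
})

test_that("identical genomes give a disjoint union of weight-n paths", {
    set.seed(61)
    g <- c(A = randomSeq(4000), B = randomSeq(3000))
    s1 <- sketchGenome(g, 24, 10, genomeId = "a")
    s2 <- sketchGenome(g, 24, 10, genomeId = "b")
    sh <- selectSharedUnique(list(s1, s2))
    mg <- buildMinimizerGraph(list(s1, s2), sh)
    gr <- minimizerGraph(mg)
    expect_true(all(igraph::E(gr)$weight == 2))
    expect_true(all(igraph::degree(gr) <= 2))
    # one path per contig
    expect_equal(igraph::components(gr)$no, 2)
})

test_that("an inverted segment produces weight-deficient breakpoint edges", {
    # g1 order: A B C D E F ; g2 inverts C..E -> A B E D C F
    occ <- occFromPositions(list(
        g1 = c(A = 100, B = 200, C = 300, D = 400, E = 500, F = 600),
        g2 = c(A = 100, B = 200, E = 300, D = 400, C = 500, F = 600)))
    e <- syntfind:::adjacencyEdges(occ, c("g1", "g2"))
    low <- e[e$weight == 1, ]
    lowPairs <- sort(paste(low$u, low$v, sep = "-"))
    # breakpoint-spanning adjacencies differ; interior inversion edges
    # (C-D, D-E) are shared because adjacency is undirected
    expect_identical(lowPairs, sort(c("B-C", "E-F", "B-E", "C-F")))
    full <- e[e$weight == 2, ]
    expect_identical(sort(paste(full$u, full$v, sep = "-")),
                     sort(c("A-B", "C-D", "D-E")))
})

test_that("isolated shared nodes stay in the graph with degree zero", {
    occ <- occFromPositions(
        list(g1 = c(X = 100), g2 = c(X = 900)),
        contigLists = list(g1 = "c1", g2 = "c9"))
    e <- syntfind:::adjacencyEdges(occ, c("g1", "g2"))
    expect_equal(nrow(e), 0)
    mg <- syntfind:::newMinimizerGraph(e, 2, nodes = "X")
    expect_equal(igraph::degree(minimizerGraph(mg))[["X"]], 0)
})

test_that("simplification removes noisy bubble middles and promotes (u,v)", {
    mg <- syntfind:::newMinimizerGraph(bubbleGraphEdges(), 2)
    out <- simplifyGraph(mg)
    gr <- minimizerGraph(out)
    expect_false("z" %in% igraph::V(gr)$name)
    uv <- igraph::get_edge_ids(gr, c("u", "v"))
    expect_equal(igraph::E(gr)$weight[uv], 2)
    # the other edges are untouched
    expect_equal(igraph::ecount(gr), 3)
    # idempotence
    out2 <- simplifyGraph(out)
    expect_true(igraph::identical_graphs(minimizerGraph(out2), gr))
})

test_that("two disjoint bubbles are both resolved in one pass", {
    e <- rbind(bubbleGraphEdges("p."), bubbleGraphEdges("q."))
    mg <- syntfind:::newMinimizerGraph(e, 2)
    out <- simplifyGraph(mg)
    nms <- igraph::V(minimizerGraph(out))$name
    expect_false(any(c("p.z", "q.z") %in% nms))
    expect_equal(igraph::ecount(minimizerGraph(out)), 6)
    expect_true(all(igraph::E(minimizerGraph(out))$weight == 2))
})

test_that("a clean weight-n path is left untouched by simplification", {
    e <- data.frame(u = c("a", "b", "c"), v = c("b", "c", "d"), weight = 2)
    mg <- syntfind:::newMinimizerGraph(e, 2)
    out <- simplifyGraph(mg)
    expect_true(igraph::identical_graphs(minimizerGraph(out),
                                         minimizerGraph(mg)))
})

test_that("weight filtering keeps exactly the weight-n edges", {
    e <- data.frame(u = c("a", "b", "c", "x"), v = c("b", "c", "x", "y"),
                    weight = c(3, 3, 1, 3))
    mg <- syntfind:::newMinimizerGraph(e, 3)
    out <- filterLowWeight(mg)
    gr <- minimizerGraph(out)
    expect_equal(igraph::ecount(gr), 3)
    expect_true(all(igraph::E(gr)$weight == 3))
    # the bridge is gone: two components now
    expect_equal(igraph::components(gr)$no, 2)
    # a fully low-weight neighbourhood drops its isolated nodes
    e2 <- data.frame(u = "a", v = "b", weight = 1)
    out2 <- filterLowWeight(syntfind:::newMinimizerGraph(e2, 2))
    expect_equal(igraph::vcount(minimizerGraph(out2)), 0)
})

test_that("extractPaths returns linear components and drops the rest", {
    path5 <- data.frame(u = c("a", "b", "c", "d"),
                        v = c("b", "c", "d", "e"), weight = 2)
    mg <- syntfind:::newMinimizerGraph(path5, 2)
    p <- extractPaths(mg)
    expect_length(p, 1)
    expect_identical(p[[1]], c("a", "b", "c", "d", "e"))

    cyc <- data.frame(u = c("a", "b", "c", "d"), v = c("b", "c", "d", "a"),
                      weight = 2)
    expect_warning(pc <- extractPaths(syntfind:::newMinimizerGraph(cyc, 2)),
                   "non-linear")
    expect_length(pc, 0)
    expect_equal(attr(pc, "excluded"), 1)

    # three paths plus one star: the star is excluded
    e <- data.frame(
        u = c("p1a", "p1b", "p2a", "p3a", "p3b", "p3c", "s0", "s0", "s0"),
        v = c("p1b", "p1c", "p2b", "p3b", "p3c", "p3d", "s1", "s2", "s3"),
        weight = 2)
    expect_warning(px <- extractPaths(syntfind:::newMinimizerGraph(e, 2)),
                   "non-linear")
    expect_length(px, 3)
    expect_identical(vapply(px, `[`, character(1), 1),
                     c("p1a", "p2a", "p3a"))
})

test_that("path extraction is deterministic and tolerant of branching", {
    # residual degree-3 node after filtering must not corrupt other paths
    e <- data.frame(u = c("a", "b", "x", "x", "x"),
                    v = c("b", "c", "y", "z", "w"), weight = 2)
    mg <- syntfind:::newMinimizerGraph(e, 2)
    expect_warning(p1 <- extractPaths(mg), "non-linear")
    expect_warning(p2 <- extractPaths(mg), "non-linear")
    expect_identical(p1, p2)
    expect_length(p1, 1)
    expect_identical(p1[[1]], c("a", "b", "c"))
})
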