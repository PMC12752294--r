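#' Select minimizer hashes shared by all genomes and unique within each
#'
#' A hash qualifies when its multiplicity is exactly 1 in every genome's
#' sketch: present everywhere, repeated nowhere.
#'
#' @param sketches list of [GenomeSketch-class] (two or more).
#' @return character vector of qualifying hashes (possibly empty), sorted.
#' @export
selectSharedUnique <- function(sketches) {
    stopifnot(length(sketches) >= 2,
              all(vapply(sketches, is, logical(1), "GenomeSketch")))
    per <- lapply(sketches, function(s) {
        m <- multiplicity(s)
        names(m)[m == 1L]
    })
    sort(Reduce(intersect, per))
}

# Occurrence table for retained hashes: one row per (genome, hash) with its
# single occurrence. Keyed by genome, hash.
occurrenceTable <- function(sketches, shared) {
    dts <- lapply(sketches, function(s) {
        m <- data.table::as.data.table(minimizers(s))
        m <- m[hash %in% shared]
        m[, genome := genomeIds(s)]
        m
    })
    occ <- data.table::rbindlist(dts)
    data.table::setkey(occ, genome, hash)
    occ
}

# Adjacency edge list: for each genome, consecutive retained minimizers in
# (contig, pos) order contribute an undirected edge.
adjacencyEdges <- function(occ, genomes) {
    es <- lapply(genomes, function(g) {
        m <- occ[J(g)]
        data.table::setorder(m, contig, pos)
        if (nrow(m) < 2) return(NULL)
        keep <- m$contig[-nrow(m)] == m$contig[-1]
        if (!any(keep)) return(NULL)
        a <- m$hash[-nrow(m)][keep]
        b <- m$hash[-1][keep]
        data.table::data.table(u = pmin(a, b), v = pmax(a, b), genome = g)
    })
    es <- es[!vapply(es, is.null, logical(1))]
    if (!length(es))
        return(data.table::data.table(u = character(), v = character(),
                                      weight = integer(),
                                      genomes = character()))
    e <- data.table::rbindlist(es)
    e[, .(weight = data.table::uniqueN(genome),
          genomes = paste(sort(unique(genome)), collapse = ",")),
      by = .(u, v)]
}

#' Build the undirected minimizer graph
#'
#' Nodes are the shared-unique minimizer hashes; for every genome, each pair
#' of consecutive retained minimizers on the same contig contributes an edge,
#' weighted by the number of genomes supporting the adjacency. A pair
#' adjacent in several genomes (in either orientation) is a single undirected
#' edge.
#'
#' @param sketches list of [GenomeSketch-class].
#' @param shared hashes from [selectSharedUnique()] computed on the same
#'   sketches.
#' @return a [MinimizerGraph-class]
#' @export
buildMinimizerGraph <- function(sketches, shared) {
    stopifnot(length(sketches) >= 2)
    gids <- vapply(sketches, genomeIds, character(1))
    occ <- occurrenceTable(sketches, shared)
    e <- adjacencyEdges(occ, gids)
    g <- igraph::graph_from_data_frame(
        as.data.frame(e), directed = FALSE,
        vertices = data.frame(name = shared, stringsAsFactors = FALSE))
    new("MinimizerGraph", graph = g, nGenomes = length(sketches),
        genomeIds = gids)
}

# Internal constructor used by tests and the refinement rounds: build a
# MinimizerGraph directly from an edge table (u, v, weight[, genomes]).
newMinimizerGraph <- function(edges, n, nodes = NULL,
                              genomeIds = paste0("g", seq_len(n))) {
    edges <- as.data.frame(edges)
    if (is.null(edges$genomes)) edges$genomes <- ""
    if (is.null(nodes)) nodes <- sort(unique(c(edges$u, edges$v)))
    g <- igraph::graph_from_data_frame(
        edges, directed = FALSE,
        vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
    new("MinimizerGraph", graph = g, nGenomes = as.integer(n),
        genomeIds = genomeIds)
}

# Node classification. Fully anchored: degree 2 with incident weight sum 2n.
# Partially anchored: degree 3 with at least one incident weight-n edge.
nodeClasses <- function(g, n) {
    deg <- igraph::degree(g)
    stren <- igraph::strength(g, weights = igraph::E(g)$weight)
    maxw <- rep(0, igraph::vcount(g))
    if (igraph::ecount(g) > 0) {
        ends <- igraph::ends(g, igraph::E(g), names = FALSE)
        w <- igraph::E(g)$weight
        for (side in 1:2) {
            agg <- tapply(w, ends[, side], max)
            idx <- as.integer(names(agg))
            maxw[idx] <- pmax(maxw[idx], agg)
        }
    }
    cls <- rep("unanchored", igraph::vcount(g))
    cls[deg == 2 & stren == 2 * n] <- "full"
    cls[deg == 3 & maxw == n] <- "partial"
    stats::setNames(cls, igraph::V(g)$name)
}

#' Simplify the minimizer graph by removing noisy alternate-path nodes
#'
#' Classifies nodes as fully anchored (degree 2, incident weight sum `2n`),
#' partially anchored (degree 3 with an incident weight-`n` edge) or
#' unanchored. For each edge `(u, v)` whose endpoints are both partially
#' anchored, any alternate length-two path `(u, z, v)` marks `z` as noisy:
#' `z` is removed and the weight of `(u, v)` is promoted to `n`. Edges are
#' examined in ascending `(min(hash), max(hash))` order and removals take
#' effect immediately, so the procedure is deterministic.
#'
#' @param mgraph a [MinimizerGraph-class] with computed weights.
#' @param iterate repeat the scan until no further node is removed
#'   (default `FALSE`: a single pass, which is idempotent on the fixtures
#'   the rule targets).
#' @return the simplified [MinimizerGraph-class]
#' @export
simplifyGraph <- function(mgraph, iterate = FALSE) {
    stopifnot(is(mgraph, "MinimizerGraph"))
    g <- mgraph@graph
    n <- mgraph@nGenomes
    repeat {
        removedAny <- FALSE
        cls <- nodeClasses(g, n)
        partial <- names(cls)[cls == "partial"]
        if (length(partial) >= 2 && igraph::ecount(g) > 0) {
            ends <- igraph::ends(g, igraph::E(g))
            cand <- which(ends[, 1] %in% partial & ends[, 2] %in% partial)
            if (length(cand)) {
                cu <- pmin(ends[cand, 1], ends[cand, 2])
                cv <- pmax(ends[cand, 1], ends[cand, 2])
                ord <- order(cu, cv)
                pairs <- cbind(cu, cv)[ord, , drop = FALSE]
                for (i in seq_len(nrow(pairs))) {
                    u <- pairs[i, 1]; v <- pairs[i, 2]
                    # re-verify against the current graph
                    if (!all(c(u, v) %in% igraph::V(g)$name)) next
                    if (!igraph::are_adjacent(g, u, v)) next
                    cls <- nodeClasses(g, n)
                    if (cls[[u]] != "partial" || cls[[v]] != "partial") next
                    nu <- igraph::neighbors(g, u)$name
                    nv <- igraph::neighbors(g, v)$name
                    z <- setdiff(intersect(nu, nv), c(u, v))
                    if (!length(z)) next
                    g <- igraph::delete_vertices(g, z)
                    eid <- igraph::get_edge_ids(g, c(u, v))
                    igraph::E(g)$weight[eid] <- n
                    removedAny <- TRUE
                }
            }
        }
        if (!iterate || !removedAny) break
    }
    methods::initialize(mgraph, graph = g)
}

#' Drop edges not supported by every genome
#'
#' Removes every edge whose weight is below `n` (the number of genomes), then
#' drops isolated nodes. Applied after [simplifyGraph()].
#'
#' @param mgraph a [MinimizerGraph-class]
#' @return the filtered [MinimizerGraph-class]
#' @export
filterLowWeight <- function(mgraph) {
    stopifnot(is(mgraph, "MinimizerGraph"))
    g <- mgraph@graph
    drop <- which(igraph::E(g)$weight < mgraph@nGenomes)
    if (length(drop)) g <- igraph::delete_edges(g, drop)
    iso <- which(igraph::degree(g) == 0)
    if (length(iso)) g <- igraph::delete_vertices(g, iso)
    methods::initialize(mgraph, graph = g)
}

#' Extract linear paths from the filtered minimizer graph
#'
#' Every connected component that is a simple path (all degrees at most 2
#' and acyclic) is returned as an ordered vector of node hashes, traversed
#' from its smaller terminal hash. Components containing a branch (degree 3
#' or more) or a cycle are excluded and counted in the `excluded` attribute;
#' a warning reports how many were dropped. Single-node components are
#' ignored (a path needs at least two minimizers).
#'
#' @param mgraph a [MinimizerGraph-class], normally after
#'   [filterLowWeight()].
#' @return list of character vectors (ordered node hashes), sorted by first
#'   node hash, with attribute `excluded` (number of non-path components).
#' @export
extractPaths <- function(mgraph) {
    stopifnot(is(mgraph, "MinimizerGraph"))
    g <- mgraph@graph
    comp <- igraph::components(g)
    paths <- list()
    excluded <- 0L
    deg <- igraph::degree(g)
    membership <- comp$membership
    for (ci in seq_len(comp$no)) {
        vs <- which(membership == ci)
        if (length(vs) < 2) next
        dsub <- deg[vs]
        nEdges <- sum(dsub) / 2
        if (max(dsub) > 2 || nEdges != length(vs) - 1) {
            excluded <- excluded + 1L
            next
        }
        terms <- vs[dsub == 1]
        nm <- igraph::V(g)$name[terms]
        root <- terms[order(nm)[1]]
        ord <- igraph::dfs(g, root = root, unreachable = FALSE)$order
        ord <- ord[!is.na(ord)]
        paths[[length(paths) + 1L]] <- igraph::V(g)$name[ord][
            seq_along(vs)]
    }
    if (length(paths)) {
        firsts <- vapply(paths, `[`, character(1), 1)
        paths <- paths[order(firsts)]
    }
    if (excluded > 0)
        warning(excluded, " non-linear component(s) excluded from paths")
    attr(paths, "excluded") <- excluded
    paths
}
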