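test_that("transformation yields singleton vertices with unit weights", {
    fx <- fig3Fixture()
    g <- transformNetwork(fx$network)
    expect_length(vertexLabels(g), 10L)
    expect_true(all(lengths(vertexLabels(g)) == 1L))
    w <- g@weights
    expect_setequal(unique(as.vector(w)), c(0, 1))
    expect_equal(sum(w > 0) / 2, 22)

    ab <- ProteinNetwork(data.frame(from = "a", to = "b"))
    g2 <- transformNetwork(ab)
    expect_equal(edgeWeight(g2, "a", "b"), 1)

    iso <- ProteinNetwork(NULL, nodes = c("a", "b"))
    g3 <- transformNetwork(iso)
    expect_length(vertexLabels(g3), 2L)
    expect_true(all(g3@weights == 0))
})

test_that("merging updates weights by summation (worked example)", {
    fx <- fig3Fixture()
    g <- transformNetwork(fx$network)
    m <- mergeVertices(g, "p1", "p2")
    m <- mergeVertices(m$graph, m$vertex, "p4")
    expect_identical(m$vertex, "p1,p2,p4")
    # all of p1,p2,p4 interact with p3; only p4 with p5
    expect_equal(edgeWeight(m$graph, "p1,p2,p4", "p3"), 3)
    expect_equal(edgeWeight(m$graph, "p1,p2,p4", "p5"), 1)

    # the two triangles of the K6 are fully interconnected: weight 9
    g2 <- m$graph
    r <- mergeVertices(g2, "p5", "p6")
    r <- mergeVertices(r$graph, r$vertex, "p7")
    triA <- r$vertex
    g2 <- r$graph
    r <- mergeVertices(g2, "p8", "p9")
    r <- mergeVertices(r$graph, r$vertex, "p10")
    triB <- r$vertex
    g2 <- r$graph
    expect_equal(edgeWeight(g2, triA, triB), 9)
    r <- mergeVertices(g2, triA, triB)
    expect_length(vertexLabels(r$graph)[[r$vertex]], 6L)
})

test_that("merges below full interconnection are refused, graph unchanged", {
    fx <- fig3Fixture()
    g <- transformNetwork(fx$network)
    m <- mergeVertices(g, "p1", "p2")
    m <- mergeVertices(m$graph, m$vertex, "p4")
    # weight 1 < 3*1: p5 is not connected to all of p1,p2,p4
    expect_error(mergeVertices(m$graph, "p1,p2,p4", "p5"), "refused")
    expect_error(mergeVertices(g, "p1", "p6"), "no edge")
    expect_error(mergeVertices(g, "p1", "zz"), "unknown vertex")
})

test_that("weights always equal recounted PPIN relations; labels conserved", {
    for (rep in 1:5) {
        withr::local_seed(100 + rep)
        pn <- randomNetwork(10, 0.5)
        g <- transformNetwork(pn)
        # random sequence of valid merges
        for (step in 1:6) {
            ids <- names(vertexLabels(g))
            ok <- NULL
            for (u in sample(ids)) {
                labs <- vertexLabels(g)
                cand <- ids[g@weights[u, ids] ==
                            length(labs[[u]]) * lengths(labs[ids])]
                cand <- setdiff(cand, u)
                if (length(cand)) {
                    ok <- c(u, sample(cand, 1L))
                    break
                }
            }
            if (is.null(ok)) break
            g <- mergeVertices(g, ok[1L], ok[2L])$graph
        }
        # label conservation
        expect_setequal(unlist(vertexLabels(g)), networkNodes(pn))
        expect_false(anyDuplicated(unlist(vertexLabels(g))) > 0)
        # weight correctness by recount, and multi-label vertices are cliques
        ids <- names(vertexLabels(g))
        for (u in ids) {
            if (length(vertexLabels(g)[[u]]) >= 2L)
                expect_true(isClique(vertexLabels(g)[[u]], pn))
            for (v in ids[ids > u]) {
                expect_equal(unname(g@weights[u, v]),
                             recountWeight(g, u, v, pn))
            }
        }
        expect_true(validObject(g))
    }
})

test_that("minimal-clique search respects seeds and availability", {
    fx <- fig3Fixture()
    g <- transformNetwork(fx$network)
    r <- findMinimalClique(g, "p4")
    expect_false(is.null(r$vertex))
    tri <- vertexLabels(r$graph)[[r$vertex]]
    expect_length(tri, 3L)
    expect_true("p4" %in% tri)
    expect_true(isClique(tri, fx$network))

    # path graph has no triangle: seed dropped, graph unchanged
    path <- ProteinNetwork(data.frame(from = c("a", "b"), to = c("b", "c")))
    gp <- transformNetwork(path)
    r2 <- findMinimalClique(gp, "b")
    expect_null(r2$vertex)
    expect_identical(vertexLabels(r2$graph), vertexLabels(gp))
    expect_error(findMinimalClique(gp, "zz"), "not in graph")
})

test_that("every 3-subset containing the seed is reachable in K4", {
    k4 <- completeNetwork(4)
    seen <- character(0)
    withr::local_seed(5)
    for (i in 1:200) {
        g <- transformNetwork(k4)
        r <- findMinimalClique(g, "k1")
        seen <- union(seen, cliqueKey(vertexLabels(r$graph)[[r$vertex]]))
    }
    # all 3 triangles containing k1, and only those
    expected <- vapply(list(c("k1", "k2", "k3"), c("k1", "k2", "k4"),
                            c("k1", "k3", "k4")), cliqueKey, "")
    expect_setequal(seen, expected)
})

test_that("extension grows a triangle to the unique maximal clique of K5", {
    k5 <- completeNetwork(5)
    withr::local_seed(8)
    for (i in 1:5) {
        g <- transformNetwork(k5)
        r <- findMinimalClique(g, "k1")
        ext <- extendCliques(r$graph, r$vertex)
        expect_length(ext$cliques, 1L)
        expect_setequal(ext$cliques[[1L]], paste0("k", 1:5))
    }
    # a clique vertex with no fully connected neighbor is returned unchanged
    fx <- fig3Fixture()
    g <- transformNetwork(fx$network)
    m <- mergeVertices(g, "p1", "p2")
    m <- mergeVertices(m$graph, m$vertex, "p3")
    m <- mergeVertices(m$graph, m$vertex, "p4")  # full K4; only nbr is p5, w=1
    ext <- extendCliques(m$graph, m$vertex)
    expect_identical(ext$cliques, list(paste0("p", 1:4)))
})
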