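# Helper: a test result table marking the given cliques significant.
fakeResults <- function(sig, insig = list()) {
    cl <- c(sig, insig)
    data.frame(clique = vapply(cl, cliqueKey, ""),
               size = lengths(cl),
               n_bg = lengths(cl), n_deg = 1L,
               eligible = TRUE,
               fisher_p = 0.001,
               perm_p = c(rep(0, length(sig)), rep(0.5, length(insig))),
               significant = rep(c(TRUE, FALSE),
                                 c(length(sig), length(insig))),
               stringsAsFactors = FALSE)
}

test_that("module assembly takes the union of significant cliques", {
    nodes <- letters[1:6]
    e <- cliqueModules:::.pairsWithin(nodes)
    e$score <- 0.95
    pn <- ProteinNetwork(e, nodes = nodes, cutoff = 0.7)
    gs <- makeGeneSets(deg = "a", background = c("a", "b", "c", "d"))

    res <- fakeResults(list(c("a", "b", "c"), c("b", "c", "d")),
                       insig = list(c("d", "e", "f")))
    mod <- assembleModule(res, pn, gs, alpha = 0.01)
    expect_setequal(moduleNodes(mod), c("a", "b", "c", "d"))
    expect_setequal(cliqueModules:::.edgeKeys(moduleEdges(mod)),
                    cliqueModules:::.edgeKeys(
                        data.frame(from = c("a", "a", "b", "b", "c"),
                                   to = c("b", "c", "c", "d", "d"))))
    ann <- moduleAnnotations(mod)
    expect_identical(ann$is_deg_associated, ann$protein == "a")
    expect_identical(ann$is_background_associated, rep(TRUE, 4L))

    # induced assembly adds the PPIN edge a-d missing from the cliques
    modI <- assembleModule(res, pn, gs, alpha = 0.01, induced = TRUE)
    expect_equal(nrow(moduleEdges(modI)), 6L)

    # a single K3 clique: 3 nodes, 3 edges, one component
    mod3 <- assembleModule(fakeResults(list(c("a", "b", "c"))), pn, gs)
    expect_length(moduleNodes(mod3), 3L)
    expect_equal(nrow(moduleEdges(mod3)), 3L)
    expect_length(unique(connectedComponents(mod3)), 1L)

    # no significant cliques: empty module with a warning
    expect_warning(
        modE <- assembleModule(fakeResults(list(), list(c("a", "b", "c"))),
                               pn, gs),
        "empty")
    expect_length(moduleNodes(modE), 0L)
})

test_that("module grows monotonically with alpha", {
    withr::local_seed(17)
    sim <- generatePlanted(plantedDesign(nBackground = 50), seed = 3)
    cc <- enumerateCliques(sim$network, 300, seed = 3)
    samples <- sampleBackgrounds(sim$genes, 300, seed = 3)
    res <- testCliques(cc, sim$genes, samples)
    for (pair in list(c(0.001, 0.01), c(0.01, 0.2), c(0.2, 1))) {
        m1 <- suppressWarnings(assembleModule(res, sim$network, sim$genes,
                                              alpha = pair[1L]))
        m2 <- suppressWarnings(assembleModule(res, sim$network, sim$genes,
                                              alpha = pair[2L]))
        expect_true(all(moduleNodes(m1) %in% moduleNodes(m2)))
        expect_true(all(cliqueModules:::.edgeKeys(moduleEdges(m1)) %in%
                        cliqueModules:::.edgeKeys(moduleEdges(m2))))
    }
})

test_that("module-level enrichment p behaves at the extremes", {
    pn <- completeNetwork(4)
    nodes <- networkNodes(pn)
    # every module protein DEG-associated, |D| << |N|
    bigBg <- c(nodes, sprintf("x%02d", 1:60))
    gs <- makeGeneSets(deg = nodes, background = bigBg)
    mod <- assembleModule(fakeResults(list(nodes[1:3], nodes[2:4])), pn, gs)
    samples <- sampleBackgrounds(gs, 300, seed = 2)
    expect_equal(suppressMessages(moduleEnrichmentP(mod, gs, samples)), 0)
    # deg == background: observed statistic cannot be exceeded or missed
    gsAll <- makeGeneSets(deg = bigBg, background = bigBg)
    samplesAll <- sampleBackgrounds(gsAll, 50, seed = 2)
    expect_equal(moduleEnrichmentP(mod, gsAll, samplesAll), 1)
    expect_error(moduleEnrichmentP(
        cliqueModules:::.newModule(character(0), NULL,
                                   moduleAnnotations(mod)[0, ]),
        gs, samples), "empty")
})

test_that("edge-betweenness sub-modules split a barbell and respect cliques", {
    # two triangles joined by a bridge
    e <- rbind(cliqueModules:::.pairsWithin(c("a", "b", "c")),
               cliqueModules:::.pairsWithin(c("x", "y", "z")),
               data.frame(from = "c", to = "x"))
    pn <- ProteinNetwork(e)
    gs <- makeGeneSets("a", c("a", "b", "c", "x", "y", "z"))
    mod <- cliqueModules:::.newModule(
        networkNodes(pn), networkEdges(pn)[c("from", "to")],
        data.frame(protein = networkNodes(pn),
                   is_deg_associated = FALSE,
                   is_background_associated = TRUE,
                   stringsAsFactors = FALSE))
    mod <- detectSubmodules(mod)
    sub <- submodules(mod)
    expect_length(unique(sub), 2L)
    expect_length(unique(sub[c("a", "b", "c")]), 1L)
    expect_length(unique(sub[c("x", "y", "z")]), 1L)

    # a single clique stays one sub-module
    k5 <- completeNetwork(5)
    modK <- cliqueModules:::.newModule(
        networkNodes(k5), networkEdges(k5)[c("from", "to")],
        data.frame(protein = networkNodes(k5),
                   is_deg_associated = FALSE,
                   is_background_associated = TRUE,
                   stringsAsFactors = FALSE))
    expect_length(unique(submodules(detectSubmodules(modK))), 1L)

    # sub-modules refine connected components
    comp <- connectedComponents(mod)
    tab <- table(submodules(mod), comp[names(submodules(mod))])
    expect_true(all(rowSums(tab > 0) == 1L))
})

test_that("planted two-community graphs are recovered by sub-module detection", {
    skip_if_not_installed("mclust")
    withr::local_seed(29)
    groups <- rep(1:2, each = 10)
    nodes <- sprintf("v%02d", 1:20)
    pairs <- cliqueModules:::.pairsWithin(nodes)
    gi <- groups[match(pairs$from, nodes)]
    gj <- groups[match(pairs$to, nodes)]
    p <- ifelse(gi == gj, 0.9, 0.05)
    e <- pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
    pn <- ProteinNetwork(e, nodes = nodes)
    mod <- cliqueModules:::.newModule(
        nodes, networkEdges(pn)[c("from", "to")],
        data.frame(protein = nodes, is_deg_associated = FALSE,
                   is_background_associated = TRUE,
                   stringsAsFactors = FALSE))
    sub <- submodules(detectSubmodules(mod))
    ari <- mclust::adjustedRandIndex(sub[nodes], groups)
    expect_gte(ari, 0.9)
})

test_that("connected components count disjoint cliques and ignore order", {
    e <- rbind(cliqueModules:::.pairsWithin(c("a", "b", "c")),
               cliqueModules:::.pairsWithin(c("x", "y", "z")))
    ann <- data.frame(protein = c("a", "b", "c", "x", "y", "z"),
                      is_deg_associated = FALSE,
                      is_background_associated = TRUE,
                      stringsAsFactors = FALSE)
    mod <- cliqueModules:::.newModule(ann$protein, e, ann)
    comp <- connectedComponents(mod)
    expect_length(unique(comp), 2L)
    modR <- cliqueModules:::.newModule(rev(ann$protein),
                                       e[sample(nrow(e)), ], ann)
    compR <- connectedComponents(modR)
    expect_length(unique(compR), 2L)
    # same partition regardless of node/edge ordering
    expect_true(comp[["a"]] != comp[["x"]])
    expect_true(compR[["a"]] != compR[["x"]])
    expect_equal(comp[["a"]], comp[["b"]])
    expect_equal(compR[["a"]], compR[["b"]])
    empty <- cliqueModules:::.newModule(character(0), NULL, ann[0, ])
    expect_length(connectedComponents(empty), 0L)
})
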