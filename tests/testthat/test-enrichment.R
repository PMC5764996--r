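test_that("background samples have the right size and uniform coverage", {
    gs <- makeGeneSets(deg = c("g1", "g2", "g3"),
                       background = paste0("g", 1:10))
    bs <- sampleBackgrounds(gs, nSamples = 5, seed = 1)
    expect_length(bs@sets, 5L)
    for (s in bs@sets) {
        expect_length(s, 3L)
        expect_false(anyDuplicated(s) > 0)
        expect_true(all(s %in% backgroundGenes(gs)))
    }
    # degenerate: deg == background -> every sample is the background
    gs2 <- makeGeneSets(paste0("g", 1:4), paste0("g", 1:4))
    bs2 <- sampleBackgrounds(gs2, nSamples = 3, seed = 1)
    for (s in bs2@sets) expect_setequal(s, paste0("g", 1:4))
    expect_error(sampleBackgrounds(
        GeneSets(character(0), "g1"), 10), "empty")

    # per-gene inclusion frequency ~ |D|/|N| within binomial error
    gs3 <- makeGeneSets(paste0("g", 1:3), paste0("g", 1:10))
    bs3 <- sampleBackgrounds(gs3, nSamples = 4000, seed = 7)
    freq <- table(factor(unlist(bs3@sets),
                         levels = backgroundGenes(gs3))) / 4000
    p <- 3 / 10
    tol <- 4 * sqrt(p * (1 - p) / 4000)
    expect_true(all(abs(freq - p) < tol))
})

test_that("clique eligibility applies both protein-level rules", {
    # 4 proteins: 1 DEG-associated, 2 background-associated -> eligible
    gs <- makeGeneSets(deg = "p1", background = c("p1", "p2"))
    el <- cliqueEligibility(c("p1", "p2", "p3", "p4"), gs)
    expect_true(el$eligible)
    expect_equal(el$nDegAssoc, 1L)
    expect_equal(el$nBackgroundAssoc, 2L)
    # 1 background-associated of 4 -> fails the half rule
    gs2 <- makeGeneSets(deg = "p1", background = "p1")
    expect_false(cliqueEligibility(c("p1", "p2", "p3", "p4"), gs2)$eligible)
    # no DEG association -> ineligible
    gs3 <- makeGeneSets(deg = "x", background = c("x", "p1", "p2", "p3"))
    expect_false(cliqueEligibility(c("p1", "p2", "p3"), gs3)$eligible)
})

test_that("the one-sided Fisher p equals the hypergeometric tail", {
    # clique mapping to 5 background genes, 3 in a gene set of 20, |N|=100
    bg <- sprintf("g%03d", 1:100)
    gs <- makeGeneSets(deg = bg[1:20], background = bg)
    clique <- c(bg[1:3], bg[90:91])  # identity mapping: proteins = genes
    geneset <- bg[1:20]
    # closed-form oracle: sum_{k>=3} C(20,k) C(80,5-k) / C(100,5)
    oracle <- sum(vapply(3:5, function(k)
        choose(20, k) * choose(80, 5 - k), 1)) / choose(100, 5)
    expect_equal(fisherP(clique, geneset, gs), oracle, tolerance = 1e-12)
    # and matches stats::fisher.test one-sided
    ft <- stats::fisher.test(matrix(c(3, 2, 17, 78), 2), alternative = "greater")
    expect_equal(fisherP(clique, geneset, gs), ft$p.value, tolerance = 1e-9)

    # zero overlap -> upper tail at 0 is 1
    expect_equal(fisherP(clique, bg[50:69], gs), 1)
    # degenerate: clique genes cover the whole background
    gsAll <- makeGeneSets(deg = bg[1:5], background = bg[1:5])
    expect_equal(fisherP(bg[1:5], bg[1:5], gsAll), 1)
})

test_that("fisherP depends only on the table counts, not gene labels", {
    bg <- sprintf("g%03d", 1:60)
    gs <- makeGeneSets(deg = bg[1:10], background = bg)
    # relabel: same counts (6 clique genes, 4 overlapping a 10-set)
    p2 <- fisherP(c(bg[7:10], bg[30:31]), bg[1:10], gs)
    expect_equal(p2, fisherP(bg[c(1:4, 30:31)], bg[1:10], gs))
})

test_that("the permutation p-value implements the literal counting rule", {
    bg <- sprintf("g%02d", 1:12)
    gs <- makeGeneSets(deg = bg[1:4], background = bg)
    samples <- sampleBackgrounds(gs, nSamples = 500, seed = 3)
    # clique with zero DEG overlap: p_D = 1, so every sample counts
    expect_equal(permutationP(bg[9:11], gs, samples), 1)
    # fully DEG-covered clique of size 4: only k=4 samples tie;
    # exact probability is 1 / C(12,4) ~ 0.002, so p* is 0 or tiny
    pstar <- permutationP(bg[1:4], gs, samples)
    expect_lte(pstar, 2 / 500)
    # smoothing shifts by the add-one rule
    expect_equal(permutationP(bg[1:4], gs, samples, smooth = TRUE),
                 (pstar * 500 + 1) / 501)
    expect_error(permutationP(bg[1:3], gs,
                              new("BackgroundSamples", sets = list(),
                                  seed = NA_integer_)), "no background")
})

test_that("permutation p matches the exhaustive subset probability", {
    # small universe: enumerate all |D|-subsets exactly
    bg <- sprintf("g%02d", 1:10)
    gs <- makeGeneSets(deg = bg[1:3], background = bg)
    clique <- bg[c(1, 2, 5, 6)]
    pD <- fisherP(clique, degGenes(gs), gs)
    subsets <- utils::combn(bg, 3, simplify = FALSE)
    exact <- mean(vapply(subsets, function(b)
        fisherP(clique, b, gs) <= pD, logical(1)))
    samples <- sampleBackgrounds(gs, nSamples = 4000, seed = 11)
    mc <- permutationP(clique, gs, samples)
    se <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(mc - exact), 3 * se + 1e-12)
})

test_that("testCliques ranks by enrichment and ignores multiplicity", {
    withr::local_seed(13)
    bg <- sprintf("g%02d", 1:40)
    gs <- makeGeneSets(deg = bg[1:8], background = bg)
    samples <- sampleBackgrounds(gs, nSamples = 400, seed = 5)
    cliques <- list(bg[1:5], bg[c(1:3, 20, 21)], bg[c(1, 22:25)],
                    bg[c(2, 30:33)])
    cc <- new("CliqueCollection",
              cliques = rep(cliques, c(3L, 1L, 1L, 1L)),
              iteration = c(1L, 2L, 3L, 1L, 2L, 3L),
              nIterations = 3L, nSeeds = 2L)
    res <- testCliques(cc, gs, samples, alpha = 0.05)
    expect_equal(nrow(res), 4L)  # unique cliques only
    expect_true(all(res$eligible))
    # permutation p is monotone in the fisher p up to Monte-Carlo error
    # (3 binomial standard errors at |B| = 400)
    mcTol <- 3 * sqrt(0.25 / 400)
    expect_true(all(diff(res$perm_p[order(res$fisher_p)]) >= -mcTol))
    # multiplicity does not change p-values
    cc1 <- new("CliqueCollection", cliques = cliques,
               iteration = rep(1L, 4L), nIterations = 1L, nSeeds = 4L)
    res1 <- testCliques(cc1, gs, samples, alpha = 0.05)
    expect_equal(res$perm_p, res1$perm_p[match(res$clique, res1$clique)])

    # ineligible cliques carry NA p-values and cannot be significant
    gsNone <- makeGeneSets(deg = bg[1], background = bg)
    resN <- testCliques(list(bg[30:34]), gsNone, samples, alpha = 1)
    expect_false(any(resN$eligible))
    expect_true(all(is.na(resN$perm_p)))
    expect_false(any(resN$significant))

    # alpha = 1 makes every eligible clique with perm_p < 1 significant
    resA <- testCliques(cliques, gs, samples, alpha = 1)
    expect_identical(resA$significant, resA$eligible & resA$perm_p < 1)

    # TSV round-trip
    f <- withr::local_tempfile()
    writeCliqueTests(res, f)
    back <- readCliqueTests(f)
    expect_equal(back$perm_p, res$perm_p)
    expect_equal(back$clique, res$clique)
})
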