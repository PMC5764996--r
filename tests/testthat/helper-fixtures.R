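# Shared test fixtures, built in code.

# Erdos-Renyi style random ProteinNetwork on n nodes with edge prob p.
randomNetwork <- function(n, p, score = 0.95) {
    nodes <- sprintf("n%02d", seq_len(n))
    pairs <- cliqueModules:::.pairsWithin(nodes)
    keep <- stats::runif(nrow(pairs)) < p
    e <- pairs[keep, , drop = FALSE]
    e$score <- score
    ProteinNetwork(e, nodes = nodes, cutoff = 0.7)
}

# A complete network K_n.
completeNetwork <- function(n, prefix = "k") {
    nodes <- paste0(prefix, seq_len(n))
    e <- cliqueModules:::.pairsWithin(nodes)
    e$score <- 0.95
    ProteinNetwork(e, nodes = nodes, cutoff = 0.7)
}

# Quick GeneSets over identity-mapped gene IDs.
makeGeneSets <- function(deg, background) {
    suppressWarnings(GeneSets(deg = deg, background = background))
}

cliqueKey <- cliqueModules:::.cliqueKey

# Is `proteins` a clique of the network?
isClique <- function(proteins, ppin) {
    pairs <- cliqueModules:::.pairsWithin(proteins)
    all(cliqueModules:::.edgeKeys(pairs) %in%
        cliqueModules:::.edgeKeys(networkEdges(ppin)))
}

# Is `proteins` a *maximal* clique of the network?
isMaximalClique <- function(proteins, ppin) {
    if (!isClique(proteins, ppin)) return(FALSE)
    adj <- cliqueModules:::.ppinAdjacency(ppin)
    outside <- setdiff(networkNodes(ppin), proteins)
    !any(vapply(outside, function(w) all(adj[w, proteins]), logical(1)))
}

# Recount PPIN relations between the label sets of two vertices of a
# LabeledGraph -- the independent check for stored edge weights.
recountWeight <- function(g, u, v, ppin) {
    lu <- vertexLabels(g)[[u]]
    lv <- vertexLabels(g)[[v]]
    keys <- cliqueModules:::.edgeKeys(networkEdges(ppin))
    sum(vapply(lu, function(a) sum(
        cliqueModules:::.edgeKeys(cliqueModules:::.canonPairs(
            rep(a, length(lv)), lv)) %in% keys), 1))
}
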