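# Step I driver: randomized clique enumeration.
#
# The per-iteration engine works on an immutable logical adjacency matrix
# with a membership overlay (consumed flags + integer member vectors)
# instead of materially rebuilding the labeled graph each iteration. The
# observable behavior is that of a fresh transform: a merge is accepted
# exactly when the two label sets are fully interconnected, which on the
# adjacency matrix is the condition that every cross pair is TRUE --
# equivalent to the labeled-graph rule weight == |label(u)|*|label(v)|.

# One enumeration attempt. `adj` is the n x n logical adjacency, `seeds`
# integer seed indices (processed sequentially). Returns a list of
# integer member vectors, each a clique of size >= 3; pairwise disjoint.
.iterateOnce <- function(adj, seeds) {
    consumed <- logical(nrow(adj))
    cliques <- list()
    # phase 2: minimal cliques of size three from each surviving seed
    for (s in seeds) {
        if (consumed[s]) next                     # seed dropped
        nb <- which(adj[s, ] & !consumed)
        if (length(nb) < 2L) next
        nb <- nb[sample.int(length(nb))]
        tri <- NULL
        for (i in seq_len(length(nb) - 1L)) {
            rest <- nb[(i + 1L):length(nb)]
            hit <- rest[adj[nb[i], rest]]
            if (length(hit)) {
                tri <- c(s, nb[i], hit[1L])
                break
            }
        }
        if (is.null(tri)) next                    # seed dropped
        consumed[tri] <- TRUE
        cliques[[length(cliques) + 1L]] <- tri
    }
    if (!length(cliques)) return(list())
    # phase 3: random round-robin extension until a full quiet pass
    alive <- rep(TRUE, length(cliques))
    repeat {
        merged <- FALSE
        for (ci in sample.int(length(cliques))) {
            if (!alive[ci]) next
            mem <- cliques[[ci]]
            avail <- which(!consumed)
            singles <- if (length(avail)) {
                avail[colSums(adj[mem, avail, drop = FALSE]) == length(mem)]
            } else integer(0)
            others <- which(alive)
            others <- others[others != ci]
            fuse <- others[vapply(others, function(d)
                all(adj[mem, cliques[[d]]]), logical(1))]
            ncand <- length(singles) + length(fuse)
            if (!ncand) next
            k <- sample.int(ncand, 1L)
            if (k <= length(singles)) {
                p <- singles[k]
                cliques[[ci]] <- c(mem, p)
                consumed[p] <- TRUE
            } else {
                d <- fuse[k - length(singles)]
                cliques[[ci]] <- c(mem, cliques[[d]])
                alive[d] <- FALSE
            }
            merged <- TRUE
        }
        if (!merged) break
    }
    cliques[alive]
}

#' Run one enumeration iteration (phases 1-3) on a PPIN
#'
#' Draws `nSeeds` distinct seed proteins uniformly without replacement
#' (unless `seedProteins` designates them), identifies a minimal clique
#' (triangle) for each surviving seed, and extends all minimal cliques in
#' random round-robin order until none can be enlarged. Seeds compete for
#' proteins: a protein consumed by a clique never joins another, though
#' two cliques that are fully interconnected fuse.
#'
#' @param ppin a [ProteinNetwork-class].
#' @param nSeeds number of seed proteins (single-seed strategy: 1).
#' @param seedProteins optional character vector of designated seeds
#'   (overrides the random draw; `nSeeds` is then ignored).
#' @param seed optional RNG seed for reproducibility.
#' @return list of cliques (sorted character vectors of protein IDs),
#'   each of size >= 3 and pairwise protein-disjoint; possibly empty.
#' @examples
#' fx <- fig3Fixture()
#' runIteration(fx$network, seedProteins = fx$seeds, seed = 1)
#' @export
runIteration <- function(ppin, nSeeds = 1L, seedProteins = NULL,
                         seed = NULL) {
    adj <- .ppinAdjacency(ppin)
    .withSeed(seed, {
        idx <- .drawSeeds(ppin@nodes, nSeeds, seedProteins)
        lapply(.iterateOnce(adj, idx),
               function(m) sort(rownames(adj)[m]))
    })
}

.drawSeeds <- function(nodes, nSeeds, seedProteins) {
    if (!is.null(seedProteins)) {
        idx <- match(seedProteins, nodes)
        if (anyNA(idx))
            stop("unknown seed protein: ",
                 seedProteins[which(is.na(idx))[1L]])
        return(idx)
    }
    nSeeds <- as.integer(nSeeds)
    if (nSeeds < 1L) stop("nSeeds must be >= 1")
    if (nSeeds > length(nodes))
        stop("nSeeds (", nSeeds, ") exceeds the number of proteins (",
             length(nodes), ")")
    sample.int(length(nodes), nSeeds)
}

#' Enumerate cliques over many randomized iterations
#'
#' Repeats [runIteration()] `iterations` times with fresh random seed
#' proteins, recording per-iteration provenance. The deduplicated view
#' (key: sorted protein tuple) approximates the PPIN's maximal-clique
#' set; with the single-seed strategy every emitted clique is maximal,
#' and for a large iteration count the unique set converges to the full
#' maximal-clique enumeration.
#'
#' @param ppin a [ProteinNetwork-class].
#' @param iterations number of iterations (>= 1). Genome-scale analyses
#'   use counts in the millions (e.g. 2,000,000 single-seed or
#'   1,020,000 x 25 seeds); desk-scale graphs saturate at thousands.
#' @param nSeeds seed proteins per iteration (1 = single-seed strategy).
#' @param seed optional RNG seed; the whole enumeration is reproducible
#'   given this seed.
#' @param progressEvery if > 0, message the unique-clique saturation
#'   (new uniques per block) every that many iterations.
#' @return A [CliqueCollection-class].
#' @examples
#' fx <- fig3Fixture()
#' cc <- enumerateCliques(fx$network, iterations = 50, seed = 1)
#' length(uniqueCliques(cc))
#' @export
enumerateCliques <- function(ppin, iterations, nSeeds = 1L, seed = NULL,
                             progressEvery = 0L) {
    iterations <- as.integer(iterations)
    if (iterations < 1L) stop("iterations must be >= 1")
    adj <- .ppinAdjacency(ppin)
    nodes <- rownames(adj)
    .withSeed(seed, {
        cl <- vector("list", 0L)
        it <- integer(0)
        seen <- new.env(hash = TRUE, parent = emptyenv())
        newInBlock <- 0L
        for (i in seq_len(iterations)) {
            idx <- .drawSeeds(nodes, nSeeds, NULL)
            res <- .iterateOnce(adj, idx)
            for (m in res) {
                cq <- sort(nodes[m])
                cl[[length(cl) + 1L]] <- cq
                it[[length(it) + 1L]] <- i
                key <- paste(cq, collapse = ";")
                if (is.null(seen[[key]])) {
                    seen[[key]] <- TRUE
                    newInBlock <- newInBlock + 1L
                }
            }
            if (progressEvery > 0L && i %% progressEvery == 0L) {
                message("iteration ", i, ": ", length(cl), " cliques, ",
                        length(ls(seen)), " unique (+", newInBlock,
                        " this block)")
                newInBlock <- 0L
            }
        }
        new("CliqueCollection", cliques = cl, iteration = it,
            nIterations = iterations, nSeeds = as.integer(nSeeds))
    })
}

#' Exact maximal-clique oracle for small graphs
#'
#' Exhaustive maximal clique enumeration (Bron-Kerbosch with pivoting,
#' via igraph) restricted to cliques of size >= 3. Intended as the
#' reference against which the randomized heuristic is validated; guarded
#' by a node bound because exact enumeration is exponential in general.
#'
#' @param ppin a [ProteinNetwork-class].
#' @param bound maximum number of nodes accepted (default 50).
#' @return list of maximal cliques (sorted character vectors), in
#'   canonical order.
#' @export
mceOracle <- function(ppin, bound = 50L) {
    if (length(ppin@nodes) > bound)
        stop("network has ", length(ppin@nodes),
             " nodes, exceeding the oracle bound of ", bound)
    if (nrow(ppin@edges) == 0L) return(list())
    g <- .ppinIgraph(ppin)
    cl <- igraph::max_cliques(g, min = 3L)
    cl <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
    keys <- vapply(cl, .cliqueKey, "")
    cl[order(keys)]
}
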