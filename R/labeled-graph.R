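#' Transform a PPIN into the labeled working graph
#'
#' Step I, phase 1: every protein becomes a singleton vertex; every PPIN
#' edge becomes a labeled-graph edge of weight 1. As vertices are merged
#' the weight of an edge always counts the number of PPIN relations
#' between the two label sets, so a weight equal to the product of the
#' two label-set sizes certifies full mutual adjacency.
#'
#' @param ppin a non-empty [ProteinNetwork-class].
#' @return A [LabeledGraph-class].
#' @examples
#' g <- transformNetwork(fig3Fixture()$network)
#' edgeWeight(g, "p1", "p2")
#' @export
transformNetwork <- function(ppin) {
    if (length(ppin@nodes) == 0L) stop("cannot transform an empty network")
    labels <- as.list(ppin@nodes)
    names(labels) <- ppin@nodes
    w <- matrix(0, length(labels), length(labels),
                dimnames = list(names(labels), names(labels)))
    if (nrow(ppin@edges)) {
        i <- match(ppin@edges$from, names(labels))
        j <- match(ppin@edges$to, names(labels))
        w[cbind(i, j)] <- 1
        w[cbind(j, i)] <- 1
    }
    new("LabeledGraph", labels = labels, weights = w, network = ppin)
}

#' Merge two fully interconnected vertices of a LabeledGraph
#'
#' Two vertices may merge only when the weight of their connecting edge
#' equals the product of their label-set sizes, i.e. every protein of one
#' label set interacts with every protein of the other, so the merged
#' label set is again a clique of the PPIN. Weights to all remaining
#' vertices are summed (an absent edge counts 0).
#'
#' @param g a [LabeledGraph-class].
#' @param u,v vertex identifiers connected by an edge.
#' @return list with elements `graph` (updated [LabeledGraph-class]) and
#'   `vertex` (identifier of the merged vertex, the comma-joined sorted
#'   label set).
#' @export
mergeVertices <- function(g, u, v) {
    labs <- g@labels
    if (!u %in% names(labs) || !v %in% names(labs))
        stop("unknown vertex: ", setdiff(c(u, v), names(labs))[1L])
    w <- g@weights[u, v]
    if (w == 0) stop("merge refused: no edge between '", u, "' and '", v, "'")
    expect <- length(labs[[u]]) * length(labs[[v]])
    if (w != expect)
        stop("merge refused: weight ", w, " < ", expect,
             " (label sets not fully interconnected)")
    newLab <- sort(c(labs[[u]], labs[[v]]))
    z <- paste(newLab, collapse = ",")
    keep <- setdiff(names(labs), c(u, v))
    newRow <- g@weights[u, keep, drop = TRUE] + g@weights[v, keep, drop = TRUE]
    W <- g@weights[keep, keep, drop = FALSE]
    W <- rbind(cbind(W, newRow), c(newRow, 0))
    rownames(W)[nrow(W)] <- z
    colnames(W)[ncol(W)] <- z
    labs <- labs[keep]
    labs[[z]] <- newLab
    g@labels <- labs
    g@weights <- W
    list(graph = g, vertex = z)
}

#' Find a minimal clique (triangle) containing a seed protein
#'
#' Step I, phase 2: starting from a seed, the search explores its
#' neighbors (and their neighbors) in random order among the available
#' singleton vertices, and the first triangle found is merged into a
#' clique vertex via two [mergeVertices()] calls. A seed that is not part
#' of any such triangle is dropped.
#'
#' @param g a [LabeledGraph-class].
#' @param seed a protein ID labelling a singleton vertex of `g`.
#' @return list with elements `graph` and `vertex` (the merged triangle
#'   vertex, or `NULL` if the seed is dropped, in which case the graph is
#'   returned unchanged).
#' @export
findMinimalClique <- function(g, seed) {
    labs <- g@labels
    if (!seed %in% names(labs)) stop("seed '", seed, "' not in graph")
    if (length(labs[[seed]]) != 1L)
        stop("seed '", seed, "' is not a singleton vertex")
    singles <- names(labs)[lengths(labs) == 1L]
    nb <- singles[g@weights[seed, singles] > 0 & singles != seed]
    if (length(nb) >= 2L) {
        nb <- nb[sample.int(length(nb))]
        for (i in seq_len(length(nb) - 1L)) {
            rest <- nb[(i + 1L):length(nb)]
            hit <- rest[g@weights[nb[i], rest] > 0]
            if (length(hit)) {
                m1 <- mergeVertices(g, seed, nb[i])
                m2 <- mergeVertices(m1$graph, m1$vertex, hit[1L])
                return(m2)
            }
        }
    }
    list(graph = g, vertex = NULL)
}

#' Extend minimal cliques until no clique can be enlarged further
#'
#' Step I, phase 3: in a freshly shuffled round-robin order, each clique
#' vertex is merged with a neighbor that is fully interconnected with it
#' (weight equal to the product of label-set sizes). Eligible neighbors
#' are available singleton vertices and other clique vertices of the same
#' iteration; when several qualify, one is picked uniformly at random.
#' A protein consumed by a clique never migrates to another clique, but
#' whole cliques may fuse. The pass loop stops after a full pass without
#' a merge.
#'
#' @param g a [LabeledGraph-class].
#' @param cliqueVertices character vector of clique-vertex IDs produced
#'   by [findMinimalClique()] on `g`.
#' @return list with elements `graph` and `cliques` (list of protein
#'   label sets, one per surviving clique vertex).
#' @export
extendCliques <- function(g, cliqueVertices) {
    cv <- cliqueVertices
    stopifnot(all(cv %in% names(g@labels)))
    repeat {
        merged <- FALSE
        for (ci in sample.int(length(cv))) {
            v <- cv[ci]
            if (is.na(v)) next
            labs <- g@labels
            sz <- length(labs[[v]])
            singles <- names(labs)[lengths(labs) == 1L &
                                   !names(labs) %in% cv[!is.na(cv)]]
            candS <- singles[g@weights[v, singles] == sz]
            others <- cv[!is.na(cv) & cv != v]
            candC <- others[g@weights[v, others] ==
                            sz * lengths(labs[others])]
            cand <- c(candS, candC)
            if (!length(cand)) next
            pick <- cand[[sample.int(length(cand), 1L)]]
            res <- mergeVertices(g, v, pick)
            g <- res$graph
            cv[ci] <- res$vertex
            if (pick %in% cv) cv[match(pick, cv)] <- NA
            merged <- TRUE
        }
        if (!merged) break
    }
    cv <- cv[!is.na(cv)]
    list(graph = g, cliques = unname(g@labels[cv]))
}
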