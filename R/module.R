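# Step III: assembly and analysis of the regulatory module.

#' Assemble the regulatory module from significant cliques
#'
#' The module is the union of all significantly enriched cliques: its
#' node set is the union of their proteins and its edge set the union of
#' their within-clique pairs (each clique contributes its complete pair
#' set, all of which exist in the PPIN by clique validity). With
#' `induced = TRUE` the edge set is instead the PPIN-induced subgraph on
#' the module nodes.
#'
#' @param results data.frame from [testCliques()].
#' @param ppin the [ProteinNetwork-class] the cliques came from.
#' @param genes a [GeneSets-class] (for node annotations).
#' @param alpha significance cutoff (strict `perm_p < alpha`); defaults
#'   to the alpha recorded on `results`.
#' @param induced use PPIN-induced edges instead of the clique union.
#' @return A [RegulatoryModule-class]. If no clique is significant an
#'   empty module is returned with a warning.
#' @export
assembleModule <- function(results, ppin, genes,
                           alpha = attr(results, "alpha"),
                           induced = FALSE) {
    if (is.null(alpha)) alpha <- 0.01
    sig <- results[results$eligible & !is.na(results$perm_p) &
                   results$perm_p < alpha, , drop = FALSE]
    emptyAnn <- data.frame(protein = character(0),
                           is_deg_associated = logical(0),
                           is_background_associated = logical(0),
                           stringsAsFactors = FALSE)
    if (nrow(sig) == 0L) {
        warning("no significantly enriched clique at alpha = ", alpha,
                "; returning an empty module")
        return(.newModule(character(0), NULL, emptyAnn))
    }
    cliques <- .splitCliqueKey(sig$clique)
    nodes <- sort(unique(unlist(cliques)))
    if (induced) {
        e <- ppin@edges
        edges <- e[e$from %in% nodes & e$to %in% nodes,
                   c("from", "to"), drop = FALSE]
    } else {
        edges <- unique(do.call(rbind, lapply(cliques, .pairsWithin)))
        missing <- !(.edgeKeys(edges) %in% .edgeKeys(ppin@edges))
        if (any(missing))
            stop("internal error: clique pair absent from the PPIN")
    }
    assoc <- .proteinAssoc(genes)
    ann <- data.frame(protein = nodes,
                      is_deg_associated = nodes %in% assoc$deg,
                      is_background_associated = nodes %in% assoc$bg,
                      stringsAsFactors = FALSE)
    .newModule(nodes, edges, ann)
}

#' Module-level permutation p-value for DEG enrichment
#'
#' The observed statistic is the number of module proteins associated to
#' a DEG; the p-value is the fraction of background samples whose
#' corresponding statistic (module proteins associated to the sampled
#' gene set) is at least as large. Resolution is `1/|B|`; a result of 0
#' is reported as `< 1/|B|` in the message.
#'
#' @param module a non-empty [RegulatoryModule-class].
#' @param genes a [GeneSets-class].
#' @param samples a [BackgroundSamples-class].
#' @return p-value in `[0, 1]`.
#' @export
moduleEnrichmentP <- function(module, genes, samples) {
    if (!length(module@nodes)) stop("empty module")
    if (!length(samples@sets)) stop("no background samples")
    map <- genes@mapping
    map <- map[map$protein %in% module@nodes, , drop = FALSE]
    assoc <- .proteinAssoc(genes)
    obs <- sum(module@nodes %in% assoc$deg)
    geneByProt <- split(map$gene, map$protein)
    stats_ <- vapply(samples@sets, function(b) {
        sum(vapply(geneByProt, function(gs) any(gs %in% b), logical(1)))
    }, 1L)
    p <- mean(stats_ >= obs)
    if (p == 0)
        message("module enrichment p-value below resolution: < 1/",
                length(samples@sets), " (reported 0)")
    p
}

#' Detect sub-modules by divisive edge-betweenness clustering
#'
#' Girvan-Newman community detection: edges of highest betweenness are
#' removed iteratively and the resulting dendrogram is cut at maximum
#' modularity (unit edge weights). The procedure is deterministic, and
#' the sub-modules always refine the connected components.
#'
#' @param module a non-empty [RegulatoryModule-class].
#' @return the module with its `submodules` slot filled (a named integer
#'   membership vector, retrievable with [submodules()]).
#' @export
detectSubmodules <- function(module) {
    if (!length(module@nodes)) stop("empty module")
    g <- .moduleIgraph(module)
    cl <- igraph::cluster_edge_betweenness(g, weights = NULL,
                                           directed = FALSE)
    mem <- as.integer(igraph::membership(cl))
    names(mem) <- igraph::V(g)$name
    module@submodules <- mem[module@nodes]
    validObject(module)
    module
}

#' @rdname connectedComponents
setMethod("connectedComponents", "RegulatoryModule", function(x) {
    if (!length(x@nodes)) return(stats::setNames(integer(0), character(0)))
    g <- .moduleIgraph(x)
    mem <- as.integer(igraph::components(g)$membership)
    names(mem) <- igraph::V(g)$name
    mem[x@nodes]
})
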