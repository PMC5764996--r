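#' @import methods
NULL

#' ProteinNetwork: a score-filtered protein-protein interaction network
#'
#' An undirected graph of proteins with evidence-scored interactions,
#' filtered at a confidence cutoff (edges with score strictly greater than
#' the cutoff are retained). Edges are stored canonically (`from < to`),
#' without self-loops or duplicates.
#'
#' @slot nodes character vector of protein identifiers (opaque strings).
#' @slot edges data.frame with columns `from`, `to`, `score`.
#' @slot cutoff numeric confidence cutoff the edges were filtered at.
#'
#' @seealso [readStringLinks()], [fig3Fixture()], [generatePlanted()]
#' @exportClass ProteinNetwork
setClass("ProteinNetwork",
    representation(nodes = "character", edges = "data.frame",
                   cutoff = "numeric"))

setValidity("ProteinNetwork", function(object) {
    e <- object@edges
    msgs <- character(0)
    if (!all(c("from", "to", "score") %in% names(e)))
        return("edges must have columns from, to, score")
    if (nrow(e)) {
        if (any(e$from == e$to)) msgs <- c(msgs, "self-loops are not allowed")
        if (any(e$from > e$to)) msgs <- c(msgs, "edges must be canonical (from < to)")
        if (anyDuplicated(.edgeKeys(e))) msgs <- c(msgs, "duplicate edges")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msgs <- c(msgs, "edge endpoint not in node set")
        if (length(object@cutoff) == 1L && any(e$score <= object@cutoff))
            msgs <- c(msgs, "edge with score not exceeding the cutoff")
    }
    if (length(msgs)) msgs else TRUE
})

#' Construct a ProteinNetwork
#'
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `score` (defaults to 1). Pairs are canonicalized; self-loops dropped;
#'   duplicate pairs collapsed to their maximum score.
#' @param nodes optional character vector of node IDs; defaults to the
#'   edge endpoints. May be a superset (isolated proteins allowed).
#' @param cutoff numeric score cutoff associated with the network
#'   (edges must exceed it strictly). Default 0.
#' @return A [ProteinNetwork-class] object.
#' @examples
#' pn <- ProteinNetwork(data.frame(from = c("a", "b"), to = c("b", "c")))
#' networkNodes(pn)
#' @export
ProteinNetwork <- function(edges, nodes = NULL, cutoff = 0) {
    if (is.null(edges) || nrow(edges) == 0L) {
        edges <- data.frame(from = character(0), to = character(0),
                            score = numeric(0), stringsAsFactors = FALSE)
    } else {
        score <- if ("score" %in% names(edges)) as.numeric(edges$score) else
            rep(1, nrow(edges))
        e <- .canonPairs(edges$from, edges$to)
        e$score <- score
        e <- e[e$from != e$to, , drop = FALSE]
        if (nrow(e)) {
            key <- .edgeKeys(e)
            mx <- tapply(e$score, key, max)
            e <- e[!duplicated(key), , drop = FALSE]
            e$score <- as.numeric(mx[.edgeKeys(e)])
            e <- e[order(e$from, e$to), , drop = FALSE]
            rownames(e) <- NULL
        }
        edges <- e
    }
    if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
    nodes <- sort(unique(as.character(nodes)))
    new("ProteinNetwork", nodes = nodes, edges = edges,
        cutoff = as.numeric(cutoff))
}

#' GeneSets: DEG list, statistical background and gene-to-protein mapping
#'
#' Holds the set of differentially expressed genes (DEGs, `D`), the
#' background of all measured genes (`N`, the statistical universe of the
#' enrichment tests), and a many-to-many gene-to-protein mapping. DEGs
#' outside the background are dropped with a warning on construction.
#'
#' @slot deg character vector of DEG identifiers (subset of background).
#' @slot background character vector of all measured gene identifiers.
#' @slot mapping data.frame with columns `gene`, `protein`.
#' @exportClass GeneSets
setClass("GeneSets",
    representation(deg = "character", background = "character",
                   mapping = "data.frame"))

setValidity("GeneSets", function(object) {
    msgs <- character(0)
    if (!all(object@deg %in% object@background))
        msgs <- c(msgs, "deg must be a subset of background")
    if (!all(c("gene", "protein") %in% names(object@mapping)))
        msgs <- c(msgs, "mapping must have columns gene, protein")
    if (nrow(object@mapping) &&
        (any(!nzchar(object@mapping$gene)) || any(!nzchar(object@mapping$protein))))
        msgs <- c(msgs, "mapping entries must be non-empty strings")
    if (length(msgs)) msgs else TRUE
})

#' Construct a GeneSets object
#'
#' @param deg character vector of DEG identifiers.
#' @param background character vector of measured gene identifiers.
#' @param mapping optional data.frame with columns `gene`, `protein`
#'   (many-to-many allowed). `NULL` assumes the identity mapping over the
#'   background genes.
#' @return A [GeneSets-class] object. DEGs not present in the background
#'   are reported and dropped.
#' @examples
#' gs <- GeneSets(deg = "g1", background = c("g1", "g2", "g3"))
#' degGenes(gs)
#' @export
GeneSets <- function(deg, background, mapping = NULL) {
    deg <- unique(as.character(deg))
    background <- unique(as.character(background))
    outside <- setdiff(deg, background)
    if (length(outside)) {
        warning("dropping ", length(outside),
                " DEG(s) not in the background: ",
                paste(utils::head(outside, 10L), collapse = ", "))
        deg <- intersect(deg, background)
    }
    if (is.null(mapping)) {
        mapping <- data.frame(gene = background, protein = background,
                              stringsAsFactors = FALSE)
    } else {
        mapping <- data.frame(gene = as.character(mapping$gene),
                              protein = as.character(mapping$protein),
                              stringsAsFactors = FALSE)
        mapping <- unique(mapping)
    }
    new("GeneSets", deg = deg, background = background, mapping = mapping)
}

#' LabeledGraph: the working graph of the clique-enumeration step
#'
#' Vertices carry pairwise-disjoint sets of protein labels whose union is
#' the PPIN's node set; an integer edge weight counts the PPIN relations
#' between the two label sets. Vertex identifiers are the comma-joined
#' sorted label sets, so a merged vertex reads like `"p1,p2,p4"`.
#'
#' @slot labels named list mapping vertex ID to its protein label set.
#' @slot weights numeric matrix (vertex x vertex); 0 encodes "no edge".
#' @slot network the source [ProteinNetwork-class].
#' @exportClass LabeledGraph
setClass("LabeledGraph",
    representation(labels = "list", weights = "matrix",
                   network = "ProteinNetwork"))

setValidity("LabeledGraph", function(object) {
    labs <- object@labels
    msgs <- character(0)
    all_prot <- unlist(labs, use.names = FALSE)
    if (anyDuplicated(all_prot))
        msgs <- c(msgs, "label sets must be pairwise disjoint")
    if (!setequal(all_prot, object@network@nodes))
        msgs <- c(msgs, "union of labels must equal the network node set")
    w <- object@weights
    if (!identical(rownames(w), names(labs)) ||
        !identical(colnames(w), names(labs)))
        msgs <- c(msgs, "weight matrix dimnames must match vertex IDs")
    if (length(msgs)) msgs else TRUE
})

#' CliqueCollection: enumerated cliques with per-iteration provenance
#'
#' A multiset of cliques (protein sets of size >= 3, each a complete
#' subgraph of the source PPIN) recording which enumeration iteration
#' produced each one. The deduplicated view is available through
#' [uniqueCliques()] and [cliqueMultiplicity()].
#'
#' @slot cliques list of sorted character vectors (one per record).
#' @slot iteration integer vector, the iteration index of each record.
#' @slot nIterations total number of iterations run.
#' @slot nSeeds number of seed proteins per iteration.
#' @exportClass CliqueCollection
setClass("CliqueCollection",
    representation(cliques = "list", iteration = "integer",
                   nIterations = "integer", nSeeds = "integer"))

setValidity("CliqueCollection", function(object) {
    if (length(object@cliques) != length(object@iteration))
        return("cliques and iteration must have equal length")
    if (length(object@iteration) &&
        (any(object@iteration < 1L) ||
         any(object@iteration > object@nIterations)))
        return("iteration indices out of range")
    if (any(vapply(object@cliques, length, 1L) < 3L))
        return("all cliques must have size >= 3")
    TRUE
})

#' BackgroundSamples: random gene sets drawn from the background
#'
#' Each set contains exactly `|D|` distinct genes sampled uniformly
#' without replacement from the background `N`; these are the sets `B`
#' of the permutation test.
#'
#' @slot sets list of character vectors.
#' @slot seed integer RNG seed used to draw the samples (NA if drawn from
#'   the ambient RNG stream).
#' @exportClass BackgroundSamples
setClass("BackgroundSamples",
    representation(sets = "list", seed = "integer"))

#' RegulatoryModule: the union of significantly enriched cliques
#'
#' @slot nodes character vector of module proteins.
#' @slot edges data.frame (`from`, `to`), canonical; every edge lies
#'   inside at least one significant clique (or, with induced assembly,
#'   inside the PPIN-induced subgraph on the module nodes).
#' @slot annotations data.frame with columns `protein`,
#'   `is_deg_associated`, `is_background_associated`.
#' @slot submodules named integer vector (may be empty until
#'   [detectSubmodules()] is called).
#' @slot modP numeric module-level permutation p-value (NA until
#'   [moduleEnrichmentP()] is called).
#' @exportClass RegulatoryModule
setClass("RegulatoryModule",
    representation(nodes = "character", edges = "data.frame",
                   annotations = "data.frame", submodules = "integer",
                   modP = "numeric"))

setValidity("RegulatoryModule", function(object) {
    e <- object@edges
    msgs <- character(0)
    if (nrow(e)) {
        if (any(e$from >= e$to)) msgs <- c(msgs, "edges must be canonical")
        if (!all(c(e$from, e$to) %in% object@nodes))
            msgs <- c(msgs, "edge endpoint outside the module node set")
    }
    if (length(object@submodules) &&
        !setequal(names(object@submodules), object@nodes))
        msgs <- c(msgs, "submodules must partition the module nodes")
    if (length(msgs)) msgs else TRUE
})

# Internal module constructor.
.newModule <- function(nodes, edges, annotations,
                       submodules = integer(0), modP = NA_real_) {
    nodes <- sort(unique(as.character(nodes)))
    if (is.null(edges) || nrow(edges) == 0L) {
        edges <- data.frame(from = character(0), to = character(0),
                            stringsAsFactors = FALSE)
    } else {
        edges <- unique(.canonPairs(edges$from, edges$to))
        edges <- edges[order(edges$from, edges$to), , drop = FALSE]
        rownames(edges) <- NULL
    }
    new("RegulatoryModule", nodes = nodes, edges = edges,
        annotations = annotations, submodules = submodules, modP = modP)
}

#' StabilityReport: bootstrap reproducibility of a regulatory module
#'
#' @slot nBootstrap number of bootstrap modules compared.
#' @slot distances numeric vector of all pairwise module distances.
#' @slot variability median pairwise distance divided by the mean of
#'   `|nodes| + |edges|` over the bootstrap modules; 0 iff all modules
#'   are identical.
#' @exportClass StabilityReport
setClass("StabilityReport",
    representation(nBootstrap = "integer", distances = "numeric",
                   variability = "numeric"))

#' PlantedDesign: parameters of the synthetic planted-clique generator
#'
#' @slot nCliques number of planted cliques.
#' @slot sizeRange integer length-2 range of clique sizes.
#' @slot overlap number of proteins shared between consecutive cliques.
#' @slot nBackground number of additional background proteins.
#' @slot noiseProb probability of a noise edge between any pair not
#'   inside a planted clique (edges that would enlarge a planted clique
#'   are rejected).
#' @slot enriched integer indices of the DEG-enriched cliques.
#' @slot degFracInside per-gene DEG probability inside enriched cliques.
#' @slot degFracOutside per-gene DEG probability elsewhere.
#' @exportClass PlantedDesign
setClass("PlantedDesign",
    representation(nCliques = "integer", sizeRange = "integer",
                   overlap = "integer", nBackground = "integer",
                   noiseProb = "numeric", enriched = "integer",
                   degFracInside = "numeric", degFracOutside = "numeric"))

setValidity("PlantedDesign", function(object) {
    msgs <- character(0)
    if (object@nCliques < 1L) msgs <- c(msgs, "need at least one clique")
    if (length(object@sizeRange) != 2L || any(object@sizeRange < 3L))
        msgs <- c(msgs, "sizeRange must be two integers >= 3")
    if (object@overlap >= min(object@sizeRange))
        msgs <- c(msgs, "overlap must be smaller than the smallest clique")
    if (object@overlap < 0L) msgs <- c(msgs, "overlap must be >= 0")
    if (object@noiseProb < 0 || object@noiseProb > 1)
        msgs <- c(msgs, "noiseProb must be in [0,1]")
    if (length(object@enriched) &&
        (any(object@enriched < 1L) || any(object@enriched > object@nCliques)))
        msgs <- c(msgs, "enriched indices out of range")
    if (any(c(object@degFracInside, object@degFracOutside) < 0) ||
        any(c(object@degFracInside, object@degFracOutside) > 1))
        msgs <- c(msgs, "DEG fractions must be in [0,1]")
    if (object@degFracInside < object@degFracOutside)
        msgs <- c(msgs, "degFracInside must be >= degFracOutside")
    if (length(msgs)) msgs else TRUE
})
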