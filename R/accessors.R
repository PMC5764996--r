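#' @rdname ProteinNetwork-class
setMethod("networkNodes", "ProteinNetwork", function(x) x@nodes)

#' @rdname ProteinNetwork-class
setMethod("networkEdges", "ProteinNetwork", function(x) x@edges)

setMethod("show", "ProteinNetwork", function(object) {
    cat("ProteinNetwork with", length(object@nodes), "proteins and",
        nrow(object@edges), "interactions (score >", object@cutoff, ")\n")
})

#' @rdname GeneSets-class
setMethod("degGenes", "GeneSets", function(x) x@deg)

#' @rdname GeneSets-class
setMethod("backgroundGenes", "GeneSets", function(x) x@background)

#' @rdname GeneSets-class
setMethod("geneMapping", "GeneSets", function(x) x@mapping)

setMethod("show", "GeneSets", function(object) {
    cat("GeneSets:", length(object@deg), "DEGs in a background of",
        length(object@background), "genes;",
        nrow(object@mapping), "gene-protein mapping entries\n")
})

#' @rdname LabeledGraph-class
setMethod("vertexLabels", "LabeledGraph", function(x) x@labels)

#' @rdname LabeledGraph-class
setMethod("edgeWeight", "LabeledGraph", function(x, u, v) {
    stopifnot(u %in% names(x@labels), v %in% names(x@labels))
    unname(x@weights[u, v])
})

setMethod("show", "LabeledGraph", function(object) {
    nv <- length(object@labels)
    cat("LabeledGraph with", nv, "vertices over",
        length(object@network@nodes), "proteins;",
        sum(object@weights > 0) / 2, "edges\n")
})

#' @rdname CliqueCollection-class
setMethod("uniqueCliques", "CliqueCollection", function(x) {
    keys <- vapply(x@cliques, .cliqueKey, "")
    x@cliques[!duplicated(keys)]
})

#' @rdname CliqueCollection-class
setMethod("cliqueMultiplicity", "CliqueCollection", function(x) {
    keys <- vapply(x@cliques, .cliqueKey, "")
    tab <- table(keys)
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
})

setMethod("show", "CliqueCollection", function(object) {
    keys <- vapply(object@cliques, .cliqueKey, "")
    cat("CliqueCollection:", length(object@cliques), "cliques (",
        length(unique(keys)), "unique ) from", object@nIterations,
        "iterations x", object@nSeeds, "seed(s)\n")
})

setMethod("show", "BackgroundSamples", function(object) {
    cat("BackgroundSamples:", length(object@sets), "gene sets of size",
        if (length(object@sets)) length(object@sets[[1L]]) else 0, "\n")
})

#' @rdname RegulatoryModule-class
setMethod("moduleNodes", "RegulatoryModule", function(x) x@nodes)

#' @rdname RegulatoryModule-class
setMethod("moduleEdges", "RegulatoryModule", function(x) x@edges)

#' @rdname RegulatoryModule-class
setMethod("moduleAnnotations", "RegulatoryModule", function(x) x@annotations)

#' @rdname RegulatoryModule-class
setMethod("submodules", "RegulatoryModule", function(x) x@submodules)

setMethod("show", "RegulatoryModule", function(object) {
    ann <- object@annotations
    cat("RegulatoryModule with", length(object@nodes), "proteins and",
        nrow(object@edges), "relations\n")
    if (nrow(ann)) {
        cat("  DEG-associated:", sum(ann$is_deg_associated),
            "; background-associated:", sum(ann$is_background_associated),
            "\n")
    }
    if (length(object@submodules))
        cat("  sub-modules:", length(unique(object@submodules)), "\n")
    if (!is.na(object@modP))
        cat("  module enrichment p:",
            if (object@modP == 0) "< 1/|B| (reported 0)" else object@modP,
            "\n")
})

#' @rdname StabilityReport-class
setMethod("variability", "StabilityReport", function(x) x@variability)

#' @rdname StabilityReport-class
setMethod("pairwiseDistances", "StabilityReport", function(x) x@distances)

setMethod("show", "StabilityReport", function(object) {
    cat("StabilityReport over", object@nBootstrap, "bootstrap modules\n",
        " median distance:", stats::median(object@distances),
        "; variability:", sprintf("%.3f%%", 100 * object@variability), "\n")
})
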