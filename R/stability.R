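# Bootstrap reproducibility of the regulatory module.
#
# The heuristic approximates an unknown exact community structure, so
# approximation quality is assessed indirectly: if re-running more
# iterations would still change the module, bootstrap resamples of the
# existing iterations will disagree. Each bootstrap draws n iteration
# indices with replacement (n = original iteration count), pools their
# cliques, and rebuilds the module. Background samples are held fixed
# across bootstraps so that variability reflects clique sampling only;
# per-clique p-values do not depend on multiplicity, so each unique
# clique is tested once and the results reused.

#' Rebuild regulatory modules from bootstrap resamples of iterations
#'
#' @param collection a [CliqueCollection-class] with per-iteration
#'   provenance.
#' @param ppin the source [ProteinNetwork-class].
#' @param genes a [GeneSets-class].
#' @param samples a [BackgroundSamples-class] (held fixed across
#'   bootstraps).
#' @param alpha significance cutoff (default 0.01).
#' @param nBootstrap number of bootstrap samples (>= 2; default 100).
#' @param seed optional RNG seed.
#' @return list of [RegulatoryModule-class] objects, one per bootstrap.
#' @export
bootstrapModules <- function(collection, ppin, genes, samples,
                             alpha = 0.01, nBootstrap = 100L,
                             seed = NULL) {
    nBootstrap <- as.integer(nBootstrap)
    if (nBootstrap < 2L) stop("nBootstrap must be >= 2")
    nIter <- collection@nIterations
    if (is.na(nIter) || nIter < 1L || !length(collection@iteration))
        stop("collection lacks per-iteration provenance")
    res <- testCliques(collection, genes, samples, alpha = alpha)
    keys <- vapply(collection@cliques, .cliqueKey, "")
    .withSeed(seed, {
        lapply(seq_len(nBootstrap), function(b) {
            idx <- sample.int(nIter, nIter, replace = TRUE)
            present <- unique(keys[collection@iteration %in% idx])
            sub <- res[res$clique %in% present, , drop = FALSE]
            suppressWarnings(
                assembleModule(sub, ppin, genes, alpha = alpha))
        })
    })
}

#' Distance between two regulatory modules
#'
#' The number of nodes plus the number of edges present in exactly one
#' of the two modules (symmetric-difference counts, equally weighted).
#' This is a metric on (node set, edge set) pairs.
#'
#' @param m1,m2 [RegulatoryModule-class] objects.
#' @return non-negative number; 0 iff the modules share both sets.
#' @export
moduleDistance <- function(m1, m2) {
    nd <- length(setdiff(m1@nodes, m2@nodes)) +
        length(setdiff(m2@nodes, m1@nodes))
    k1 <- .edgeKeys(m1@edges)
    k2 <- .edgeKeys(m2@edges)
    ed <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
    nd + ed
}

#' Summarize bootstrap module stability
#'
#' Computes all pairwise [moduleDistance()]s among the bootstrap modules
#' and the variability statistic: the median pairwise distance divided by
#' the average of `|nodes| + |edges|` over the modules. A variability of
#' 0 means every bootstrap produced the identical module; published
#' full-scale analyses report average variabilities below 5%.
#'
#' @param modules list of at least two [RegulatoryModule-class] objects.
#' @return A [StabilityReport-class].
#' @export
stabilityReport <- function(modules) {
    if (length(modules) < 2L) stop("need at least two modules")
    sizes <- vapply(modules, function(m)
        length(m@nodes) + nrow(m@edges), 1)
    if (all(sizes == 0))
        stop("all bootstrap modules are empty; variability is undefined")
    idx <- utils::combn(length(modules), 2L)
    d <- vapply(seq_len(ncol(idx)), function(i)
        moduleDistance(modules[[idx[1L, i]]], modules[[idx[2L, i]]]), 1)
    new("StabilityReport", nBootstrap = length(modules),
        distances = d,
        variability = stats::median(d) / mean(sizes))
}

#' Write a stability report as TSV
#'
#' @param report a [StabilityReport-class].
#' @param path output path. Writes one row per pairwise distance plus
#'   the summary variability in a trailing comment line.
#' @return invisibly, `path`.
#' @export
writeStability <- function(report, path) {
    lines <- c("pair\tdistance",
               paste(seq_along(report@distances), report@distances,
                     sep = "\t"),
               sprintf("# n_bootstrap=%d median_distance=%g variability=%g",
                       report@nBootstrap, stats::median(report@distances),
                       report@variability))
    writeLines(lines, path)
    invisible(path)
}
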