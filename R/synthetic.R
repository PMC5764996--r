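# Synthetic fixtures: the ten-protein worked-example network and a
# planted-clique generator with planted DEG enrichment. These emulate
# the statistical structure the method assumes -- a PPIN whose community
# structure is a set of (possibly overlapping) cliques, with differential
# expression concentrated in a subset of them -- and give the pipeline a
# fully self-contained ground truth.

#' The ten-protein worked-example network
#'
#' Proteins `p1..p10` with all pairs within `{p1..p4}` (6 edges), all
#' pairs within `{p5..p10}` (15 edges) and the bridge `p4-p5` connected
#' (22 relations in total, the text-attested subset of the published
#' example figure). Its only maximal cliques of size >= 3 are the K4
#' `{p1..p4}` and the K6 `{p5..p10}`; the designated seeds are
#' `p4`, `p6`, `p9`. All scores are 0.95.
#'
#' @return list with elements `network` (a [ProteinNetwork-class]) and
#'   `seeds` (character vector `c("p4","p6","p9")`).
#' @examples
#' fx <- fig3Fixture()
#' lengths(mceOracle(fx$network))
#' @export
fig3Fixture <- function() {
    k4 <- .pairsWithin(paste0("p", 1:4))
    k6 <- .pairsWithin(paste0("p", 5:10))
    bridge <- data.frame(from = "p4", to = "p5", stringsAsFactors = FALSE)
    e <- rbind(k4, k6, bridge)
    e$score <- 0.95
    list(network = ProteinNetwork(e, nodes = paste0("p", 1:10),
                                  cutoff = 0.7),
         seeds = c("p4", "p6", "p9"))
}

#' Construct a planted-clique design
#'
#' @param nCliques number of planted cliques (default 4).
#' @param sizeRange clique size range (default `c(6, 6)`).
#' @param overlap proteins shared between consecutive cliques
#'   (default 1; must be smaller than the smallest clique).
#' @param nBackground additional background proteins (default 200).
#' @param noiseProb probability of a noise edge for each pair not inside
#'   a planted clique (default 0.01).
#' @param enriched indices of the DEG-enriched cliques (default
#'   `c(1, 2)`).
#' @param degFracInside per-gene DEG probability for genes of enriched
#'   cliques (default 0.8).
#' @param degFracOutside per-gene DEG probability elsewhere
#'   (default 0.02).
#' @return A [PlantedDesign-class].
#' @export
plantedDesign <- function(nCliques = 4L, sizeRange = c(6L, 6L),
                          overlap = 1L, nBackground = 200L,
                          noiseProb = 0.01, enriched = c(1L, 2L),
                          degFracInside = 0.8, degFracOutside = 0.02) {
    new("PlantedDesign", nCliques = as.integer(nCliques),
        sizeRange = as.integer(sizeRange), overlap = as.integer(overlap),
        nBackground = as.integer(nBackground),
        noiseProb = as.numeric(noiseProb), enriched = as.integer(enriched),
        degFracInside = as.numeric(degFracInside),
        degFracOutside = as.numeric(degFracOutside))
}

#' Generate a planted-clique PPIN with planted DEG enrichment
#'
#' Planted cliques are wired as complete subgraphs laid out along a
#' protein sequence, consecutive cliques sharing `overlap` proteins.
#' Noise edges are added between any pair not inside a planted clique
#' with probability `noiseProb`, rejecting edges that would enlarge a
#' planted clique (so with zero noise the planted cliques are exactly
#' the maximal cliques of size >= 3, and they remain maximal under
#' noise). Genes map 1:1 to proteins; each gene of an enriched clique is
#' declared a DEG with probability `degFracInside`, every other gene
#' with probability `degFracOutside`; the background contains all genes.
#'
#' @param design a [PlantedDesign-class].
#' @param seed optional RNG seed (the generator is fully reproducible
#'   given it).
#' @param scramble if `TRUE`, replace the identity gene-protein mapping
#'   by a many-to-many one (each protein additionally receives a shared
#'   alias gene) to exercise the mapping path; associations are
#'   preserved.
#' @return list with elements `network` ([ProteinNetwork-class]),
#'   `genes` ([GeneSets-class]) and `truth` (list: `cliques` -- the
#'   planted protein sets, `enriched` -- their indices, `enrichedNodes`
#'   -- the node union of the enriched cliques).
#' @examples
#' sim <- generatePlanted(plantedDesign(noiseProb = 0), seed = 1)
#' length(mceOracle(sim$network, bound = 300))
#' @export
generatePlanted <- function(design, seed = NULL, scramble = FALSE) {
    validObject(design)
    .withSeed(seed, {
        sizes <- if (design@sizeRange[1L] == design@sizeRange[2L])
            rep(design@sizeRange[1L], design@nCliques)
        else
            sample(seq(design@sizeRange[1L], design@sizeRange[2L]),
                   design@nCliques, replace = TRUE)
        cliques <- list()
        nxt <- 1L
        for (i in seq_len(design@nCliques)) {
            if (i == 1L) {
                cliques[[i]] <- seq(nxt, nxt + sizes[i] - 1L)
            } else {
                shared <- utils::tail(cliques[[i - 1L]], design@overlap)
                fresh <- seq(nxt, length.out = sizes[i] - design@overlap)
                cliques[[i]] <- c(shared, fresh)
            }
            nxt <- max(cliques[[i]]) + 1L
        }
        nCliqueProt <- nxt - 1L
        nTotal <- nCliqueProt + design@nBackground
        prot <- sprintf("prot%04d", seq_len(nTotal))
        cliqueProts <- lapply(cliques, function(ix) prot[ix])

        adj <- matrix(FALSE, nTotal, nTotal)
        for (ix in cliques) {
            adj[ix, ix] <- TRUE
        }
        diag(adj) <- FALSE
        inClique <- adj  # pairs inside at least one planted clique

        # noise edges, with rejection of clique-enlarging edges
        pairs <- which(upper.tri(adj) & !inClique, arr.ind = TRUE)
        pairs <- pairs[stats::runif(nrow(pairs)) < design@noiseProb, ,
                       drop = FALSE]
        if (nrow(pairs)) {
            for (r in sample.int(nrow(pairs))) {
                i <- pairs[r, 1L]; j <- pairs[r, 2L]
                adj[i, j] <- TRUE; adj[j, i] <- TRUE
                enlarges <- any(vapply(cliques, function(ix) {
                    for (w in c(i, j)) {
                        if (!(w %in% ix) && all(adj[w, ix])) return(TRUE)
                    }
                    FALSE
                }, logical(1)))
                if (enlarges) {
                    adj[i, j] <- FALSE; adj[j, i] <- FALSE
                }
            }
        }
        ut <- which(upper.tri(adj) & adj, arr.ind = TRUE)
        net <- ProteinNetwork(
            data.frame(from = prot[ut[, 1L]], to = prot[ut[, 2L]],
                       score = 0.95, stringsAsFactors = FALSE),
            nodes = prot, cutoff = 0.7)

        genesAll <- sub("^prot", "gene", prot)
        inside <- prot %in% unlist(cliqueProts[design@enriched])
        pDeg <- ifelse(inside, design@degFracInside, design@degFracOutside)
        isDeg <- stats::runif(nTotal) < pDeg
        mapping <- data.frame(gene = genesAll, protein = prot,
                              stringsAsFactors = FALSE)
        if (scramble) {
            alias <- data.frame(gene = sub("^gene", "alias", genesAll),
                                protein = prot, stringsAsFactors = FALSE)
            mapping <- rbind(mapping, alias)
            genesAll <- c(genesAll, alias$gene)
            isDeg <- c(isDeg, isDeg)
        }
        gs <- GeneSets(deg = genesAll[isDeg], background = genesAll,
                       mapping = mapping)
        list(network = net, genes = gs,
             truth = list(cliques = cliqueProts,
                          enriched = design@enriched,
                          enrichedNodes =
                              sort(unique(unlist(cliqueProts[design@enriched])))))
    })
}

#' Write a generated dataset to disk in the pipeline's input formats
#'
#' Writes the PPIN as a STRING-style links file, the DEG and background
#' gene lists, the mapping TSV and the ground truth as JSON.
#'
#' @param sim result of [generatePlanted()].
#' @param prefix output path prefix (files `<prefix>ppin.txt`,
#'   `<prefix>deg.txt`, `<prefix>background.txt`, `<prefix>mapping.tsv`,
#'   `<prefix>truth.json`).
#' @return invisibly, the named vector of paths written.
#' @export
writePlanted <- function(sim, prefix) {
    paths <- c(ppin = paste0(prefix, "ppin.txt"),
               deg = paste0(prefix, "deg.txt"),
               background = paste0(prefix, "background.txt"),
               mapping = paste0(prefix, "mapping.tsv"),
               truth = paste0(prefix, "truth.json"))
    writeStringLinks(sim$network, paths[["ppin"]])
    writeLines(degGenes(sim$genes), paths[["deg"]])
    writeLines(backgroundGenes(sim$genes), paths[["background"]])
    utils::write.table(geneMapping(sim$genes), paths[["mapping"]],
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE)
    invisible(paths)
}
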