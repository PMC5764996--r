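# Step II: clique enrichment testing.
#
# Counting conventions: eligibility is decided at protein level (a
# protein is DEG-/background-associated iff at least one gene mapping to
# it is in D / N), while the 2x2 Fisher table is built at gene level over
# the universe N (a gene is "in the clique" iff it maps to at least one
# clique protein). The one-sided (over-representation) Fisher exact
# p-value is the hypergeometric upper tail at the observed overlap.

# protein -> association flags, precomputed once per GeneSets
.proteinAssoc <- function(genes) {
    map <- genes@mapping
    list(deg = unique(map$protein[map$gene %in% genes@deg]),
         bg = unique(map$protein[map$gene %in% genes@background]))
}

# background genes mapped to >= 1 clique protein (the gene-level clique)
.cliqueGenes <- function(clique, genes) {
    map <- genes@mapping
    intersect(unique(map$gene[map$protein %in% clique]), genes@background)
}

# hypergeometric upper tail P(X >= k) for overlap k, |cliqueGenes| = m,
# universe N, draw K
.upperTail <- function(k, m, N, K) {
    stats::phyper(k - 1, m, N - m, K, lower.tail = FALSE)
}

#' Sample random gene sets from the background
#'
#' Draws `nSamples` gene sets, each containing exactly `|D|` distinct
#' genes sampled uniformly without replacement from the background `N`.
#' These are the sets `B` against which the permutation p-value of each
#' clique is computed. The published analysis used 10,000 sets.
#'
#' @param genes a [GeneSets-class].
#' @param nSamples number of sets to draw (default 10000).
#' @param seed optional RNG seed.
#' @return A [BackgroundSamples-class].
#' @export
sampleBackgrounds <- function(genes, nSamples = 10000L, seed = NULL) {
    d <- length(genes@deg)
    if (d < 1L) stop("DEG set is empty")
    if (d > length(genes@background))
        stop("|deg| exceeds |background|")
    nSamples <- as.integer(nSamples)
    if (nSamples < 1L) stop("nSamples must be >= 1")
    sets <- .withSeed(seed, replicate(nSamples,
                                      sample(genes@background, d),
                                      simplify = FALSE))
    new("BackgroundSamples", sets = sets,
        seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Clique eligibility for enrichment testing
#'
#' A clique is tested only if (i) at least one of its proteins is
#' associated to a DEG and (ii) at least half of its proteins are
#' associated to genes in the statistical background.
#'
#' @param clique character vector of clique proteins (size >= 3).
#' @param genes a [GeneSets-class].
#' @return list with elements `eligible`, `size`, `nDegAssoc`,
#'   `nBackgroundAssoc` (protein-level counts).
#' @export
cliqueEligibility <- function(clique, genes) {
    clique <- unique(as.character(clique))
    assoc <- .proteinAssoc(genes)
    nDeg <- sum(clique %in% assoc$deg)
    nBg <- sum(clique %in% assoc$bg)
    list(eligible = nDeg >= 1L && 2L * nBg >= length(clique),
         size = length(clique), nDegAssoc = nDeg, nBackgroundAssoc = nBg)
}

#' One-sided Fisher exact p-value for a clique against a gene set
#'
#' Builds the 2x2 table over the gene universe `N` (rows: gene mapped /
#' not mapped to a clique protein; columns: gene in `geneset` / not) and
#' returns the over-representation p-value, i.e. the hypergeometric upper
#' tail at the observed overlap.
#'
#' @param clique character vector of clique proteins.
#' @param geneset character vector of gene IDs (subset of the
#'   background).
#' @param genes a [GeneSets-class].
#' @return p-value in `(0, 1]`.
#' @export
fisherP <- function(clique, geneset, genes) {
    cg <- .cliqueGenes(clique, genes)
    geneset <- intersect(geneset, genes@background)
    .upperTail(sum(geneset %in% cg), length(cg),
               length(genes@background), length(geneset))
}

#' Permutation p-value of a clique (literal counting rule)
#'
#' The final clique p-value is the fraction of background samples whose
#' Fisher p-value is less than or equal to the observed one:
#' `p* = |{b in B : p_b <= p_D}| / |B|`. Ties count toward the
#' numerator; zero is attainable (resolution is `1/|B|`). Optional
#' add-one smoothing (`(x+1)/(|B|+1)`) is off by default.
#'
#' @param clique character vector of clique proteins.
#' @param genes a [GeneSets-class].
#' @param samples a [BackgroundSamples-class].
#' @param smooth logical; apply add-one smoothing (default `FALSE`).
#' @return p-value in `[0, 1]`.
#' @export
permutationP <- function(clique, genes, samples, smooth = FALSE) {
    if (!length(samples@sets)) stop("no background samples")
    cg <- .cliqueGenes(clique, genes)
    N <- length(genes@background)
    m <- length(cg)
    pD <- .upperTail(sum(genes@deg %in% cg), m, N, length(genes@deg))
    k <- vapply(samples@sets, function(b) sum(b %in% cg), 1L)
    pb <- .upperTail(k, m, N, length(samples@sets[[1L]]))
    x <- sum(pb <= pD)
    if (smooth) (x + 1) / (length(pb) + 1) else x / length(pb)
}

#' Test every unique clique of a collection for DEG enrichment
#'
#' Computes eligibility, the observed one-sided Fisher p-value and the
#' permutation p-value for each unique clique (multiplicity in the
#' collection does not affect p-values). Significance is
#' `eligible & perm_p < alpha` (strict). No multiple-testing correction
#' is applied by default, mirroring the raw p-value cutoff of the
#' procedure; `correct = "BH"` optionally adds a Benjamini-Hochberg
#' adjusted column and bases significance on it.
#'
#' @param collection a [CliqueCollection-class] (or list of cliques).
#' @param genes a [GeneSets-class].
#' @param samples a [BackgroundSamples-class].
#' @param alpha significance cutoff on the permutation p-value
#'   (default 0.01).
#' @param correct `"none"` (default) or `"BH"`.
#' @return data.frame with one row per unique clique: `clique`
#'   (';'-joined sorted protein IDs), `size`, `n_bg`, `n_deg`,
#'   `eligible`, `fisher_p`, `perm_p`, `significant` (p-values `NA` for
#'   ineligible cliques). The `alpha` used is kept as an attribute.
#' @export
testCliques <- function(collection, genes, samples, alpha = 0.01,
                        correct = c("none", "BH")) {
    correct <- match.arg(correct)
    cliques <- if (is(collection, "CliqueCollection"))
        uniqueCliques(collection) else collection
    if (!length(cliques)) stop("empty clique collection")
    if (!length(samples@sets)) stop("no background samples")
    assoc <- .proteinAssoc(genes)
    map <- genes@mapping
    bg <- genes@background
    N <- length(bg)
    D <- length(genes@deg)
    # sample membership as an index matrix into the background
    SM <- vapply(samples@sets, function(b) match(b, bg),
                 integer(length(samples@sets[[1L]])))
    SM <- matrix(SM, nrow = length(samples@sets[[1L]]))
    B <- ncol(SM)
    degIdx <- match(genes@deg, bg)
    n <- length(cliques)
    out <- data.frame(
        clique = vapply(cliques, .cliqueKey, ""),
        size = lengths(cliques),
        n_bg = integer(n), n_deg = integer(n),
        eligible = logical(n),
        fisher_p = rep(NA_real_, n), perm_p = rep(NA_real_, n),
        stringsAsFactors = FALSE)
    inBg <- logical(N)
    for (i in seq_len(n)) {
        cq <- cliques[[i]]
        out$n_deg[i] <- sum(cq %in% assoc$deg)
        out$n_bg[i] <- sum(cq %in% assoc$bg)
        eligible <- out$n_deg[i] >= 1L && 2L * out$n_bg[i] >= length(cq)
        out$eligible[i] <- eligible
        if (!eligible) next
        cgIdx <- match(.cliqueGenes(cq, genes), bg)
        inBg[] <- FALSE
        inBg[cgIdx] <- TRUE
        m <- length(cgIdx)
        pD <- .upperTail(sum(inBg[degIdx]), m, N, D)
        k <- colSums(matrix(inBg[SM], nrow = nrow(SM)))
        pb <- .upperTail(k, m, N, nrow(SM))
        out$fisher_p[i] <- pD
        out$perm_p[i] <- sum(pb <= pD) / B
    }
    if (correct == "BH") {
        out$perm_p_bh <- NA_real_
        out$perm_p_bh[out$eligible] <-
            stats::p.adjust(out$perm_p[out$eligible], method = "BH")
        out$significant <- out$eligible & !is.na(out$perm_p_bh) &
            out$perm_p_bh < alpha
    } else {
        out$significant <- out$eligible & !is.na(out$perm_p) &
            out$perm_p < alpha
    }
    attr(out, "alpha") <- alpha
    attr(out, "nSamples") <- B
    out
}

#' Write / read a clique test table as TSV
#'
#' @param results data.frame from [testCliques()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeCliqueTests <- function(results, path) {
    utils::write.table(results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeCliqueTests
#' @export
readCliqueTests <- function(path) {
    utils::read.table(path, sep = "\t", header = TRUE,
                      colClasses = NA, stringsAsFactors = FALSE)
}
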