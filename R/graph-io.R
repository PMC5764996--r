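#' Read a STRING-style protein links file into a ProteinNetwork
#'
#' Parses a whitespace- or tab-delimited file with at least three columns
#' (`protein1`, `protein2`, `combined_score`; a header line is optional)
#' and returns the network of edges whose score strictly exceeds
#' `cutoff`. STRING distributes combined scores as integers in 0-999
#' (milli-units); `scale = "auto"` inspects the maximum raw score and
#' divides by 1000 when it exceeds 1, so "score > 0.7" retains raw
#' scores > 700.
#'
#' @param path path to the links file.
#' @param cutoff numeric in `[0,1]`; edges must exceed it strictly.
#'   Default 0.7, the usual high-confidence setting.
#' @param scale one of `"auto"`, `"unit"` (scores already in `[0,1]`) or
#'   `"milli"` (raw scores divided by 1000).
#' @return A [ProteinNetwork-class]. Self-loops are dropped and symmetric
#'   duplicate pairs collapsed (maximum score kept). An empty result
#'   after filtering raises a warning, not an error.
#' @examples
#' f <- tempfile()
#' writeLines(c("protein1 protein2 combined_score",
#'              "a b 900", "b c 500"), f)
#' readStringLinks(f, cutoff = 0.7)
#' @export
readStringLinks <- function(path, cutoff = 0.7,
                            scale = c("auto", "unit", "milli")) {
    scale <- match.arg(scale)
    stopifnot(cutoff >= 0, cutoff <= 1)
    lines <- readLines(path)
    keep <- nzchar(trimws(lines))
    lineno <- which(keep)
    toks <- strsplit(trimws(lines[keep]), "[ \t]+")
    if (length(toks) &&
        (length(toks[[1L]]) < 3L ||
         is.na(suppressWarnings(as.numeric(toks[[1L]][3L]))))) {
        toks <- toks[-1L]       # header line
        lineno <- lineno[-1L]
    }
    if (!length(toks)) {
        warning("no interactions in '", path, "'")
        return(ProteinNetwork(NULL, cutoff = cutoff))
    }
    nf <- lengths(toks)
    if (any(nf < 3L))
        stop("malformed line ", lineno[which(nf < 3L)[1L]], " in '", path,
             "': fewer than 3 fields")
    a <- vapply(toks, `[[`, "", 1L)
    b <- vapply(toks, `[[`, "", 2L)
    s <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 3L)))
    if (anyNA(s))
        stop("malformed line ", lineno[which(is.na(s))[1L]], " in '", path,
             "': non-numeric score")
    if (scale == "milli" || (scale == "auto" && max(s) > 1)) s <- s / 1000
    pn <- ProteinNetwork(data.frame(from = a, to = b, score = s,
                                    stringsAsFactors = FALSE))
    e <- pn@edges[pn@edges$score > cutoff, , drop = FALSE]
    if (nrow(e) == 0L)
        warning("network is empty after filtering at score > ", cutoff)
    rownames(e) <- NULL
    ProteinNetwork(e, cutoff = cutoff)
}

#' Write a ProteinNetwork as a STRING-style links file
#'
#' @param ppin a [ProteinNetwork-class].
#' @param path output path. Scores are written in unit scale, one
#'   canonical edge per line, with the standard three-column header.
#' @return invisibly, `path`.
#' @export
writeStringLinks <- function(ppin, path) {
    e <- ppin@edges
    lines <- c("protein1 protein2 combined_score",
               if (nrow(e)) paste(e$from, e$to, format(e$score, trim = TRUE)))
    writeLines(lines, path)
    invisible(path)
}

#' Read DEG and background gene lists (plus optional ID mapping)
#'
#' Gene list files carry one identifier per line. DEGs outside the
#' background are reported and dropped (the enrichment tests are
#' restricted to the measured background). Without a mapping file the
#' gene-to-protein mapping is the identity.
#'
#' @param degPath path to the DEG list (must be non-empty).
#' @param backgroundPath path to the background list.
#' @param mappingPath optional path to a two-column TSV (gene, protein).
#' @return A [GeneSets-class].
#' @export
readGeneSets <- function(degPath, backgroundPath, mappingPath = NULL) {
    readIds <- function(p) {
        x <- trimws(readLines(p))
        unique(x[nzchar(x)])
    }
    deg <- readIds(degPath)
    if (!length(deg)) stop("empty DEG list: '", degPath, "'")
    background <- readIds(backgroundPath)
    mapping <- NULL
    if (!is.null(mappingPath)) {
        mapping <- utils::read.table(mappingPath, sep = "\t",
                                     header = FALSE, comment.char = "",
                                     quote = "",
                                     col.names = c("gene", "protein"),
                                     colClasses = "character")
    }
    GeneSets(deg = deg, background = background, mapping = mapping)
}

#' Write a regulatory module to disk
#'
#' @param module a [RegulatoryModule-class].
#' @param path output path.
#' @param format `"sif"` (lines `a pp b`), `"edgelist"` (tab-separated
#'   pairs), `"graphml"` (via igraph, with node annotations), or
#'   `"tsv-nodes"` (node table with columns `protein`,
#'   `is_deg_associated`, `is_background_associated`, `submodule_id`).
#' @return invisibly, `path`.
#' @export
writeModule <- function(module, path,
                        format = c("sif", "edgelist", "graphml",
                                   "tsv-nodes")) {
    format <- match.arg(format)
    e <- module@edges
    if (format == "sif") {
        writeLines(if (nrow(e)) paste(e$from, "pp", e$to) else character(0),
                   path)
    } else if (format == "edgelist") {
        writeLines(if (nrow(e)) paste(e$from, e$to, sep = "\t")
                   else character(0), path)
    } else if (format == "graphml") {
        g <- .moduleIgraph(module)
        ann <- module@annotations
        if (nrow(ann)) {
            i <- match(igraph::V(g)$name, ann$protein)
            igraph::V(g)$is_deg_associated <- as.integer(ann$is_deg_associated[i])
            igraph::V(g)$is_background_associated <-
                as.integer(ann$is_background_associated[i])
        }
        if (length(module@submodules))
            igraph::V(g)$submodule_id <-
                unname(module@submodules[igraph::V(g)$name])
        igraph::write_graph(g, path, format = "graphml")
    } else {  # tsv-nodes
        sub <- module@submodules
        tab <- data.frame(
            protein = module@nodes,
            is_deg_associated = logical(length(module@nodes)),
            is_background_associated = logical(length(module@nodes)),
            submodule_id = if (length(sub)) unname(sub[module@nodes])
                           else rep(NA_integer_, length(module@nodes)),
            stringsAsFactors = FALSE)
        ann <- module@annotations
        if (nrow(ann)) {
            i <- match(tab$protein, ann$protein)
            tab$is_deg_associated <- ann$is_deg_associated[i]
            tab$is_background_associated <- ann$is_background_associated[i]
        }
        utils::write.table(tab, path, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}

#' Read a module graph back from disk
#'
#' Reconstructs the node and edge sets from a `sif`, `edgelist` or
#' `graphml` file written by [writeModule()]. Annotations are restored
#' only from GraphML (the other formats do not encode them).
#'
#' @param path input path.
#' @param format one of `"sif"`, `"edgelist"`, `"graphml"`.
#' @return A [RegulatoryModule-class] (annotations empty unless GraphML).
#' @export
readModule <- function(path, format = c("sif", "edgelist", "graphml")) {
    format <- match.arg(format)
    emptyAnn <- data.frame(protein = character(0),
                           is_deg_associated = logical(0),
                           is_background_associated = logical(0),
                           stringsAsFactors = FALSE)
    if (format == "graphml") {
        g <- igraph::read_graph(path, format = "graphml")
        el <- igraph::as_edgelist(g)
        ann <- emptyAnn
        va <- igraph::vertex_attr(g)
        if (all(c("is_deg_associated", "is_background_associated") %in%
                names(va))) {
            ann <- data.frame(protein = va$name,
                              is_deg_associated = as.logical(va$is_deg_associated),
                              is_background_associated =
                                  as.logical(va$is_background_associated),
                              stringsAsFactors = FALSE)
        }
        sub <- integer(0)
        if ("submodule_id" %in% names(va)) {
            sub <- as.integer(va$submodule_id)
            names(sub) <- va$name
        }
        return(.newModule(igraph::V(g)$name,
                          data.frame(from = el[, 1L], to = el[, 2L],
                                     stringsAsFactors = FALSE),
                          ann, submodules = sub))
    }
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines))
        return(.newModule(character(0), NULL, emptyAnn))
    toks <- strsplit(trimws(lines), "[ \t]+")
    if (format == "sif") {
        bad <- which(lengths(toks) != 3L)
        if (length(bad)) stop("malformed SIF line ", bad[1L])
        from <- vapply(toks, `[[`, "", 1L)
        to <- vapply(toks, `[[`, "", 3L)
    } else {
        bad <- which(lengths(toks) < 2L)
        if (length(bad)) stop("malformed edge-list line ", bad[1L])
        from <- vapply(toks, `[[`, "", 1L)
        to <- vapply(toks, `[[`, "", 2L)
    }
    .newModule(c(from, to),
               data.frame(from = from, to = to, stringsAsFactors = FALSE),
               emptyAnn)
}

#' Write / read an enumerated clique collection as TSV
#'
#' One clique per line: the iteration index, a tab, then the
#' tab-separated protein IDs. A leading comment line records the total
#' iteration count and seeds per iteration so that bootstrap resampling
#' of iterations remains possible after a round-trip.
#'
#' @param collection a [CliqueCollection-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeCliques <- function(collection, path) {
    hdr <- sprintf("# iterations=%d seeds=%d",
                   collection@nIterations, collection@nSeeds)
    body <- vapply(seq_along(collection@cliques), function(i) {
        paste(c(collection@iteration[i], collection@cliques[[i]]),
              collapse = "\t")
    }, "")
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' @rdname writeCliques
#' @export
readCliques <- function(path) {
    lines <- readLines(path)
    nIter <- NA_integer_
    nSeeds <- 1L
    if (length(lines) && startsWith(lines[1L], "#")) {
        m <- regmatches(lines[1L],
                        regexec("iterations=(\\d+) seeds=(\\d+)", lines[1L]))[[1L]]
        if (length(m) == 3L) {
            nIter <- as.integer(m[2L])
            nSeeds <- as.integer(m[3L])
        }
        lines <- lines[-1L]
    }
    lines <- lines[nzchar(trimws(lines))]
    toks <- strsplit(lines, "\t", fixed = TRUE)
    iter <- vapply(toks, function(t) as.integer(t[1L]), 1L)
    cl <- lapply(toks, function(t) sort(t[-1L]))
    if (is.na(nIter)) nIter <- if (length(iter)) max(iter) else 0L
    new("CliqueCollection", cliques = cl, iteration = iter,
        nIterations = nIter, nSeeds = nSeeds)
}

# igraph views -------------------------------------------------------------

.ppinIgraph <- function(ppin) {
    igraph::graph_from_data_frame(ppin@edges[, c("from", "to")],
                                  directed = FALSE,
                                  vertices = ppin@nodes)
}

.moduleIgraph <- function(module) {
    igraph::graph_from_data_frame(module@edges, directed = FALSE,
                                  vertices = module@nodes)
}

# Logical adjacency matrix of a ProteinNetwork (dense; enumeration-scale
# networks in this package are small enough for this to be the fastest
# representation for the per-iteration overlay).
.ppinAdjacency <- function(ppin) {
    n <- length(ppin@nodes)
    adj <- matrix(FALSE, n, n, dimnames = list(ppin@nodes, ppin@nodes))
    if (nrow(ppin@edges)) {
        i <- match(ppin@edges$from, ppin@nodes)
        j <- match(ppin@edges$to, ppin@nodes)
        adj[cbind(i, j)] <- TRUE
        adj[cbind(j, i)] <- TRUE
    }
    adj
}
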