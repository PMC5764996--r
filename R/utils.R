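# Internal helpers shared across modules.

# Canonicalize unordered protein pairs: from < to lexicographically.
.canonPairs <- function(a, b) {
    a <- as.character(a)
    b <- as.character(b)
    swap <- a > b
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
    data.frame(from = a, to = b, stringsAsFactors = FALSE)
}

.edgeKeys <- function(edges) {
    if (nrow(edges) == 0L) return(character(0))
    paste(edges$from, edges$to, sep = "\r")
}

# All unordered pairs within a node set, canonicalized.
.pairsWithin <- function(nodes) {
    nodes <- sort(unique(as.character(nodes)))
    if (length(nodes) < 2L) {
        return(data.frame(from = character(0), to = character(0),
                          stringsAsFactors = FALSE))
    }
    idx <- utils::combn(length(nodes), 2L)
    data.frame(from = nodes[idx[1L, ]], to = nodes[idx[2L, ]],
               stringsAsFactors = FALSE)
}

# Evaluate `code` under a temporary RNG seed; NULL means use the current
# RNG stream unchanged.
.withSeed <- function(seed, code) {
    if (is.null(seed)) return(force(code))
    withr::with_seed(as.integer(seed), code)
}

# Canonical string key for a clique (sorted, ';'-joined protein IDs).
.cliqueKey <- function(proteins) {
    paste(sort(as.character(proteins)), collapse = ";")
}

.splitCliqueKey <- function(key) strsplit(key, ";", fixed = TRUE)
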