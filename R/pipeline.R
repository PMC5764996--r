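# End-to-end pipeline: enumerate -> test -> assemble -> stability,
# with a validated configuration, derived per-stage RNG seeds and a run
# manifest for reproducibility.

#' Build a validated pipeline configuration
#'
#' Defaults mirror the published full-scale settings: score cutoff 0.7,
#' 10,000 background samples, significance cutoff 0.01, 100 bootstrap
#' samples. Iteration counts are analysis-specific and must be supplied.
#'
#' @param ppin path to a STRING-style links file.
#' @param deg,background paths to gene list files.
#' @param mapping optional path to a gene-protein mapping TSV.
#' @param outDir output directory (created if missing).
#' @param scoreCutoff edge confidence cutoff (strict `>`), default 0.7.
#' @param scoreScale `"auto"`, `"unit"` or `"milli"`.
#' @param iterations number of enumeration iterations.
#' @param nSeeds seed proteins per iteration (1 = single-seed).
#' @param nSamples number of background gene sets, default 10000.
#' @param alpha significance cutoff on the permutation p-value,
#'   default 0.01.
#' @param nBootstrap bootstrap samples for the stability assessment
#'   (0 disables it), default 100.
#' @param induced assemble the module with PPIN-induced edges.
#' @param seed master RNG seed; per-stage child seeds are derived from
#'   it deterministically so stages are independently reproducible.
#' @return a validated configuration (class `RunConfig`, a list).
#' @export
runConfig <- function(ppin, deg, background, mapping = NULL,
                      outDir = ".", scoreCutoff = 0.7,
                      scoreScale = "auto", iterations = 10000L,
                      nSeeds = 1L, nSamples = 10000L, alpha = 0.01,
                      nBootstrap = 100L, induced = FALSE, seed = 1L) {
    cfg <- list(ppin = ppin, deg = deg, background = background,
                mapping = mapping, outDir = outDir,
                scoreCutoff = as.numeric(scoreCutoff),
                scoreScale = match.arg(scoreScale,
                                       c("auto", "unit", "milli")),
                iterations = as.integer(iterations),
                nSeeds = as.integer(nSeeds),
                nSamples = as.integer(nSamples),
                alpha = as.numeric(alpha),
                nBootstrap = as.integer(nBootstrap),
                induced = isTRUE(induced), seed = as.integer(seed))
    stopifnot(cfg$scoreCutoff >= 0, cfg$scoreCutoff <= 1,
              cfg$iterations >= 1L, cfg$nSeeds >= 1L, cfg$nSamples >= 1L,
              cfg$alpha > 0, cfg$alpha <= 1, cfg$nBootstrap >= 0L)
    for (p in c(cfg$ppin, cfg$deg, cfg$background, cfg$mapping)) {
        if (!file.exists(p)) stop("input file not found: '", p, "'")
    }
    class(cfg) <- "RunConfig"
    cfg
}

#' Read a pipeline configuration from YAML
#'
#' YAML keys mirror the arguments of [runConfig()]; `overrides` (a named
#' list, e.g. from command-line flags) take precedence.
#'
#' @param path path to a YAML file.
#' @param overrides named list of values overriding the file.
#' @return a validated `RunConfig`.
#' @export
readRunConfig <- function(path, overrides = list()) {
    vals <- yaml::read_yaml(path)
    vals[names(overrides)] <- overrides
    do.call(runConfig, vals)
}

# Derive a per-stage child seed from the master seed (kept within the
# 32-bit integer range).
.childSeed <- function(seed, stage) {
    offsets <- c(enumerate = 1L, samples = 2L, bootstrap = 3L)
    (as.integer(seed) + 99991L * offsets[[stage]]) %% .Machine$integer.max
}

# Write an artifact atomically: the writer targets <path>.partial which
# is renamed on success, so a failed stage leaves only a .partial file.
.writeArtifact <- function(path, writer) {
    partial <- paste0(path, ".partial")
    writer(partial)
    file.rename(partial, path)
    invisible(path)
}

#' Run the full module-identification pipeline
#'
#' Chains enumeration (Step I), clique enrichment testing (Step II),
#' module assembly with sub-module detection and module-level enrichment
#' (Step III) and the bootstrap stability assessment, writing
#' `cliques.tsv`, `clique_tests.tsv`, `module.sif`, `module_nodes.tsv`,
#' `stability.tsv` and a JSON run manifest into the output directory.
#' Outputs are byte-identical for identical configurations.
#'
#' @param config a `RunConfig` from [runConfig()] or [readRunConfig()].
#' @return invisibly, a list with the in-memory results (`collection`,
#'   `tests`, `module`, `stability`, `paths`).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "RunConfig"))
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    out <- function(f) file.path(config$outDir, f)

    ppin <- readStringLinks(config$ppin, cutoff = config$scoreCutoff,
                            scale = config$scoreScale)
    genes <- readGeneSets(config$deg, config$background, config$mapping)
    message("PPIN: ", length(networkNodes(ppin)), " proteins, ",
            nrow(networkEdges(ppin)), " relations; ",
            length(degGenes(genes)), " DEGs / ",
            length(backgroundGenes(genes)), " background genes")

    collection <- enumerateCliques(ppin, iterations = config$iterations,
                                   nSeeds = config$nSeeds,
                                   seed = .childSeed(config$seed,
                                                     "enumerate"))
    .writeArtifact(out("cliques.tsv"),
                   function(p) writeCliques(collection, p))
    message("enumerated ", length(collection@cliques), " cliques (",
            length(uniqueCliques(collection)), " unique)")

    samples <- sampleBackgrounds(genes, nSamples = config$nSamples,
                                 seed = .childSeed(config$seed,
                                                   "samples"))
    tests <- testCliques(collection, genes, samples,
                         alpha = config$alpha)
    .writeArtifact(out("clique_tests.tsv"),
                   function(p) writeCliqueTests(tests, p))
    message(sum(tests$significant), " of ", nrow(tests),
            " unique cliques significant at alpha = ", config$alpha)

    module <- assembleModule(tests, ppin, genes, alpha = config$alpha,
                             induced = config$induced)
    if (length(moduleNodes(module))) {
        module <- detectSubmodules(module)
        module@modP <- moduleEnrichmentP(module, genes, samples)
    }
    .writeArtifact(out("module.sif"),
                   function(p) writeModule(module, p, format = "sif"))
    .writeArtifact(out("module_nodes.tsv"),
                   function(p) writeModule(module, p,
                                           format = "tsv-nodes"))

    stab <- NULL
    if (config$nBootstrap >= 2L && length(moduleNodes(module))) {
        boots <- bootstrapModules(collection, ppin, genes, samples,
                                  alpha = config$alpha,
                                  nBootstrap = config$nBootstrap,
                                  seed = .childSeed(config$seed,
                                                    "bootstrap"))
        stab <- stabilityReport(boots)
        .writeArtifact(out("stability.tsv"),
                       function(p) writeStability(stab, p))
    }

    manifest <- list(
        package = as.character(utils::packageVersion("cliqueModules")),
        r_version = paste(R.version$major, R.version$minor, sep = "."),
        config = unclass(config),
        child_seeds = list(
            enumerate = .childSeed(config$seed, "enumerate"),
            samples = .childSeed(config$seed, "samples"),
            bootstrap = .childSeed(config$seed, "bootstrap")))
    .writeArtifact(out("manifest.json"), function(p)
        jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                             pretty = TRUE))

    invisible(list(collection = collection, tests = tests,
                   module = module, stability = stab,
                   paths = vapply(c("cliques.tsv", "clique_tests.tsv",
                                    "module.sif", "module_nodes.tsv",
                                    "manifest.json"), out, "")))
}
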