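---
title: "Identifying regulatory modules in PPINs by randomized clique enumeration"
author: "cliqueModules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying regulatory modules in PPINs by randomized clique enumeration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliqueModules)
```

## The problem and the model

Disease- and phenotype-associated modules are sub-networks of a
protein-protein interaction network (PPIN) enriched with
phenotype-relevant proteins, typically proteins whose genes are
differentially expressed. One established route decomposes the PPIN into
its maximal cliques — fully interconnected protein groups, the tightest
form of topological community — and defines the module as the union of
the cliques significantly enriched with differentially expressed genes
(DEGs). Exact maximal clique enumeration (MCE) is NP-hard, which makes
this route impractical for genome-scale PPINs with hundreds of thousands
of high-confidence edges.

This package implements a randomization heuristic that approximates the
clique-based community structure instead of enumerating it exactly, and
then carries out the enrichment testing, module assembly, sub-module
detection and bootstrap stability assessment around it.

## Step I: randomized clique enumeration

One *iteration* has three phases, carried out on a transformed
representation of the PPIN:

1. **Transformation.** Each protein becomes a vertex of a labeled graph;
   each PPIN edge becomes an edge of weight 1. The weight of an edge
   always counts the number of PPIN relations between the two vertices'
   protein label sets, so after merging, a weight equal to the product of
   the two label-set sizes certifies that the two label sets are fully
   interconnected — exactly the condition under which their union is
   again a clique.
2. **Minimal cliques.** From each randomly chosen seed protein the
   algorithm searches the seed's neighborhood in random order for a
   triangle of available singleton vertices; the first one found is
   merged into a clique vertex. A seed without a triangle is dropped.
3. **Extension.** Clique vertices are processed round-robin in a freshly
   shuffled order; in each visit a clique vertex merges with one
   uniformly chosen fully interconnected neighbor (an unconsumed
   singleton, or another clique vertex of the same iteration). The pass
   loop ends after a full pass without a merge. Consumed proteins never
   migrate between cliques — cliques *compete* for nodes — but two clique
   vertices that are fully interconnected may fuse.

With a single seed per iteration every emitted clique is maximal in the
PPIN, and repeating the iteration converges on the exact maximal-clique
set (the package ships `mceOracle()`, an exact Bron–Kerbosch reference,
to verify this on small graphs). With several competing seeds per
iteration large maximal cliques are broken into smaller valid cliques,
which lets proteins that only occur in small cliques reach the final
module at the cost of admitting non-maximal cliques.

`transformNetwork()`, `mergeVertices()`, `findMinimalClique()` and
`extendCliques()` expose the labeled-graph mechanics with full weight
bookkeeping; `runIteration()` and `enumerateCliques()` run the same
procedure on an immutable adjacency matrix with a per-iteration overlay,
which is observably equivalent to rebuilding the labeled graph each
iteration and far cheaper. The equivalence is asserted in the test suite
by recounting weights and by checking both paths on the worked example.

## Step II: enrichment testing

Let $N$ be the background — all genes measured on the expression
platform — and $D \subseteq N$ the DEG set. A collection $B$ of random
gene sets is drawn, each of size $|D|$, uniformly without replacement
from $N$ (`sampleBackgrounds()`; the full-scale default is
$|B| = 10{,}000$). For a clique $c_i$, $p_{i,D}$ is the one-sided
(over-representation) Fisher exact p-value of the $2\times2$ table over
the gene universe $N$ — gene mapped / not mapped to a clique protein
versus gene in $D$ / not — computed as the hypergeometric upper tail at
the observed overlap. The permutation p-value is the literal counting
rule

$$p_i^\ast = \frac{\left|\{\, b \in B : p_{i,b} \le p_{i,D} \,\}\right|}{|B|},$$

with ties counting toward the numerator and 0 attainable (resolution
$1/|B|$; a zero is logged as $< 1/|B|$). Optional add-one smoothing is
available behind a flag but off by default because the counting rule is
the definition. A clique is *eligible* for testing only if at least one
of its proteins is associated to a DEG and at least half of its proteins
are associated to background genes; eligibility is decided at protein
level (a protein is associated iff at least one gene mapping to it is in
the respective set), while the Fisher table is counted at gene level.
This distinction matters with many-to-many gene-protein mappings: the
eligibility rules quantify over proteins, whereas $D$ and $N$ are gene
sets, so the sampling universe of the permutation test must be genes.
Significance is `eligible & perm_p < alpha` (strict), with a raw cutoff
(default `alpha = 0.01`) and no multiple-testing correction by default;
Benjamini–Hochberg is available as an option.

## Step III: module assembly and analysis

The regulatory module is the union of all significant cliques: node set
the union of their proteins, edge set the union of their within-clique
pairs. The alternative — the PPIN-induced subgraph on the module nodes —
is available via `induced = TRUE`; the clique-union default is the
stricter reading of "union of cliques", since an induced edge between two
proteins that never co-occurred in a significant clique is not attested
by any enriched community. Module-level enrichment is a permutation test
of the count of DEG-associated module proteins against the same
background samples. Sub-modules are detected by divisive edge-betweenness
(Girvan–Newman) clustering with the dendrogram cut at maximum modularity
on unit edge weights, via igraph; the procedure is deterministic, and
sub-modules always refine the connected components.

## Bootstrap stability

The exact community structure is unknown, so approximation quality is
assessed indirectly: bootstrap samples of the $n$ enumeration iterations
(drawn with replacement, size $n$) are pooled, re-deduplicated,
re-thresholded and re-assembled into modules. The distance between two
modules is the node symmetric difference plus the edge symmetric
difference, equally weighted (the simplest metric on the "shared nodes
and edges" comparison; node/edge weighting is a free choice and equal
weights are used throughout). The *variability* statistic is the median
pairwise distance divided by the mean of $|V| + |E|$ over the bootstrap
modules: 0 iff every bootstrap reproduces the identical module.
Background samples are held fixed across bootstraps so the statistic
reflects clique-sampling variability only, and per-clique p-values are
computed once per unique clique (multiplicity cannot change them).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 0.7 | edge confidence filter, strict `>`; STRING-style integer scores are auto-detected and divided by 1000 |
| `iterations` | analysis-specific | enumeration iterations; genome-scale runs use millions (e.g. 2,000,000 single-seed, or 1,020,000 with 25 seeds), desk-scale graphs saturate at thousands |
| `nSeeds` | 1 | seeds per iteration; 1 reproduces MCE-like modules, >1 adds small-clique proteins at the cost of non-maximal cliques |
| `nSamples` | 10,000 | background sets $|B|$; the resolution of $p^\ast$ is $1/|B|$, so `alpha = 0.01` needs $|B| \gg 100$ |
| `alpha` | 0.01 | strict cutoff on $p^\ast$ |
| `nBootstrap` | 100 | bootstrap modules for the stability report |

Because enumeration has no intrinsic stopping rule, `enumerateCliques()`
can log unique-clique saturation (new unique cliques per block) via
`progressEvery`, which is the practical convergence diagnostic: when new
iterations stop producing new unique cliques, additional iterations
cannot change the module, and the bootstrap variability confirms it.

## The synthetic generator

`generatePlanted()` emulates the structure the method assumes: planted
cliques wired as complete subgraphs (consecutive cliques sharing
`overlap` proteins), sparse noise edges added between all other pairs
with a rejection step that discards any edge that would enlarge a
planted clique (keeping the ground truth well-defined), genes mapped 1:1
to proteins (a many-to-many scrambler exercises the mapping path), and
DEG status drawn per gene — probability `degFracInside` in enriched
cliques, `degFracOutside` elsewhere. The defaults (4 cliques of size 6,
overlap 1, 200 background proteins, noise probability 0.01, 2 enriched
cliques at 0.8 vs 0.02) give a clear planted effect at a scale where a
few hundred iterations saturate; the null calibration design sets both
fractions to 0.1 so that eligible cliques arise while no enrichment
exists. What the generator does *not* emulate: the degree heterogeneity,
clique-size distribution and annotation incompleteness of real
interactomes, correlated differential expression along pathways, and
many-to-many ID mappings with missing entries. Passing tests on planted
data therefore demonstrate correctness of the machinery and calibration
of the statistics, not performance guarantees on real PPINs.

## Numerical and design choices

- The Fisher p-value is computed directly as the hypergeometric upper
  tail (`phyper`), which is exact and fast; equality with
  `fisher.test(alternative = "greater")` is asserted in the tests.
- Ties $p_{i,b} = p_{i,D}$ arise from identical overlap counts and are
  counted as "at least as extreme", per the `<=` in the counting rule.
- Degenerate inputs: an empty DEG list is an error; an empty network
  after score filtering is a warning; a module with no significant clique
  is an empty module with a warning; a bootstrap set of entirely empty
  modules makes the variability denominator undefined and is an error.
- Edge-betweenness tie-breaking follows igraph's deterministic internal
  order; determinism is the requirement, the specific tie order is not.
- Worked-example scale: the test suite validates the heuristic against
  the exact oracle on 50 random graphs of 12–20 nodes (10,000 iterations
  each) and runs the planted designs at 250–3,000 iterations with
  $|B| = 1{,}000$; these sizes saturate the small graphs and keep the
  suite fast. Full-scale counts reported for genome-wide analyses
  (hundreds of thousands of unique cliques from millions of iterations)
  require the same calls with larger `iterations`/`nSamples` and are a
  recipe, not a test.

## Known limitations

- The heuristic samples maximal cliques non-uniformly (seed choice
  favors cliques that many seeds lead to), so unique-clique counts are
  approximations from below until saturation.
- With `nSeeds > 1` the emitted clique set depends on seed interleaving;
  only validity and disjointness within an iteration are guaranteed.
- The permutation p-value inherits Monte-Carlo noise of order
  $\sqrt{p(1-p)/|B|}$; ranking of near-tied cliques can flip between
  runs with different sampling seeds.
- Eligibility conditions on having at least one DEG-associated protein,
  which slightly biases the eligible-clique population toward enrichment;
  calibration under the null is therefore checked empirically (the
  observed false-positive fraction at 0.05 stays below 0.08 on the null
  design) rather than assumed.

## A minimal session

```{r example, eval = FALSE}
sim <- generatePlanted(plantedDesign(), seed = 7)
cc <- enumerateCliques(sim$network, iterations = 600, seed = 7)
samples <- sampleBackgrounds(sim$genes, nSamples = 1000, seed = 7)
res <- testCliques(cc, sim$genes, samples, alpha = 0.01)
mod <- assembleModule(res, sim$network, sim$genes)
mod <- detectSubmodules(mod)
moduleEnrichmentP(mod, sim$genes, samples)
variability(stabilityReport(bootstrapModules(
    cc, sim$network, sim$genes, samples, nBootstrap = 100, seed = 1)))
```
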