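---
title: "Topological modules from multi-layer molecular networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological modules from multi-layer molecular networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifmodules)
library(dplyr)
```

## The problem

Integrated molecular networks combine several interaction types over a
shared gene space: directed regulatory layers (transcription factor to
target, miRNA to mRNA) and undirected layers (protein-protein, co-functional,
homology). Treated as a single graph they form an uninterpretable hairball;
treated layer by layer they lose the cross-layer regulatory structure that
makes them interesting. `motifmodules` decomposes such a composite network
into its smallest multi-layer building blocks — typed two- and three-node
subgraphs — and reassembles those blocks into small (5–50 node) modules
that share a topological character, then re-embeds the modules in their
network context with statistics for module–module connectivity, regulators,
functional annotation, expression coherence and condition-specific
activity.

## Composite subgraphs

Every three-node subgraph is a triangle carrying one typed edge per node
pair. It is written as a three-letter code over the edge slots (1–2),
(1–3), (2–3); a lowercase letter marks a directed edge running against the
slot order. Codes related by a relabelling of the three nodes describe the
same object (PPC, PCP and CPP collapse to one class), so the catalogue
holds one canonical representative per isomorphism class — we take the
bytewise-smallest code over the six node permutations. Any internally
consistent canonicalisation would do, since only class identity matters
downstream; bytewise comparison keeps the choice independent of the session
locale.

Each class belongs to one of seven three-node topological types, defined by
the direction pattern alone: COM (three undirected edges), COP (two edges
converging on a target, regulators linked by an undirected edge), COR (one
regulator controlling two interacting targets), FFL (transitive directed
triangle), CIR (directed three-cycle), FBU (directed cascade closed by an
undirected edge) and FB2U (one directed, two undirected). Two-node
subgraphs add 2FB (a directed and an undirected edge on the same pair) and
DD (antiparallel directed edges). DD instances take part only in the joint
(`ALL`) clustering pool, since no DD-specific module family is defined;
2FB instances get their own pool and the joint pool.

Enumeration is non-induced: a triple carrying extra edges still matches
every code its edges contain, and one triple contributes one instance per
distinct choice of one concrete edge per pair. The implementation lists
triangles of the layer-union support graph and expands the per-pair edge
choices; its contract is exact agreement with brute force over all node
triples and pairs, which the test suite and the acceptance script verify on
hundreds of random networks.

Self-loops are rejected on load (three-node codes assume distinct nodes;
the dropped count is reported), and undirected edges are stored with the
bytewise-smaller endpoint first so that A–B and B–A merge.

## Hypergraph clustering

Each subgraph instance becomes a hyperedge (weight 1) over its nodes.
Clusters are extracted iteratively; the objective for a candidate node set
$S$ is its edge-to-node ratio

$$ r(S) = \frac{\sum_{e \subseteq S} w_e}{|S|}. $$

Each round first runs a nonlinear power iteration,
$x_i \leftarrow \sum_{e \ni i} w_e \prod_{j \in e,\, j \ne i} x_j^{p}$,
renormalised until the sup-norm change falls below `tol`, giving a score
vector whose large entries mark densely co-covered nodes. We use the
reference exponent $p = 1$, `tol = 1e-9` and `max_iter = 1000` (standard
power-iteration practice), a deterministic uniform start, and a 0.5 damping
step — the undamped multiplicative update can enter a period-2 oscillation
on asymmetric hypergraphs; damping preserves the fixed points and restores
convergence. If the iteration still has not converged after `max_iter`
steps the last iterate is used, with a warning.

Nodes are then sorted by descending score (ties broken bytewise by
identifier so output is order-stable) and the prefix maximising $r$ is
located. Because a score-order prefix is not guaranteed to be the global
maximiser of $r$ — on random small hypergraphs it misses in roughly 6% of
instances, and restarts do not help since the iteration has a unique fixed
point — the selected prefix is refined to the exact maximum-ratio subset by
parametric min-cut: a ratio $g$ is attainable iff
$\max_S (w(S) - g\,|S|) > 0$, which a min-cut on the bipartite
source→hyperedge→node→sink network decides, and a binary search on $g$
(warm-started at the prefix ratio) pins the optimum. This keeps the
spectral machinery as the fast path and guarantees the algorithm's defining
property: each extracted cluster attains the exhaustive-search maximum
edge-to-node ratio over the remaining hyperedges. The cluster's hyperedges
are removed and extraction repeats until none remain, so every hyperedge is
assigned to exactly one cluster while nodes may recur across clusters.

Clusters are filtered into modules: 5–50 nodes (counting every node,
including miRNAs and TFs — the census of real runs includes miRNA-bearing
modules, so no node class is exempt), and clusters whose induced internal
edges are more than 90% homologous are dropped (strictly greater than 0.9;
a 9-of-10 homology fraction survives). Survivors are named
`<TYPE>_<index>` in extraction order. A module's internal edges are
defined as all network edges among its nodes (the induced set, a superset
of its member subgraphs' edges); the induced convention makes the homology
filter, the expression-coverage figures and the Cytoscape export agree with
what a user sees when they load the module's neighbourhood.

## Superview statistics

For every unordered module pair and layer, the observed number of edges
with one endpoint in each module (directions pooled, each edge counted
once, edges within the overlap included) is compared against a sampling
null: 1000 draws of two disjoint uniform node sets of the same sizes.
Disjoint sampling mirrors the typical disjointness of observed module
pairs. The z-score is $(x - \mu)/\sigma$ with a right-tail normal p-value;
an observed count of zero is reported as $(z, p) = (0, 1)$ by convention,
and a degenerate null ($\sigma = 0$, e.g. a complete or empty layer) caps
the z-score at $10^6$ so records stay serialisable. Null moments depend
only on the two set sizes, so they are computed once per distinct size pair
and reused; this is also where the optional per-module parallelism applies
(forked workers, derived per-job seeds, identical results at any core
count). Degree-preserving nulls are deliberately not the default — the
method's reference null is uniform node sampling — and are out of scope
here.

Regulator statistics follow the definitions: connection strength of a
regulator–module pair is the fraction of module nodes it targets in a
layer; module specificity is the fraction of all layer regulators hitting
the module (a regulator inside the module counts when it targets a
co-member — the inclusive convention); regulator specificity is the
fraction of modules a regulator hits.

For a selected module set, connectivity against 1000 random same-size
module sets is summarised by the 95% confidence interval *on the mean* of
the null sums, $\bar{x} \pm 1.96\,s/\sqrt{B}$, and a fold change of the
observed sum over the upper bound — the CI-of-the-mean form is what the
reconstruction arithmetic (mean 1720, sd 880, $B = 1000$ → upper ≈ 1774.5,
fold ≈ 18) requires. Differential-expression enrichment of a module set
uses a one-sided hypergeometric test of DE membership among the set's genes
versus the genes of all other modules.

## Functional annotation

Per-module over-representation uses the one-sided hypergeometric test per
term with at least one study hit. The population is the annotated part of
the chosen background — all genes of the module's own type pool, all
network genes, or a user list — so padding a background with unannotated
genes changes nothing. Benjamini–Hochberg correction is applied within
each module across its tested terms (matching the one-file-per-module
output convention; a global mode exists behind a flag); rows with adjusted
p below 0.05 are kept. The retention comparator is configurable because
the opposite direction occasionally appears in the wild as a typo; the
default is the standard `<`. Retained rows carry a 1-based rank by
ascending adjusted p-value and $\log_2$ fold change
$\log_2\!\big((k/n)\,/\,(K/N)\big)$. When an OBO ontology is supplied,
annotations propagate to is_a ancestors before testing. Keyword selection
("hypoxia") matches retained term names case-insensitively.

## Expression contextualisation

Three scores embed modules in expression data, each against 1000
size-matched random gene sets with moments cached per distinct size:

* **nPCC** — mean pairwise Pearson correlation over module genes with
  expression (all gene pairs, per the score's definition), z-scored
  against random sets of the same effective size; $p = 1 - \Phi(z)$.
* **ECD** — mean over internal module *edges* (both endpoints expressed) of
  PCC(condition) − PCC(control), bounded in $[-2, 2]$. The random modules
  of the null preserve only the gene count, averaging over all pairs of the
  random set: the null's edge structure is unspecified by the score's
  definition and size-only sampling is the simplest faithful choice.
* **Activity $s_a$** — per-gene p-values are mapped to
  $z_i = \Phi^{-1}(1 - p_i)$ (clamped to $[10^{-16}, 1 - 10^{-16}]$ so
  exported $p = 0$ stays finite), aggregated as
  $z_a = k^{-1/2} \sum z_i$ over the $k$ scored module genes, and
  standardised by the moments of random size-$k$ gene sets:
  $s_a = (z_a - \mu_k)/\sigma_k$. Under uniform p-values $s_a$ is
  standard-normal to within sampling error, which the acceptance checks
  verify. Modules positive in every contrast form the "active set".

Genes absent from the expression matrix or p-value table are dropped per
score, never imputed; the effective size and the edge-wise expression
coverage are reported with each record. Correlation-based scores require
at least three samples and two expressed genes.

## Stability harness

Robustness to missing interactions is measured by sampling
90%, 80%, …, 10% of the pooled edges without replacement (layer membership
preserved, ten repetitions per fraction with seeds `seed + rep`), rerunning
detection on each sample, and scoring each re-derived module by its best
match against the full-network modules restricted to the sampled edges
(nodes left without internal edges are dropped; restriction never
re-splits a module). Jaccard on node sets is the headline metric; ARI and
AMI are computed on binary in/out membership vectors over the full node
universe — the universe must be fixed somehow and the full network's node
set is the only canonical choice. Repetitions where re-clustering recovers
nothing score zero rather than being dropped, so sparse fractions are
penalised, not censored. With planted synthetic modules the mean best-match
score decreases as the retained fraction falls, reproducing the known
saturation-then-decay trend.

## The synthetic generator

The fixture generator plants modules of declared types — COM as undirected
cliques sampled at the intra-module density, COR as a regulator wired to an
interacting target clique, FFL as an order-respecting directed density —
and sprinkles uniform background edges per layer. Its defaults are the
validation study's conditions: 10 planted modules, sizes 6–12,
intra-density 0.8, background density 0.02, 20 extra background nodes,
layers R/M directed and H/P/C undirected. Expression follows a
latent-factor Gaussian model (shared per-module factor, correlation 0.8 by
default, 8 samples per condition) with a 2-sd mean shift for modules
declared active and Welch-test p-values per gene. The generator emulates
dense typed communities and module-correlated expression; it does not
mimic the heavy-tailed degree distributions, annotation structure or batch
effects of real compendia, so passing tests demonstrate correctness of the
machinery and calibration of the statistics, not biological performance.

Problem sizes used by the validation runs — 200 oracle networks of up to
~15 nodes, 100 clustering instances of up to 10 nodes (where exhaustive
subset search is feasible), 20 recovery seeds, 500 calibration module
pairs, a six-module stability fixture — were chosen so that every check
runs from scratch in minutes on a laptop while keeping the statistical
comparisons meaningful.

## Degenerate inputs and numerical choices

Empty layers are valid (warned, zero edges); an empty instance pool yields
zero modules; a module with no annotated, expressed or scored genes yields
an `NA` record rather than an error. Ratio ties in cluster selection
resolve toward the binary-search optimum with bytewise node-order
tie-breaks; all randomness flows from explicit integer seeds, and reruns
with the same seed are bit-identical across core counts. The parametric
min-cut tolerance ($\min(10^{-9}, 1/(2n^2W))$) is below the minimum gap
between distinct ratios with unit weights, so the refined subset is exact
there and approximate only for irrational weight mixtures.

## Known limitations

The module catalogue stops at three nodes by design; larger motifs and
motif-significance profiling against randomized networks are out of scope.
Ratio-maximising extraction can absorb two equally dense communities joined
by enough bridging subgraphs into one cluster — an inherent property of the
objective, visible in the planted-recovery scores for small modules.
Superview p-values rely on a normal right-tail approximation to the
sampling null, which degrades for very sparse layers where the shared-edge
count is strongly discrete; the zero-count convention $(z,p) = (0,1)$ is a
deliberate bias toward non-significance there. AMI between two individual
modules depends on the chosen node universe; comparisons should therefore
fix the universe, as the stability harness does.
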