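---
title: "Network module discovery: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network module discovery: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmodr)
```

This vignette explains the statistical model behind netmodr, the parameters
that matter and their defaults, what the bundled benchmark generator does
and does not emulate, and the numerical and design decisions taken where
the method leaves room for choice.

## The model

The premise is that genes altered in a disease cohort perturb a small
number of cellular processes, and that those processes appear in a curated
interactome as clusters of interacting genes. Individual genes may be
altered too rarely to reach significance on recurrence alone; aggregating
over an interacting cluster restores power. The analysis has three stages.

### Linker inference

Candidate linkers are unaltered genes adjacent to at least one altered
gene: they patch holes that incomplete alteration calls (or genuinely rare
alterations) leave in a process cluster. For a candidate of degree $k$ with
$x$ altered neighbors, we ask how surprising $x$ is if the candidate's $k$
neighbors had been drawn uniformly from the network:

$$\Pr(X \ge x) = \sum_{i=x}^{\min(k,A)}
  \frac{\binom{A}{i}\binom{N-A}{k-i}}{\binom{N}{k}},$$

a hypergeometric tail with population $N$ and altered count $A$.

* **Population $N$** is the number of nodes in the full prior network minus
  one — the candidate cannot be its own neighbor. The method itself does not
  pin down the urn; this is the standard reading, it is isolated in a single
  function (`linker_pvalue()`), and the consequence worth knowing is that
  even an isolated node added to the prior network changes every raw
  p-value (the tests exercise this). Isolated nodes are therefore retained
  on input: they are part of the population even though they can never be
  linkers.
* **$A$** is the number of *mapped* altered genes. Altered genes are never
  tested as linkers, even when they neighbor other altered genes.
* **Multiple testing**: Benjamini–Hochberg across the candidate set only —
  candidates are the hypotheses actually tested; non-candidate genes have
  $x = 0$ by construction and testing them would only dilute the FDR.
* **Acceptance is inclusive**: adjusted $p \le$ cutoff (default 0.05).
  The boundary case is tested with a fixture whose adjusted p-value is
  exactly the double `0.05`.
* **`mode = "point"`** computes $\Pr(X = x)$ instead of the tail. It exists
  because the original, pre-R implementation of this algorithm used the
  point probability; the two modes agree on the accepted set at the usual
  cutoff in typical data but not on raw values. The tail test is the
  default and the statistically defensible choice.

The extended network is the induced subgraph on mapped altered genes plus
accepted linkers — all induced edges, including linker–linker edges, since
the process cluster we are reconstructing does not distinguish edge
classes. Altered genes left isolated by this restriction are removed from
the graph (community detection on singletons is vacuous) but reported in a
side table.

### Community detection

Modules are communities of the extended network, found either by
Girvan–Newman edge betweenness (default) or by the leading-eigenvector
method, both via igraph, both deterministic for a given graph. The
Girvan–Newman dendrogram is cut at the modularity-maximizing level —
standard practice, and on every small fixture where exhaustive search over
all partitions is feasible (up to Bell(8) = 4140 partitions) the suite
verifies the returned partition attains the global maximum of $Q$.
Disconnected components are partitioned jointly and fall into separate
modules naturally. Edge betweenness costs roughly $O(|E|^2|V|)$; above
2000 nodes the package warns and suggests the leading-eigenvector method
rather than switching silently. For degenerate eigenvalue problems the
spectral method declines to split further, which keeps it deterministic.

Module ids are renumbered canonically — decreasing size, ties broken by the
lexicographically smallest member, consecutive integers from 1 — so that
identical inputs give identical tables.

Modularity $Q = \sum_c (e_{cc} - a_c^2)$ is implemented in the package
(`modularity_q()`) rather than delegated, so that the partition returned by
igraph is scored by an independent route; the test suite additionally
cross-checks `modularity_q()` against `igraph::modularity()` on random
graphs and against closed forms ($Q = 0$ for the whole graph as one module,
$Q = 1/2$ for two disconnected equal cliques split apart).

### Significance

Two complementary nulls:

* **Global connectivity.** Observed statistic: the largest connected
  component (LCC) induced by the mapped altered genes in the *full* prior
  network. Null: the same number of genes drawn uniformly without
  replacement from all network nodes — the same frame the observed list was
  mapped into. The p-value uses the permutation pseudocount
  $p = (r+1)/(T+1)$, never zero. Uniform (rather than degree-matched)
  drawing is the classical form of this test; degree-matched sampling would
  be a reasonable extension for interactomes with strong study bias.
* **Modularity.** Null ensemble: degree-preserving rewiring (double edge
  swaps, rejecting self-loops and duplicates, `swap_factor` = 10 attempted
  swaps per edge, a common mixing heuristic). Each rewired network is
  re-partitioned from scratch — reusing the observed partition would
  inflate the z-score, since the null must be allowed its own best
  partition. The observed $Q$ is reported as
  $z = (Q - \bar Q_0)/s_0$ with a one-sided upper-tail normal p-value.
  When the null is degenerate ($s_0 = 0$; e.g. a triangle, which rewiring
  cannot change), the z-score is `NA` and the empirical fraction is
  reported instead.

Default trial counts: 1000 for the LCC test (cheap: one induced-subgraph
component computation per trial) and 100 for the modularity null (each
trial runs community detection). Master seed → per-trial seeds are derived
deterministically, so a `SignificanceReport` is bit-reproducible from
`(inputs, seed)`.

## The planted benchmark

`generate_planted()` draws a stochastic block model: `n_modules` dense
blocks (edge probability `p_intra`) over a sparse background
(`p_inter` between modules, `p_background` for any pair touching a
background node). The altered list takes `altered_fraction` of each module
plus `altered_background` background genes; the unaltered module members
with at least one altered neighbor are the *withheld linkers* — genes an
ideal analysis would recover. Defaults: 3 modules × 12 genes,
`p_intra = 0.6`, `p_inter = p_background = 0.02`, 40 background nodes,
`altered_fraction = 0.7`, 5 altered background genes.

What the generator emulates: modular structure denser inside processes
than between them, an altered list that covers processes incompletely, and
background genes that carry no signal. What it does not emulate: the
scale-free, hub-dominated degree distribution of real interactomes, study
bias (well-studied genes have more recorded edges), edge-type semantics,
and — importantly — the *size ratio* of a real analysis, where a few hundred
altered genes meet an interactome of ~10⁴ nodes. Passing the benchmark
therefore demonstrates correct mechanics and module recovery, not the
linker test's operating characteristics on a real interactome.

That last limitation is quantitative and worth spelling out. In the default
benchmark, $A/N \approx 29/75 \approx 0.39$: a withheld module member with
6 of 8 neighbors altered is only mildly surprising against so saturated a
baseline (raw tail p ≈ 0.01–0.07), and after BH across ~25–30 candidates no
linker reaches 0.05 — the suite's end-to-end benchmark observes exactly
this (median linker recall 0, while median module ARI is 1). With a
realistically large background the same test is well powered: the p-value
for the same $x/k$ shrinks by orders of magnitude as $A/N$ falls. In short:
linker inference is designed for the sparse-alteration regime; on small
dense toy problems it is deliberately conservative, and module recovery —
which does not depend on accepting linkers — is what the compact benchmark
can meaningfully certify.

## Numerical choices and degenerate inputs

* Hypergeometric probabilities go through `phyper()`/`dhyper()` (log-space;
  stable for networks of $10^5$ nodes and beyond). Exhaustive enumeration
  over all $\binom{N}{k}$ neighbor sets is the test oracle at small $N$.
* The tail p-value is non-increasing in $x$ and non-increasing in $N$
  (fixed $A, k, x$): growing the population dilutes the altered fraction.
* Empty gene lists, lists that map to nothing, networks with no connected
  altered gene, edgeless networks (modularity undefined; singleton
  modules), fewer than 2 edges for rewiring, and `trials < 2` for the
  modularity null all raise early, named errors rather than propagating
  `NaN`s.
* Identifier matching is exact string equality after stripping surrounding
  whitespace. No case folding, no alias resolution: silent aliasing is a
  reproducibility hazard, so identifier harmonization is the user's job.
* SIF and TSV edge lists cannot represent isolated nodes; `write_network()`
  drops them with a warning in those formats and keeps them in GraphML.
* Output tables are written with fixed 15-digit formatting and LF endings,
  so identical runs produce byte-identical bundles on any platform.

## Test design notes

The suite generates all fixtures in code. Problem sizes were chosen to keep
the full suite under a minute while leaving the oracles exact: enumeration
oracles use $N \le 12$ (tail vs. all neighbor sets) and $N \le 30$ (exact
integer binomials), exhaustive modularity search goes up to 8 nodes, the
planted-recovery benchmark runs the 20-seed default configuration, and the
null-calibration check uses 200 replicates of 99 permutation trials each.

One calibration fixture deserves a note: the uniformity check for the LCC
permutation p-value samples 60-gene sets from a 200-node Erdős–Rényi graph
with edge probability 0.03, so the induced subgraphs sit near the
percolation regime where the LCC statistic has wide support. With a much
sparser fixture the statistic is nearly constant, its permutation p-value
is dominated by ties, and no implementation could look uniform — the
discreteness of permutation p-values, not a defect, but a constraint on
where uniformity is observable.

## Known limitations

* Edge direction, sign and type are ignored; the discovery operates on an
  undirected, untyped simple graph.
* Girvan–Newman is quadratic-ish in edges; use the leading-eigenvector
  method beyond a few thousand nodes.
* The LCC null draws genes uniformly, not degree-matched; hub-heavy altered
  lists will look more connected than a degree-aware null would say.
* Linker p-values depend on the population definition ($N$); comparisons
  across differently-pruned prior networks are not meaningful.
* No overlapping modules: each gene belongs to exactly one module.
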