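# netmodr

Data-driven discovery of candidate pathway modules from cancer genomics (or
any other perturbation) data. Given

1. a **prior-knowledge interaction network** — genes as nodes, curated
   molecular interactions as edges (e.g. a Pathway Commons export in SIF
   format), and
2. a list of **altered genes** — genes flagged as significantly mutated,
   copy-number changed, or otherwise perturbed in a cohort,

netmodr maps the altered genes onto the network, infers unaltered **linker
genes** that connect them more often than chance, partitions the resulting
extended network into **modules** by community detection, and reports two
permutation-based significance assessments. Modules discovered this way are
defined by the data and the interactome, not by pre-curated gene sets, so
they can cross the boundaries of annotated pathways and aggregate weak
per-gene recurrence signals into a detectable process-level signal.

Intended users are computational biologists working with cohort-level
alteration calls who want hypothesis-generating pathway modules without
committing to a fixed gene-set collection.

## The method

**Linker inference.** Candidate linkers are genes without alterations that
are direct neighbors of altered genes. For a candidate with global degree
*k* and *x* neighbors in the altered set, the p-value is the hypergeometric
tail

    Pr(X >= x) = sum_{i=x}^{min(k,A)} C(A,i) C(N-A, k-i) / C(N,k)

with population *N* = (nodes in the prior network) − 1 and *A* = number of
mapped altered genes. P-values are Benjamini–Hochberg corrected across the
candidate set and candidates with adjusted p ≤ 0.05 (inclusive) are accepted.
A `point` mode computing Pr(X = x) is available to reproduce the raw
p-values of the original pre-R implementation of the algorithm; the accepted
set at FDR 0.05 is what matters and the tail test is the default.

**Module detection.** The extended network (connected altered genes plus
accepted linkers, with all induced edges) is partitioned by Girvan–Newman
edge betweenness or, for large networks, the leading-eigenvector method,
keeping the partition that maximizes Newman modularity
*Q = Σ_c (e_cc − a_c²)*.

**Significance.** Two tests: (a) an empirical p-value for the size of the
largest connected component (LCC) induced by the altered genes, against the
same number of genes drawn uniformly from the network (p = (r+1)/(trials+1));
(b) a z-score for the observed modularity against a null ensemble of
degree-preserving rewired networks (double edge swaps; each rewired network
is re-partitioned from scratch), reported as a one-sided normal p-value.

A stochastic-block-model benchmark generator with planted modules, a
controlled altered-gene list and withheld linkers makes the whole pipeline
testable offline; `score_recovery()` reports adjusted Rand index, linker
recall and background false positives against the planted truth.

## Worked example

```r
library(netmodr)

truth <- generate_planted(planted_config(seed = 42))   # benchmark instance
ext   <- build_extended_network(truth$network, truth$altered)
ext
#> Extended network: 28 nodes, 63 edges
#>   altered genes retained: 28 (of 29 mapped; 1 isolated excluded)
#>   linkers accepted: 0 of 27 candidates (tail test, FDR cutoff 0.05)

part <- detect_communities(ext$graph)
part
#> Module partition (edge_betweenness): 3 modules over 28 nodes, Q = 0.5551
#>   module sizes: 10, 9, 9

global_connectivity_test(truth$network, truth$altered, trials = 999, seed = 7)
#> Global connectivity test: observed LCC = 28 of 29 genes
#>   null (n = 999 trials): mean 15.36, max 26; empirical p = 0.001

modularity_significance(ext$graph, trials = 100, seed = 8)
#> Modularity significance: observed Q = 0.5551
#>   rewired null (n = 100): mean 0.2642, sd 0.0334
#>   z = 8.72, one-sided p = 1.42e-18

score_recovery(truth, part, ext)$ari
#> [1] 1
```

Reading: the 29 altered genes of this instance form a 28-gene connected
component where random 29-gene draws reach only ~15 (p = 0.001), its module
structure is far stronger than degree-matched chance (z = 8.7), and
community detection recovers the three planted modules exactly (ARI = 1).
No linker reaches FDR 0.05 here: with 29 of 76 genes altered, the
hypergeometric baseline is so high that a gene with 6 of 8 neighbors altered
is only mildly surprising — see the vignette for this power discussion.

`tidy()` / `glance()` turn every result into a tibble, and `autoplot()`
draws the extended network, the module partition and both null
distributions. For file-based runs, `run_pipeline()` (or the `exec/netmodr`
command-line wrapper) executes the whole workflow and writes a results
bundle — linker table, module table, SIF/GraphML networks, significance
report and a reproducibility manifest.

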