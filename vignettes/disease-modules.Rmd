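---
title: "Disease modules and drug-target proximity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease modules and drug-target proximity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netmod)
```

`netmod` implements an integrated network-medicine workflow: place curated
disease genes on a high-confidence protein interaction network, find the
topological communities they concentrate in, characterize those communities
functionally, and ask where existing drugs act relative to them. This
vignette is the package's own account of the methods: the statistics, the
parameters that matter, the synthetic data the tests rely on, and the
design choices made where the field's conventions leave the design open.

## The interactome and its confidence filter

Input networks are STRING-style weighted edge lists: two protein
identifiers and an integer combined confidence score in 0–1000.
`load_interactome()` keeps interactions with `score >= score_threshold`
(inclusive; default 700, the conventional "high confidence" cut for STRING
scores), uppercases identifiers, collapses duplicate and reversed-duplicate
records to the maximum score, and drops self-loops with a count message.
The analysis treats the filtered network as an undirected simple graph;
restriction to the largest connected component is available
(`largest_component()`, `use_largest_component` in the pipeline config) but
off by default, since module detection and BFS distances are well defined
on disconnected graphs and dropping small components silently would change
seed-gene accounting.

## Size-bounded topological modules

Modules are detected by Louvain modularity maximization. Because
over-representation statistics lose power on very large gene sets and are
unstable on very small ones, communities are constrained to a workable size
band (defaults 5–400): any community larger than `max_size` is re-run
through Louvain on its induced subgraph, recursively, until it fits or the
algorithm returns a single community (kept, and reported as
"unsplittable"). Communities below `min_size` are *flagged* rather than
merged — forcing them into neighbours would create communities the
optimizer never proposed — and downstream association excludes flagged
modules by default.

Two open choices are worth recording:

* **Edge weights.** After confidence filtering the graph is treated as
  binary topology (`weighted = FALSE`); the scores already did their job as
  a quality filter, and using them again as Louvain weights would double-
  count confidence as connection strength. A `weighted = TRUE` switch is
  provided.
* **Determinism.** Louvain is order-sensitive, so `detect_modules()` fixes
  the RNG seed and visits vertices in sorted-name order; identical seed and
  input give an identical partition (a tested invariant). Module ids
  `M1, M2, ...` are assigned by each module's lexicographically smallest
  member, so labels are stable across runs.

The module-level graph weights a module pair as $w = c/(a \cdot b)$ with
$c$ the number of cross-interactions and $a, b$ the module sizes; $w$ lies
in $(0, 1]$ and equals 1 exactly for a complete bipartite connection.
Module degree in this graph identifies hub modules.

## Disease association: relative risk and chi-square

For a module with $k$ seed genes among $m$ proteins, against a background
of $S$ seed genes among $N$ proteins,

$$\mathrm{RR} = \frac{k/m}{S/N},$$

tested by a Pearson chi-square (1 df) on the 2×2 table
$[[k, m-k], [S-k, N-m-(S-k)]]$, Bonferroni-corrected over the number of
modules tested. Two conventions matter:

* **Background.** The default background is the set of modules containing
  at least one seed gene (their proteins and the seeds inside them), not
  the whole interactome: a module's seed density is judged against the
  universe in which seeds actually land. `background = "all_modules"` and
  explicit `S`, `N` overrides are provided. With the worked counts
  `k = 45, m = 305, S = 921, N = 12084` this gives RR = 1.94 (2 d.p.).
* **Continuity correction.** No Yates correction by default (the classic
  Pearson statistic has the clean property that $\chi^2 = 0$ iff
  RR $= 1$ on the same table, which the tests assert); `yates = TRUE` is
  available.

Selection takes either a fixed RR cutoff or an *anchor module* whose RR
becomes the cutoff — the pattern in which the last module surviving a
conservative p-value filter sets the RR bar for the rest. Per-disease
mapping (`disease_to_modules()`) scores each disease's own genes against
the whole-partition background and reports modules with RR strictly above
the threshold (default 1.0).

## Enrichment and functional similarity

Over-representation uses the upper-tail hypergeometric probability
$P(X \ge k)$ for $X \sim \mathrm{Hypergeom}(N, K, n)$, with the query
restricted to annotated genes. The Bonferroni family size defaults to the
number of terms with nonzero overlap for the query — the behaviour family
of module-level GO tools — with an "all terms in the collection" option;
both are exposed because published tool defaults differ and are rarely
stated. The universe defaults to the collection's annotated genes, not the
interactome, again with an override. GO-hierarchy propagation is *not*
performed: collections are taken as flat sets.

Functional profiles assign each significant term the value
$-\log p_{\mathrm{corrected}}$ (natural log; cosine similarity is
scale-invariant, so the base is immaterial). Corrected p-values are floored
at $10^{-300}$ before the log so that underflowed values stay finite.
Terms at or above the significance threshold contribute zero. Module pairs
are compared per namespace by cosine similarity on the union of their term
coordinates (all-zero vectors give similarity 0 by convention), and

$$\mathrm{combined} = 0.5 \cdot \frac{s_{BP} + s_{CC} + s_{MF}}{3}
  + 0.5 \cdot s_{\mathrm{pathway}},$$

weighting the three GO namespaces jointly as much as the single pathway
similarity. Clustering runs weighted Louvain on the similarity graph after
discarding edges below `min_combined` (default 0.05 — no published
threshold exists for this graph, so a permissive floor that merely removes
numerical dust was chosen); modules left isolated are reported as
unclustered rather than forced into singleton clusters.

## Drug-target proximity and nomination

Distances are unweighted hop counts (BFS; identical to Dijkstra on unit
costs): the number of molecular steps from a target to the nearest seed
gene, 0 if the target is itself a seed. Targets missing from the graph are
dropped with a count; unreachable targets are reported with `Inf` and
excluded from test statistics. The null model draws `n_samples` (default
100) random protein sets of the observed size — uniformly by default, with
a degree-matched mode (log2 degree bins) because uniform draws are biased
toward the low-degree majority — and compares observed distances against
the pooled null distances with a two-sided, pooled-variance Student t-test
(Welch by flag). Pooling the null minima, rather than testing against
per-sample means, keeps the comparison on the same per-protein scale as
the observed distances; this choice is deliberate and configurable only by
post-processing `null_distances`.

The per-module census counts direct targets (members), neighbor targets
(non-members at distance exactly 1 from the module's *own* seed genes —
the module-scoped reading of "first neighbors of seed nodes"), distinct
drugs with a direct target in the module, and drugs per protein.
Candidate nomination inside a module requires: membership in the module's
most enriched pathway (minimum corrected p), no existing disease-specific
drug targeting the gene, and — when an expression table is supplied —
expression in at least one required tissue (default cerebral cortex and
hippocampus, the tissues whose pathology motivates the rule).

## External validation of a curated gene list

`validate_against_reference()` measures the overlap of a curated list with
an independent reference list as fold enrichment over the uniform
expectation $|\mathrm{ref}|\cdot|\mathrm{genes}|/\mathrm{universe}$, with a
one-sided upper-tail binomial p-value. The default universe of 19,063
protein-coding genes is a documented reconstruction — it is the value that
reproduces the published 5.70-fold benchmark — not a reported number; pass
your own universe size when you have one.

## The synthetic data: what it does and does not emulate

`synthetic_spec()`/`generate_synthetic()` produce every input the pipeline
consumes, with planted ground truth. The default conditions: five blocks
of 100 proteins; within-block edge probability 0.3, between-block 0.01
(strongly assortative, so community recovery is expected); within-block
edges score in 700–999 with probability 0.9 and between-block edges with
probability 0.3, others 150–699, so confidence filtering sharpens the
planted structure; two diseases of 40 genes homed in distinct blocks with
a 5% leak; per namespace, one planted term of 30 genes per block plus 10
random decoy terms over a universe padded to 2,000 annotated genes; four
drugs (two disease-class) with five targets each placed at hop distance at
most 1 from the seeds; and an expression table covering both required
tissues. Generation is deterministic per seed down to byte-identical
files, and realized densities are tested against binomial 99% bounds.

The generator emulates the *statistical* structure the analysis assumes —
assortative modules, clustered disease genes, block-enriched terms,
proximal targets — and nothing else. It does not reproduce heavy-tailed
PPI degree distributions, GO's DAG structure and term overlap, literature
bias in gene curation, or database-snapshot idiosyncrasies. Passing tests
therefore demonstrate that the machinery recovers planted signal under the
assumed generating model, not that any particular real-data module list
will be reproduced; results that depend on a specific interactome or
curation snapshot (exact module counts and ids, specific candidate genes)
are explicitly out of reach of desk-scale validation.

Test problem sizes were chosen to keep the full suite fast while leaving
the statistics non-trivial: 500–1,000-node planted graphs, 20-seed repeat
batteries for recovery properties, 50-repeat calibration of the proximity
null at 100 samples per run, and exhaustive hypergeometric enumeration up
to $N = 12$.

## Degenerate inputs and numerical conventions

* Empty filter results: a valid empty graph with a warning; the pipeline
  treats an empty stage-1 graph as a hard error naming the stage.
* Thresholds above the score range simply produce that empty graph; the
  loader does not reject them.
* Singleton components become their own (flagged) modules.
* `k = 0` hypergeometric queries return probability 1; bound violations
  are errors, not clamps.
* All-zero similarity vectors yield cosine 0; combined-score inputs are
  validated to [0, 1].
* A degenerate t-test (both samples constant) reports t = 0, p = 1.
* Ties are broken deterministically everywhere (sorted ids), and every
  stochastic step takes an explicit integer seed.

## Known limitations

Louvain recursion honours the size band only up to unsplittable
communities, which are retained oversize and flagged. The Bonferroni
family size and the enrichment universe materially affect corrected
p-values and are configuration, not ground truth. The RR background
convention changes RR values; both conventions are provided and the
default is stated above. Uniform null sampling under-represents hub
proteins; the degree-matched mode mitigates but bins coarsely. None of the
shipped statistics model annotation dependence between GO terms.
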