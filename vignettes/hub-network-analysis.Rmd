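---
title: "Hub-gene prioritization from confidence-scored interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hub-gene prioritization from confidence-scored interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hubnet)
```

## The analysis

`hubnet` implements a network-medicine pipeline for prioritizing candidate
disease genes from a confidence-scored protein–protein interaction (PPI)
network, of the kind exported by the STRING database, and for vetting those
candidates against two-group differential-expression evidence from two
independent cohorts. The stages are:

1. **Network construction.** A weighted undirected edge list
   (`protein_a`, `protein_b`, `combined_score`) is read, cleaned
   (self-loops dropped, duplicate unordered pairs collapsed to the maximum
   confidence), filtered to high-confidence edges (score strictly greater
   than 0.9, STRING's "high confidence" band), and reduced to its largest
   connected component.
2. **Topology.** Degree distribution with a scale-free power-law fit,
   average clustering coefficient, characteristic path length, and
   diameter.
3. **Hub selection.** Nodes are ranked by degree and, separately, by
   betweenness centrality; the top 50 under each ranking are intersected.
   The intersection — the *common hub* set — is the candidate gene list.
4. **Clustering.** k-means on the rows of the adjacency matrix, with the
   cluster count set by the rule of thumb $k = \sqrt{n/2}$.
5. **Enrichment.** Hypergeometric over-representation of the hub list
   against user-supplied gene sets (GMT), Benjamini–Hochberg adjustment,
   minimum overlap of two genes per category, $\alpha = 0.05$.
6. **Expression meta-filter.** Per cohort, a pooled two-sample Student's
   *t* per gene; genes split by fold-change sign into under-/over-expressed
   classes and ranked within class by ascending *p* (an Oncomine-style
   "gene rank", reported as a top-percentile). Across the two cohorts a
   gene is kept when it is reported in both, its fold changes agree in
   sign, and its cumulative rank percentile is within the top 36%.

## Models and conventions

**Power-law fit.** The scale-free model $P(k) \sim k^{-\gamma}$ is fitted
by ordinary least squares of $\log_{10} P(k)$ on $\log_{10} k$ over the
raw, unbinned support with $k \ge 1$ — the convention of Cytoscape's
NetworkAnalyzer. This is a descriptive fit, not a maximum-likelihood tail
estimate: on empirical distributions it can return exponents below 1,
which would be non-normalizable for a pure power law on infinite support
but are routinely reported by network tools for finite PPI networks.
$R^2$ is computed on the log–log regression; a zero-residual fit reports
exactly 1. Logarithmic binning and Clauset-style estimation are outside
the scope of this pipeline.

**Path metrics on the largest component.** Characteristic path length and
diameter are only finite on a connected graph, and published network
summaries report single finite values, so both are computed on the largest
connected component (ties broken toward the component containing the
lexicographically smallest node).

**Clustering coefficient conventions.** The average local clustering
coefficient counts nodes of degree < 2 as zero; because tools differ,
`topology_summary()` also reports the mean over degree ≥ 2 nodes.

**Betweenness.** Unnormalized shortest-path betweenness (Brandes'
algorithm via igraph, exact path-count accumulation, no sampling).
Normalization by $2/((n-1)(n-2))$ is available but irrelevant to ranking,
the only downstream use. Confidence weighting is off by default — the
weighted treatment used by common hub-ranking plugins is not standardized —
but `use_confidence_weights = TRUE` ranks by strength (summed confidence)
and routes shortest paths along distances $1/\text{confidence}$.

**Tie-breaking.** All rankings break score ties lexicographically by node
symbol, so top-$N$ boundaries, and therefore the common hub set, are
deterministic and reproducible across platforms.

**k-means.** Nodes are embedded as their adjacency-matrix rows (binary by
default, confidence-weighted behind a flag) and partitioned with
`stats::kmeans` (Hartigan–Wong, `n_init = 10` random restarts keeping the
lowest within-cluster sum of squares, `max_iter = 300`). The partition is
seed-reproducible and the caller's RNG state is left untouched. On two
disjoint 5-cliques with $k = 2$ the partition attains the exhaustive
minimum inertia over all 2-partitions (verified in the tests). Exact
cluster memberships produced by proprietary embeddings of online network
viewers are not reproducible and not attempted.

**Enrichment filter order.** Categories overlapping the query in fewer
than two genes are excluded *before* BH adjustment, matching WebGestalt's
behaviour; the significance cutoff applies to the adjusted *p* by default
(`alpha_on = "raw"` is available, since reports of "a P-value of 0.05"
cut-offs are often ambiguous on this point).

**Student's t and degenerate genes.** The pooled-variance test is the
default because it is the classical "Student's t-test" named by microarray
databases; Welch's form is behind `var_equal = FALSE`. A gene with zero
pooled variance and equal means gets $t = 0, p = 1$; zero variance with
unequal means gets the smallest representable *p* and a `degenerate` flag
rather than a silent infinity.

**"Cumulative gene rank".** The two cohorts' percentiles are combined by
their **mean** by default (`sum` and `max` are available). Percentiles are
computed within each direction class separately, mirroring how expression
databases run separate over- and under-expression analyses. On the bundled
published T-ALL summary the mean rule reproduces the printed under/over
split exactly (16 and 11 genes); one printed row (EGFR, percentiles 34 and
39, mean 36.5) falls just outside the top-36% cumulative cutoff and is
flagged by `passes_filter = FALSE` rather than silently reclassified —
the direction classification is unaffected.

## The synthetic-data generator

Real STRING exports and cohort microarray matrices cannot be bundled, so
the generator produces inputs with the statistical structure the pipeline
assumes:

- `make_network()` grows a Barabási–Albert preferential-attachment graph
  (`igraph::sample_pa`, linear attachment), which is connected and
  heavy-tailed — the "small-world scale-free" character of curated PPI
  networks. Edge confidences are uniform on [0.4, 1] by default (the range
  of STRING combined scores above the low-confidence floor) or fixed.
- `make_expression_pair()` emulates two independent log-scale,
  median-centered two-group cohorts over the same genes: standard Gaussian
  noise, with a planted gene subset shifted by `effect_size` noise
  standard deviations in the disease group, each planted gene's sign drawn
  once and shared across the pair (`shared_planted = TRUE`), and every
  sample median-centered afterwards.

What the generator does **not** emulate: STRING's evidence channels and
score correlations, probe-level artifacts, heteroskedastic
(intensity-dependent) microarray noise, gene–gene expression correlation,
and batch effects. Passing tests therefore demonstrate correctness of the
pipeline's computations and its ability to recover planted signal under
idealized noise — not performance on real cohorts.

## Test and simulation sizes

The default verification suite uses deliberately small problems chosen so
every check runs against an exhaustive oracle: random graphs of ≤ 10 nodes
for brute-force betweenness/BFS/triangle comparisons (200 and 100
instances), 2 000-gene null cohorts at 20 + 20 samples for type-I
calibration, and ten replicates of a 300-node network with 20 planted
high-degree differential genes (30 + 30 samples, effect two s.d.) for
end-to-end recovery, where at least 90% of planted hub genes must reappear
in the final under/over lists. The analysis scripts use a 201-node network,
the scale at which the $\sqrt{n/2}$ rule prescribes 10 clusters.

## Known limitations

- The log–log least-squares exponent is biased relative to
  maximum-likelihood estimators and should be read as a descriptive
  summary, not an inferential estimate of a tail index.
- Rank percentiles use `ceiling(100 * rank / class size)`, so very small
  classes quantize coarsely.
- The meta-filter treats the two cohorts symmetrically and equally
  weighted; no cohort-size or variance weighting is applied.
- Genes with a fold change of exactly zero belong to neither direction
  class and cannot pass the meta-filter.
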