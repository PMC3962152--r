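# hubnet

Hub-gene prioritization from confidence-scored protein–protein interaction
(PPI) networks, with a two-cohort differential-expression meta-filter.

## The problem

Disease-gene candidates are often nominated from interaction networks: in
a STRING-style PPI network around a query protein (here, the motivating
context is the NOTCH1 interactome in T-cell acute lymphoblastic leukemia),
the *hubs* — the most connected and most traversed nodes — are the genes
most likely to matter. `hubnet` implements that workflow end to end for
anyone with (a) a weighted edge list, (b) optional gene sets in GMT
format, and (c) two-group expression matrices from two independent
cohorts:

1. **Network**: read `protein_a / protein_b / combined_score` TSV (unit or
   STRING 0–1000 score dialect), keep edges with confidence > 0.9, take
   the largest connected component.
2. **Topology**: degree distribution with a scale-free fit
   P(k) ∼ k<sup>−γ</sup> by least squares of log₁₀ P(k) on log₁₀ k;
   average clustering coefficient ⟨C⟩; characteristic path length ⟨L⟩ and
   diameter on the largest component.
3. **Hubs**: rank nodes by degree and by (unnormalized Brandes)
   betweenness σ<sub>st</sub>(v)/σ<sub>st</sub> summed over pairs; the
   *common hub set* is the intersection of the two top-50 lists.
4. **Clusters**: k-means on adjacency rows with k = round(√(n/2)).
5. **Enrichment**: upper-tail hypergeometric over-representation of the
   hub list per category, minimum overlap 2, Benjamini–Hochberg
   adjustment, α = 0.05.
6. **Expression meta-filter**: per cohort and gene a pooled Student's
   t-test; genes split by fold-change sign and ranked within class by
   ascending p into top-percentile "gene ranks"; a hub gene is called
   under-/over-expressed when it appears in both cohorts with concordant
   fold-change signs and its mean rank percentile is within the top 36%.

Scale-free synthetic networks (preferential attachment) and paired
two-group expression cohorts with planted differential genes are built in,
so the whole pipeline is testable without any database access. A bundled
table ships the published hub list (42 genes) and per-cohort expression
summaries (27 genes) for the NOTCH1-interactome / T-ALL analysis.

## Worked example

```r
library(hubnet)

# a 201-node scale-free interactome with high-confidence scores
net <- make_network(201, attach_m = 3, conf_range = c(0.9, 1), seed = 42)
net <- largest_component(filter_by_confidence(net, 0.9))
topology_summary(net)
#> nodes: 201  edges: 597
#> degree exponent gamma: 1.680 (R^2 = 0.767)
#> avg clustering coefficient: 0.094 (0.094 over deg >= 2 nodes)
#> characteristic path length: 2.848  diameter: 5

hubs <- select_hubs(net, n_top = 50)
hubs
#> hub selection (top 50 by degree and betweenness): 43 common hubs
cluster_count_rule(n_nodes(net))
#> [1] 10

# two synthetic 30-vs-30 cohorts with a 2-s.d. shift planted on the hubs
pair <- make_expression_pair(n_genes = n_nodes(net), n_normal = 30,
                             n_disease = 30, effect_size = 2,
                             gene_names = net$nodes,
                             planted_genes = hubs$common_hubs, seed = 7)
sa <- rank_percentiles(differential_stats(pair$a))
sb <- rank_percentiles(differential_stats(pair$b))
classify_hub_expression(hubs$common_hubs,
                        meta_combine(sa, sb, threshold_pct = 36))
#> hub expression classification:
#>      under       over discordant     absent unmeasured
#>         15         28          0          0          0
```

The 43 common hubs are the nodes in both top-50 centrality lists; all 43
planted genes are recovered by the meta-filter, split 15/28 by the random
planted signs. On the bundled published T-ALL summary the same
classification yields 16 underexpressed and 11 overexpressed hub genes:

```r
report <- classify_hub_expression(notch1_hub_genes(),
                                  meta_from_printed(tall_hub_expression()))
report$counts[c("under", "over")]
#> under  over
#>    16    11
```

## The analysis workflow

The numbered scripts under `analysis/` run the full pipeline on a
simulated 201-node interactome and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_network.R   # export, dialect round-trip, 0.9 filter
Rscript analysis/02_topology.R           # power-law fit, <C>, <L>, diameter
Rscript analysis/03_hubs_and_clusters.R  # top-50 intersection, k = sqrt(n/2) k-means
Rscript analysis/04_enrichment.R         # hub list vs cluster-derived gene sets
Rscript analysis/05_expression_meta.R    # planted cohorts + published T-ALL table
```

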