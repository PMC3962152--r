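#!/usr/bin/env Rscript
# Step 3 — hub prioritization and network clustering.
#
# Hubs are the nodes common to the top-50 degree and top-50 betweenness
# rankings (lexicographic tie-breaks keep the lists deterministic). The
# network is then partitioned by k-means on adjacency rows with the cluster
# count prescribed by the k = sqrt(n/2) rule of thumb.

suppressPackageStartupMessages(library(hubnet))
seed <- 42

net <- read_edge_list("results/network_hc_edges.tsv")

hubs <- select_hubs(net, n_top = 50)
print(hubs)
write.table(hub_table(hubs), "results/hub_table.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(hubs$common_hubs, "results/common_hubs.txt")

k <- cluster_count_rule(n_nodes(net))
cat(sprintf("cluster-count rule: n = %d nodes -> k = %d\n", n_nodes(net), k))
part <- kmeans_partition(net, k = k, seed = seed)
print(part)
write.table(data.frame(node = names(part$labels), cluster = part$labels),
            "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/hub_table.tsv, results/common_hubs.txt, results/clusters.tsv\n")
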