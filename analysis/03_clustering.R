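#!/usr/bin/env Rscript
# Unsupervised view: hierarchical clustering of the log2 median-centered
# MFA table on both axes (correlation distance, average linkage), the
# two main sample clusters' association with clinical variables, and
# the pathway membership of the KO clusters.

library(mucometa)

mfa <- read_mfa("results/mfa_log2centered.tsv")
clinical <- read_clinical("results/cohort/clinical.csv")
map <- load_pathway_map("results/cohort/pathway_map.tsv")

cl <- hierarchical_cluster(mfa, n_sample_clusters = 2L, n_ko_clusters = 2L)
assoc <- cluster_clinical_association(cl, clinical)
overlap <- ko_cluster_pathway_overlap(cl, map)

write.table(data.frame(sample_id = names(cl$sample_clusters),
                       cluster = unname(cl$sample_clusters)),
            "results/sample_clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(assoc, "results/cluster_clinical.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(overlap, "results/ko_cluster_pathways.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
if (requireNamespace("ape", quietly = TRUE)) {
  ape::write.tree(ape::as.phylo(cl$sample_tree), "results/sample_tree.nwk")
  ape::write.tree(ape::as.phylo(cl$ko_tree), "results/ko_tree.nwk")
}

# sub-cluster view: the same trees cut at 4
sub <- cutree(cl$sample_tree, k = 4L)
cat(sprintf("Samples: 2 main clusters (%s), 4 sub-clusters (%s)\n",
            paste(table(cl$sample_clusters), collapse = "/"),
            paste(table(sub), collapse = "/")))
size_p <- assoc$p[assoc$variable == "tumor_size_cm"]
cat(sprintf("Cluster association with tumor size: Wilcoxon p = %.3g%s\n",
            size_p, if (size_p < 0.05) " (clusters split by tumor size)" else ""))
top <- overlap[order(overlap$p), ][1:3, ]
cat("Most cluster-concentrated pathways:\n")
print(top[, c("ko_cluster", "pathway_id", "overlap", "p")], row.names = FALSE)
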