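#!/usr/bin/env Rscript
# Taxonomy: order-level OTU table from contig length x depth, taxa
# differentially abundant between the tumor groups, and the taxa
# representing the glycan degradation pathway with their correlation to
# its activity score.

library(mucometa)

contigs <- read_contigs("results/cohort/contigs.tsv")
clinical <- read_clinical("results/cohort/clinical.csv")
map <- load_pathway_map("results/cohort/pathway_map.tsv")
norm <- read_mfa("results/mfa_normalized.tsv")
groups <- assign_size_groups(clinical, k = 14L)

otu <- taxa_abundance(contigs, rank = "order")
dtaxa <- differential_taxa(otu, groups, alpha = 0.05)
write.table(data.frame(taxon = rownames(otu$values), otu$values,
                       check.names = FALSE),
            "results/otu_order.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(dtaxa, "results/differential_taxa.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

glycan_kos <- map$ko_id[map$pathway_id == "glycan_degradation"]
prof <- pathway_taxa_profile(contigs, glycan_kos, rank = "order")
score <- activity_score(norm, glycan_kos, pseudocount = 1)
cors <- correlate_pathway_taxa(score, prof)
write.table(cors, "results/glycan_taxa_correlation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# composition of the glycan-degrading community, samples ordered by size
ord <- clinical$patient_id[order(clinical$tumor_size_cm)]
png("results/glycan_taxa_composition.png", width = 900, height = 450)
barplot(prof$values[, ord], col = seq_len(nrow(prof$values)) + 1,
        border = NA, las = 2, cex.names = 0.6,
        ylab = "fraction of pathway-encoding contig mass",
        main = "Glycan degradation: representative taxa (samples by tumor size)")
legend("topleft", legend = rownames(prof$values), bty = "n", cex = 0.8,
       fill = seq_len(nrow(prof$values)) + 1)
invisible(dev.off())

sel <- dtaxa[dtaxa$selected, ]
cat(sprintf("%d of %d orders differentially abundant:\n", nrow(sel), nrow(dtaxa)))
print(sel[, c("taxon", "fisher_p", "mw_p", "direction")], row.names = FALSE,
      digits = 3)
lt <- groups$patient_id[groups$group == "LT"]
st <- groups$patient_id[groups$group == "ST"]
cat(sprintf("Glycan-degrading contig mass carried by Clostridiales: %.0f%% in LT vs %.0f%% in ST samples\n",
            100 * mean(prof$values["Clostridiales", lt]),
            100 * mean(prof$values["Clostridiales", st])))
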