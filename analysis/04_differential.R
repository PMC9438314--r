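#!/usr/bin/env Rscript
# Supervised comparison: the 14 largest-tumor (LT) vs 14 smallest-tumor
# (ST) patients; every KO found in at least one sample is tested by
# Fisher's exact presence test and a Mann-Whitney abundance test,
# unadjusted p < 0.05 on either selecting the KO.

library(mucometa)

norm <- read_mfa("results/mfa_normalized.tsv")
clinical <- read_clinical("results/cohort/clinical.csv")

groups <- assign_size_groups(clinical, k = 14L)
diff <- differential_kos(norm, groups, alpha = 0.05)

write.table(groups, "results/size_groups.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(diff, "results/differential_kos.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

n_sel <- sum(diff$selected)
n_lt <- sum(diff$selected & diff$direction == "LT", na.rm = TRUE)
cat(sprintf("Tested %d KOs; %d differentially abundant (%d%% LT-enriched)\n",
            nrow(diff), n_sel, round(100 * n_lt / n_sel)))
cat(sprintf("Group tumor sizes: LT %.1f-%.1f cm, ST %.1f-%.1f cm\n",
            min(groups$tumor_size_cm[groups$group == "LT"]),
            max(groups$tumor_size_cm[groups$group == "LT"]),
            min(groups$tumor_size_cm[groups$group == "ST"]),
            max(groups$tumor_size_cm[groups$group == "ST"])))
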