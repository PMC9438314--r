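#!/usr/bin/env Rscript
# Recurrence-free survival: pathway activity scores categorized at the
# first quartile (Low vs High), Kaplan-Meier curves with log-rank
# tests, and univariate Cox models for pathway activities and clinical
# covariates.

library(mucometa)

clinical <- read_clinical("results/cohort/clinical.csv")
activity <- read.delim("results/pathway_activity.tsv", check.names = FALSE,
                       stringsAsFactors = FALSE)
pathways <- setdiff(names(activity), "patient_id")

rows <- list()
png("results/km_curves.png", width = 1200, height = 300 * ceiling(length(pathways) / 3))
op <- par(mfrow = c(ceiling(length(pathways) / 3), 3))
for (p in pathways) {
  score <- setNames(activity[[p]], activity$patient_id)
  labels <- categorize_score(score)
  km <- km_logrank(labels, clinical)
  cox <- cox_ph(data.frame(patient_id = names(score), activity = score),
                clinical)
  rows[[p]] <- data.frame(pathway = p, logrank_p = km$p, hr = cox$hr,
                          ci_lower = cox$ci_lower, ci_upper = cox$ci_upper,
                          cox_p = cox$p)
  plot(km$fit, col = c("firebrick", "steelblue"), lwd = 2,
       xlab = "months", ylab = "RFS probability",
       main = sprintf("%s (log-rank p = %.2g)", p, km$p))
  legend("bottomleft", c("High activity", "Low activity"),
         col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
}
par(op)
invisible(dev.off())

# clinical covariates, categorized per the fixed cut-offs
cats <- categorize_clinical(clinical)
for (v in c("age_cat", "tumor_size_cat", "bmi_cat", "stage_cat", "node_cat")) {
  cov <- data.frame(patient_id = cats$patient_id, x = cats[[v]])
  names(cov)[2] <- v
  cox <- cox_ph(cov, clinical)
  km <- km_logrank(setNames(cats[[v]], cats$patient_id), clinical)
  rows[[v]] <- data.frame(pathway = v, logrank_p = km$p, hr = cox$hr,
                          ci_lower = cox$ci_lower, ci_upper = cox$ci_upper,
                          cox_p = cox$p)
}

res <- do.call(rbind, rows)
write.table(res, "results/survival.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("RFS associations (activity scores and clinical categories):\n")
print(res, row.names = FALSE, digits = 3)
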