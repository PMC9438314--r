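lineage4 <- function(order, family = "F1", genus = "G1", species = "S1",
                     phylum = "P1", class = "C1") {
  paste("Bacteria", phylum, class, order, family, genus, species, sep = ";")
}

test_that("taxon abundance is normalized contig length x depth mass", {
  # a lone contig owns its sample
  df <- make_contigs("s1", NA_character_, 0L, length_bp = 2000L, depth = 3,
                     lineage = lineage4("O1"))
  otu <- taxa_abundance(df, rank = "order")
  expect_equal(unname(otu$values["O1", "s1"]), 1.0)

  # 2000x3 + 1000x6 for one order vs 4000x3 for another: 0.5 each
  df2 <- make_contigs(rep("s1", 3), NA_character_, 0L,
                      length_bp = c(2000L, 1000L, 4000L),
                      depth = c(3, 6, 3),
                      lineage = c(lineage4("O1"), lineage4("O1"),
                                  lineage4("O2")))
  otu2 <- taxa_abundance(df2, rank = "order")
  expect_equal(unname(otu2$values["O1", "s1"]), 0.5)
  expect_equal(unname(otu2$values["O2", "s1"]), 0.5)

  # columns sum to one on a full synthetic cohort
  co <- small_cohort(seed = 14)
  otu3 <- taxa_abundance(co, rank = "order")
  expect_true(all(abs(colSums(otu3$values) - 1) < 1e-9))
  expect_true(all(otu3$values >= 0))

  # a contig carrying several genes enters the mass once
  multi <- df2
  extra <- df2[1, ]
  extra$gene_id <- "s1_c001_g2"
  multi <- rbind(multi, extra)
  expect_equal(taxa_abundance(multi, rank = "order")$values,
               otu2$values)

  expect_error(taxa_abundance(make_contigs("s1", NA_character_, 0L,
                                           depth = 0)), "zero total")
})

test_that("coarser ranks aggregate their child-rank abundances", {
  co <- small_cohort(seed = 16)
  fam <- taxa_abundance(co, rank = "family")$values
  ord <- taxa_abundance(co, rank = "order")$values
  # map each family row to its parent order via the cohort's lineages
  uc <- unique(co$contigs[, c("lineage")])
  parts <- strsplit(uc, ";", fixed = TRUE)
  fam_of <- vapply(parts, `[`, "", 5)
  ord_of <- vapply(parts, `[`, "", 4)
  fam_of[fam_of == "NA"] <- "unclassified"
  ord_of[ord_of == "NA"] <- "unclassified"
  lut <- unique(data.frame(fam = fam_of, ord = ord_of))
  rolled <- rowsum(fam, lut$ord[match(rownames(fam), lut$fam)])
  expect_equal(rolled[rownames(ord), ], ord, tolerance = 1e-12)
})

test_that("differential taxa route rare to Fisher and common to Mann-Whitney", {
  samples <- sprintf("s%02d", 1:28)
  groups <- setNames(rep(c("LT", "ST"), each = 14), samples)
  v <- rbind(
    rare_st = c(rep(0, 14), rep(0, 2), rep(0.2, 12)) / 10, # in 12/28 samples
    common = c(rnorm(14, 0.6, 0.02), rnorm(14, 0.4, 0.02)),
    flat = rep(0.3, 28)
  )
  colnames(v) <- samples
  otu <- structure(list(values = v, rank = "order"), class = "otu_matrix")
  d <- differential_taxa(otu, groups)
  rare <- d[d$taxon == "rare_st", ]
  expect_false(is.na(rare$fisher_p))
  expect_true(is.na(rare$mw_p))
  expect_equal(rare$direction, "ST")
  expect_equal(rare$fisher_p, fisher_enum_p(0, 14, 12, 2), tolerance = 1e-9)
  common <- d[d$taxon == "common", ]
  expect_true(is.na(common$fisher_p))
  expect_equal(common$direction, "LT")
  expect_false(d$selected[d$taxon == "flat"])
})

test_that("the planted small-tumor order is detected ST-directional", {
  hits <- sapply(1:20, function(s) {
    co <- small_cohort(seed = 700 + s)
    otu <- taxa_abundance(co, rank = "order")
    d <- differential_taxa(otu, assign_size_groups(co$clinical))
    row <- d[d$taxon == "Bacteroidales", ]
    nrow(row) == 1 && !is.na(row$direction) && row$direction == "ST"
  })
  expect_gte(mean(hits), 0.9)
})

test_that("pathway taxa profiles cover only pathway-encoding contigs", {
  df <- rbind(
    make_contigs("s1", c("K1", NA), c(5L, 0L),
                 length_bp = c(2000L, 3000L), depth = c(2, 9),
                 lineage = c(lineage4("O1"), lineage4("O2"))),
    make_contigs("s2", c(NA_character_), 0L, depth = 4,
                 lineage = lineage4("O2"))
  )
  expect_warning(prof <- pathway_taxa_profile(df, "K1", rank = "order"), "s2")
  expect_equal(unname(prof$values["O1", "s1"]), 1.0)
  expect_equal(unname(prof$values[, "s2"]),
               rep(0, nrow(prof$values)))
  expect_error(pathway_taxa_profile(df, character()), "empty")

  # subset property under the whole-sample denominator: selected-contig
  # mass can never exceed the taxon's total mass
  co <- small_cohort(seed = 26)
  pm <- co$truth$pathway_map
  kos <- pm$ko_id[pm$pathway_id == "glycan_degradation"]
  hit <- co$contigs[!is.na(co$contigs$ko_id) & co$contigs$ko_id %in% kos, ]
  full <- taxa_abundance(co, rank = "order")
  hit_order <- vapply(strsplit(hit$lineage, ";", fixed = TRUE), `[`, "", 4)
  hit_order[hit_order == "NA"] <- "unclassified"
  sel_mass <- tapply(hit$length_bp * hit$depth,
                     list(factor(hit_order, levels = rownames(full$values)),
                          factor(hit$sample_id, levels = colnames(full$values))),
                     sum, default = 0)
  uc <- unique(co$contigs[, c("sample_id", "contig_id", "length_bp", "depth")])
  tot_mass <- tapply(uc$length_bp * uc$depth,
                     factor(uc$sample_id, levels = colnames(full$values)),
                     sum)
  sel_rel <- sweep(sel_mass, 2, tot_mass, `/`)
  expect_true(all(sel_rel <= full$values + 1e-12))

  # the planted mucus-degrading order dominates the pathway in LT samples
  prof2 <- pathway_taxa_profile(co, kos, rank = "order")
  g <- assign_size_groups(co$clinical)
  lt <- g$patient_id[g$group == "LT"]
  expect_gt(mean(prof2$values["Clostridiales", lt]), 0.5)
})

test_that("pathway-taxa correlations match the closed-form Pearson", {
  set.seed(30)
  scores <- setNames(rnorm(10), paste0("s", 1:10))
  v <- rbind(prop = 2 * scores + 5,
             noise = runif(10),
             const = rep(0.2, 10))
  colnames(v) <- names(scores)
  prof <- structure(list(values = v, rank = "order"), class = "otu_matrix")
  res <- correlate_pathway_taxa(scores, prof)
  expect_equal(res$r[res$taxon == "prop"], 1.0, tolerance = 1e-12)
  expect_equal(res$r[res$taxon == "noise"],
               pearson_closed_form(v["noise", ], scores), tolerance = 1e-12)
  expect_true(res$undefined[res$taxon == "const"])
  expect_true(is.na(res$r[res$taxon == "const"]))
  expect_error(correlate_pathway_taxa(scores[1:2], prof), "3")
})
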