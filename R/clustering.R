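# Unsupervised hierarchical clustering of the transformed MFA table.
# Distance is 1 - Pearson correlation with average linkage on both axes
# (the defaults of the Cluster 3.0 lineage of expression-clustering
# tools); sub-clusters are a second cut of the same trees.

#' Hierarchically cluster KOs and samples
#'
#' Agglomerative clustering (average linkage on correlation distance) on
#' both axes of a log2-centered MFA table, with each tree cut at a
#' requested number of clusters. Deterministic for fixed input and
#' invariant to row/column input order.
#'
#' @param mfa a `log2centered` (or otherwise complete, numeric)
#'   `mfa_table` with at least 2 rows and 2 columns.
#' @param n_sample_clusters clusters for the sample axis (default 2; the
#'   sub-cluster view of the same tree uses 4).
#' @param n_ko_clusters clusters for the KO axis (default 2).
#' @param method linkage method passed to [stats::hclust()].
#' @return object of class `cluster_assignment`: named cluster labels
#'   `sample_clusters` and `ko_clusters`, and the two `hclust` trees
#'   (`sample_tree`, `ko_tree`).
#' @export
hierarchical_cluster <- function(mfa, n_sample_clusters = 2L,
                                 n_ko_clusters = 2L, method = "average") {
  stopifnot(inherits(mfa, "mfa_table"))
  v <- mfa$values
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("clustering needs at least 2 KOs and 2 samples")
  if (anyNA(v)) stop("clustering requires a complete table (no NAs)")
  if (any(apply(v, 1, sd) == 0) || any(apply(v, 2, sd) == 0))
    stop("degenerate distance: constant KO row(s) or sample column(s)")
  cor_dist <- function(m) as.dist(1 - cor(m))
  sample_tree <- hclust(cor_dist(v), method = method)
  ko_tree <- hclust(cor_dist(t(v)), method = method)
  structure(list(
    sample_clusters = cutree(sample_tree, k = n_sample_clusters),
    ko_clusters = cutree(ko_tree, k = n_ko_clusters),
    sample_tree = sample_tree, ko_tree = ko_tree
  ), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("Cluster assignment: %d samples in %d clusters, %d KOs in %d clusters\n",
              length(x$sample_clusters), length(unique(x$sample_clusters)),
              length(x$ko_clusters), length(unique(x$ko_clusters))))
  invisible(x)
}

#' Associate sample clusters with clinical variables
#'
#' Compares the two main sample clusters (the sample tree cut at k = 2,
#' regardless of the stored cut): continuous variables (age, BMI, tumor
#' size) by two-sided rank-sum, categorical ones (FIGO stage I/II vs
#' III/IV, nodal status) by Fisher's exact test. P-values are invariant
#' to cluster relabeling.
#'
#' @param assignment a [hierarchical_cluster()] result.
#' @param clinical clinical table covering all clustered samples.
#' @return data.frame `variable`, `test` (`"wilcoxon"`/`"fisher"`), `p`.
#' @export
cluster_clinical_association <- function(assignment, clinical) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  cl <- cutree(assignment$sample_tree, k = 2L)
  missing <- setdiff(names(cl), clinical$patient_id)
  if (length(missing))
    stop("clinical table lacks clustered samples: ",
         paste(missing, collapse = ", "))
  if (length(unique(cl)) < 2L) stop("only one sample cluster")
  clinical <- clinical[match(names(cl), clinical$patient_id), ]
  in1 <- cl == 1L
  cont <- function(x) .mw_test(x[in1], x[!in1])
  cat2 <- function(x) fisher.test(table(factor(in1, c(TRUE, FALSE)),
                                        factor(x)))$p.value
  advanced <- clinical$stage %in% c("III", "IV")
  data.frame(
    variable = c("age", "bmi", "tumor_size_cm", "stage_III_IV", "node_positive"),
    test = c("wilcoxon", "wilcoxon", "wilcoxon", "fisher", "fisher"),
    p = c(cont(clinical$age), cont(clinical$bmi), cont(clinical$tumor_size_cm),
          if (length(unique(advanced)) == 2L) cat2(advanced) else NA_real_,
          if (length(unique(clinical$node_positive)) == 2L)
            cat2(clinical$node_positive) else NA_real_),
    stringsAsFactors = FALSE
  )
}

#' Overlap of KO clusters with pathways
#'
#' Counts each (KO cluster, pathway) overlap among the clustered KOs and
#' reports the hypergeometric over-representation p-value (probability
#' of at least the observed overlap when drawing the cluster from the
#' clustered-KO universe).
#'
#' @param assignment a [hierarchical_cluster()] result.
#' @param map pathway map data.frame (`pathway_id`, `ko_id`).
#' @return data.frame `ko_cluster`, `pathway_id`, `overlap`,
#'   `cluster_size`, `pathway_in_universe`, `p`.
#' @export
ko_cluster_pathway_overlap <- function(assignment, map) {
  stopifnot(inherits(assignment, "cluster_assignment"))
  universe <- names(assignment$ko_clusters)
  pw <- lapply(split(map$ko_id, map$pathway_id),
               function(k) intersect(unique(k), universe))
  rows <- list()
  for (cl in sort(unique(assignment$ko_clusters))) {
    members <- universe[assignment$ko_clusters == cl]
    for (p in names(pw)) {
      ov <- length(intersect(pw[[p]], members))
      m <- length(pw[[p]])
      rows[[length(rows) + 1L]] <- data.frame(
        ko_cluster = cl, pathway_id = p, overlap = ov,
        cluster_size = length(members), pathway_in_universe = m,
        p = phyper(ov - 1L, m, length(universe) - m, length(members),
                   lower.tail = FALSE),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
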