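# Taxon quantification from assembled contigs. A contig's read mass is
# approximated by length x mean depth; taxa are quantified by summing
# that mass over contigs sharing the taxon at a chosen rank and
# normalizing within the sample.

.ranks <- c("superkingdom", "phylum", "class", "order", "family",
            "genus", "species")

# positional rank extraction on the fixed 7-rank semicolon dialect
.lineage_at_rank <- function(lineage, rank) {
  i <- match(rank, .ranks)
  if (is.na(i)) stop("unknown rank: ", rank, " (use one of ",
                     paste(.ranks, collapse = ", "), ")")
  parts <- strsplit(lineage, ";", fixed = TRUE)
  out <- vapply(parts, function(p) if (length(p) >= i) p[i] else NA_character_, "")
  out[is.na(out) | out == "NA" | out == ""] <- "unclassified"
  out
}

# one row per (sample, contig): contigs enter the mass sum once even
# when they carry several genes
.unique_contigs <- function(contigs) {
  unique(contigs[, c("sample_id", "contig_id", "length_bp", "depth", "lineage")])
}

.mass_table <- function(uc, rank) {
  taxon <- .lineage_at_rank(uc$lineage, rank)
  mass <- uc$length_bp * uc$depth
  agg <- stats::aggregate(mass,
                          by = list(taxon = taxon, sample_id = uc$sample_id),
                          FUN = sum)
  taxa <- sort(unique(agg$taxon))
  samples <- sort(unique(uc$sample_id))
  values <- matrix(0, length(taxa), length(samples),
                   dimnames = list(taxa, samples))
  values[cbind(match(agg$taxon, taxa), match(agg$sample_id, samples))] <- agg$x
  values
}

#' Taxon abundances from contig length x depth
#'
#' For each sample, every contig contributes `length_bp * depth` to its
#' taxon at the requested rank (unassigned ranks pool into
#' `"unclassified"`); taxon masses are normalized by the sample's total
#' mass over all contigs, so columns sum to 1.
#'
#' @param contigs per-gene annotation table or a `mucometa_cohort`.
#' @param rank one of superkingdom, phylum, class, order (default),
#'   family, genus, species.
#' @return object of class `otu_matrix`: a list with `values` (taxon x
#'   sample relative abundances) and `rank`.
#' @export
taxa_abundance <- function(contigs, rank = "order") {
  if (inherits(contigs, "mucometa_cohort")) contigs <- contigs$contigs
  uc <- .unique_contigs(contigs)
  values <- .mass_table(uc, rank)
  totals <- colSums(values)
  if (any(totals == 0))
    stop("zero total contig mass in sample(s): ",
         paste(colnames(values)[totals == 0], collapse = ", "))
  structure(list(values = sweep(values, 2, totals, `/`), rank = rank),
            class = "otu_matrix")
}

#' @export
print.otu_matrix <- function(x, ...) {
  cat(sprintf("OTU table at rank %s: %d taxa x %d samples\n",
              x$rank, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Differentially abundant taxa between tumor-size groups
#'
#' The KO differential machinery applied to OTU rows, with rare taxa
#' (prevalence below `rare_threshold` of included samples) routed to
#' Fisher's exact presence/absence test and common taxa to the
#' Mann-Whitney abundance test, each at unadjusted `alpha`.
#'
#' @param otu an `otu_matrix` from [taxa_abundance()].
#' @param groups an [assign_size_groups()] result.
#' @param alpha unadjusted cutoff (default 0.05).
#' @param rare_threshold prevalence fraction separating rare from common
#'   taxa (default 0.5).
#' @return data.frame as [differential_kos()], keyed by `taxon`.
#' @export
differential_taxa <- function(otu, groups, alpha = 0.05, rare_threshold = 0.5) {
  stopifnot(inherits(otu, "otu_matrix"))
  g <- .group_samples(groups)
  .two_group_tests(otu$values, g$lt, g$st, alpha = alpha,
                   route = "prevalence", rare_threshold = rare_threshold,
                   id_name = "taxon")
}

#' Taxa representing a pathway's enzymes
#'
#' Restricts the mass computation to contigs carrying at least one gene
#' annotated with a pathway KO; the unique taxa of those contigs are the
#' pathway's representative taxa, and their masses are normalized within
#' the selected-contig subtotal of each sample. Samples with no
#' pathway-encoding contig get an all-zero column (with a warning).
#'
#' @param contigs per-gene annotation table or a `mucometa_cohort`.
#' @param pathway_kos non-empty character vector of KO ids.
#' @param rank taxonomic rank (default `"order"`).
#' @return an `otu_matrix` of within-pathway taxon composition.
#' @export
pathway_taxa_profile <- function(contigs, pathway_kos, rank = "order") {
  if (inherits(contigs, "mucometa_cohort")) contigs <- contigs$contigs
  if (!length(pathway_kos)) stop("pathway KO set is empty")
  hit <- contigs[!is.na(contigs$ko_id) & contigs$ko_id %in% pathway_kos, ,
                 drop = FALSE]
  all_samples <- sort(unique(contigs$sample_id))
  if (!nrow(hit))
    stop("no contig encodes any of the supplied pathway KOs")
  keys <- unique(paste(hit$sample_id, hit$contig_id))
  sel <- contigs[paste(contigs$sample_id, contigs$contig_id) %in% keys, ,
                 drop = FALSE]
  values <- .mass_table(.unique_contigs(sel), rank)
  missing <- setdiff(all_samples, colnames(values))
  if (length(missing)) {
    warning("no pathway-encoding contigs in sample(s): ",
            paste(missing, collapse = ", "), "; all-zero column(s)")
    values <- cbind(values,
                    matrix(0, nrow(values), length(missing),
                           dimnames = list(rownames(values), missing)))
    values <- values[, sort(colnames(values)), drop = FALSE]
  }
  totals <- colSums(values)
  nz <- totals > 0
  values[, nz] <- sweep(values[, nz, drop = FALSE], 2, totals[nz], `/`)
  structure(list(values = values, rank = rank), class = "otu_matrix")
}

#' Correlate a pathway activity score with representative taxa
#'
#' Pearson correlation (two-sided) of each taxon's abundance profile
#' against the per-sample score. Zero-variance taxa are flagged
#' undefined (`NA` correlation).
#'
#' @param scores named per-sample numeric vector (e.g.
#'   [activity_score()]).
#' @param profile an `otu_matrix` whose samples cover `names(scores)`.
#' @return data.frame `taxon`, `r`, `p`, `undefined`.
#' @export
correlate_pathway_taxa <- function(scores, profile) {
  stopifnot(inherits(profile, "otu_matrix"))
  samples <- intersect(names(scores), colnames(profile$values))
  if (length(samples) < 3L)
    stop("correlation needs at least 3 shared samples")
  s <- scores[samples]
  rows <- lapply(rownames(profile$values), function(tx) {
    a <- profile$values[tx, samples]
    if (sd(a) == 0 || sd(s) == 0)
      return(data.frame(taxon = tx, r = NA_real_, p = NA_real_,
                        undefined = TRUE, stringsAsFactors = FALSE))
    ct <- cor.test(a, s, method = "pearson")
    data.frame(taxon = tx, r = unname(ct$estimate), p = ct$p.value,
               undefined = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
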