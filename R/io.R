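# Plain-text I/O for the pipeline's tabular dialects. All tables are
# tab-separated (clinical is CSV) with a header row; lineages use a fixed
# 7-rank semicolon string (superkingdom;phylum;class;order;family;genus;
# species) with "NA" at unassigned ranks.

.contig_cols <- c("sample_id", "contig_id", "length_bp", "depth", "lineage",
                  "gene_id", "ko_id", "read_count")

#' Read a per-gene contig annotation table
#'
#' One row per predicted gene: sample, contig, contig length (bp), contig
#' mean read depth, 7-rank lineage, gene id, KO id (`NA` when the gene has
#' no functional annotation) and mapped-read count.
#'
#' @param path TSV file written by [write_cohort()] or an upstream
#'   annotation pipeline using the same columns.
#' @return a data.frame with the 8 annotation columns.
#' @export
read_contigs <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(ko_id = "character"))
  missing <- setdiff(.contig_cols, names(x))
  if (length(missing))
    stop("contig annotation table lacks columns: ", paste(missing, collapse = ", "))
  x$ko_id[x$ko_id %in% c("", "NA")] <- NA_character_
  x[, .contig_cols]
}

#' Read the clinical table
#'
#' @param path CSV with columns `patient_id`, `age`, `bmi`, `stage`
#'   (FIGO I--IV), `tumor_size_cm`, `node_positive`, `rfs_months`,
#'   `rfs_event`, and optionally `total_reads`.
#' @return a data.frame.
#' @export
read_clinical <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "bmi", "stage", "tumor_size_cm",
            "node_positive", "rfs_months", "rfs_event")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("clinical table lacks columns: ", paste(missing, collapse = ", "))
  x$node_positive <- as.logical(x$node_positive)
  x$rfs_event <- as.logical(x$rfs_event)
  x
}

#' Write a synthetic cohort to disk
#'
#' Writes `contigs.tsv` (per-gene annotations), `clinical.csv`, and the
#' latent ground truth as `truth.json`.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mucometa_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(cohort$contigs, file.path(dir, "contigs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  truth <- cohort$truth
  truth$params <- unclass(truth$params)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read / write an MFA table
#'
#' The TSV layout is KO rows by sample columns with a `ko_id` first column;
#' a sidecar `<stem>.meta.tsv` carries the per-sample total read counts and
#' the processing stage.
#'
#' @param mfa an [mfa_table()] object.
#' @param path path to the main TSV.
#' @return `write_mfa()`: `path`, invisibly. `read_mfa()`: an `mfa_table`.
#' @export
write_mfa <- function(mfa, path) {
  stopifnot(inherits(mfa, "mfa_table"))
  df <- data.frame(ko_id = rownames(mfa$values), mfa$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- data.frame(sample_id = colnames(mfa$values),
                     total_reads = if (is.null(mfa$total_reads)) NA
                                   else mfa$total_reads[colnames(mfa$values)],
                     stage = mfa$stage, stringsAsFactors = FALSE)
  write.table(meta, sub("(\\.tsv)?$", ".meta.tsv", path, perl = TRUE)[1],
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mfa
#' @export
read_mfa <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$ko_id
  meta_path <- sub("(\\.tsv)?$", ".meta.tsv", path, perl = TRUE)[1]
  total_reads <- NULL
  stage <- "raw"
  if (file.exists(meta_path)) {
    meta <- read.delim(meta_path, stringsAsFactors = FALSE)
    stage <- meta$stage[1]
    if (!all(is.na(meta$total_reads)))
      total_reads <- setNames(meta$total_reads, meta$sample_id)
  }
  mfa_table(values, total_reads = total_reads, stage = stage)
}
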