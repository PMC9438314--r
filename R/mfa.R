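# The Metagenome Function Abundance (MFA) table: KO x sample read counts
# summed over all genes carrying the function, ignoring which organism
# carries them; genes without a KO annotation are ignored.

#' Construct an MFA table object
#'
#' @param values numeric KO x sample matrix with row and column names.
#' @param total_reads optional named per-sample total sequenced read
#'   counts (the normalization denominator; includes reads outside
#'   annotated functions).
#' @param stage one of `"raw"`, `"normalized"`, `"log2centered"`.
#' @return an object of class `mfa_table`.
#' @export
mfa_table <- function(values, total_reads = NULL,
                      stage = c("raw", "normalized", "log2centered")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("mfa_table values need KO rownames and sample colnames")
  if (stage != "log2centered" && any(values < 0))
    stop("raw/normalized MFA entries must be non-negative")
  if (!is.null(total_reads)) {
    if (is.null(names(total_reads)))
      stop("total_reads must be named by sample")
    missing <- setdiff(colnames(values), names(total_reads))
    if (length(missing))
      stop("total_reads missing for samples: ", paste(missing, collapse = ", "))
    total_reads <- total_reads[colnames(values)]
  }
  structure(list(values = values, total_reads = total_reads, stage = stage),
            class = "mfa_table")
}

#' @export
print.mfa_table <- function(x, ...) {
  cat(sprintf("MFA table (%s): %d KOs x %d samples\n",
              x$stage, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.mfa_table <- function(x) dim(x$values)

#' Build the raw MFA table from per-gene contig annotations
#'
#' Cell (KO k, sample s) is the total number of mapped reads over all
#' genes in sample s annotated with k. Genes without a KO annotation are
#' ignored; KOs not observed in a sample are 0.
#'
#' @param contigs per-gene annotation table (see [read_contigs()]); a
#'   `mucometa_cohort` is also accepted.
#' @param total_reads optional named per-sample total sequenced reads,
#'   attached for later normalization.
#' @return an `mfa_table` with `stage = "raw"`.
#' @export
build_mfa <- function(contigs, total_reads = NULL) {
  if (inherits(contigs, "mucometa_cohort")) {
    if (is.null(total_reads))
      total_reads <- setNames(contigs$clinical$total_reads,
                              contigs$clinical$patient_id)
    contigs <- contigs$contigs
  }
  if (anyDuplicated(contigs[, c("sample_id", "gene_id")]))
    stop("duplicate (sample_id, gene_id) pairs in annotation table")
  if (any(contigs$read_count < 0, na.rm = TRUE))
    stop("negative read_count in annotation table")
  samples <- sort(unique(contigs$sample_id))
  ann <- contigs[!is.na(contigs$ko_id), , drop = FALSE]
  if (any(is.na(ann$read_count)))
    stop("KO-annotated gene with missing read_count")
  kos <- sort(unique(ann$ko_id))
  values <- matrix(0, length(kos), length(samples),
                   dimnames = list(kos, samples))
  if (nrow(ann)) {
    agg <- stats::aggregate(read_count ~ ko_id + sample_id, data = ann, FUN = sum)
    values[cbind(match(agg$ko_id, kos), match(agg$sample_id, samples))] <-
      agg$read_count
  }
  mfa_table(values, total_reads = total_reads, stage = "raw")
}

#' Normalize an MFA table to counts per million sequenced reads
#'
#' Each raw entry is scaled by `1e6 / total_reads(sample)`; zeros are
#' preserved.
#'
#' @param mfa a raw `mfa_table`.
#' @param total_reads named per-sample totals; defaults to the totals
#'   stored in `mfa`.
#' @return an `mfa_table` with `stage = "normalized"`.
#' @export
normalize_mfa <- function(mfa, total_reads = NULL) {
  stopifnot(inherits(mfa, "mfa_table"))
  if (mfa$stage != "raw")
    stop("normalize_mfa expects a raw MFA table, got stage ", mfa$stage)
  if (is.null(total_reads)) total_reads <- mfa$total_reads
  if (is.null(total_reads))
    stop("no total_reads available for normalization")
  missing <- setdiff(colnames(mfa$values), names(total_reads))
  if (length(missing))
    stop("total_reads missing for samples: ", paste(missing, collapse = ", "))
  total_reads <- total_reads[colnames(mfa$values)]
  bad <- names(total_reads)[total_reads <= 0]
  if (length(bad))
    stop("non-positive total_reads for sample(s): ", paste(bad, collapse = ", "))
  values <- sweep(mfa$values, 2, 1e6 / total_reads, `*`)
  mfa_table(values, total_reads = total_reads, stage = "normalized")
}

#' Keep KOs found in at least a given number of samples
#'
#' "Found" means a strictly nonzero entry. The default of 30 samples is
#' the prevalence filter applied before unsupervised clustering.
#'
#' @param mfa an `mfa_table` (any stage with non-negative values).
#' @param min_samples minimum number of samples a KO must be found in.
#' @return the filtered `mfa_table` (possibly with zero rows).
#' @export
filter_prevalent <- function(mfa, min_samples = 30L) {
  stopifnot(inherits(mfa, "mfa_table"))
  if (min_samples < 1L) stop("min_samples must be >= 1")
  keep <- rowSums(mfa$values != 0) >= min_samples
  mfa_table(mfa$values[keep, , drop = FALSE],
            total_reads = mfa$total_reads, stage = mfa$stage)
}

#' Log2-transform and median-center an MFA table
#'
#' Entries become `log2(value + pseudocount)`; each KO row (or sample
#' column) is then centered by subtracting its median, so output row (or
#' column) medians are 0. Row centering is the default, as clustering
#' heatmaps center the gene/KO axis.
#'
#' @param mfa a normalized `mfa_table`.
#' @param pseudocount non-negative offset added before the log; 0 is
#'   allowed when the caller guarantees strictly positive entries.
#' @param center `"ko"` (rows, default), `"sample"` (columns), or
#'   `"none"`.
#' @return an `mfa_table` with `stage = "log2centered"`.
#' @export
log2_center <- function(mfa, pseudocount = 1, center = c("ko", "sample", "none")) {
  stopifnot(inherits(mfa, "mfa_table"))
  center <- match.arg(center)
  if (mfa$stage != "normalized")
    stop("log2_center expects a normalized MFA table, got stage ", mfa$stage)
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (pseudocount == 0 && any(mfa$values <= 0))
    stop("pseudocount = 0 requires strictly positive entries")
  x <- log2(mfa$values + pseudocount)
  if (center == "ko") {
    x <- x - apply(x, 1, median)
  } else if (center == "sample") {
    x <- sweep(x, 2, apply(x, 2, median))
  }
  mfa_table(x, total_reads = mfa$total_reads, stage = "log2centered")
}
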