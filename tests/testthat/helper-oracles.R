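# Independent oracles and small fixture builders shared across tests.

# Two-sided Fisher exact p by direct hypergeometric enumeration over the
# table's support (minimum-likelihood rule): sums the point masses of all
# tables with the same margins whose probability does not exceed the
# observed table's.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  sum(probs[probs <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

# Closed-form Pearson correlation from the covariance formula.
pearson_closed_form <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (stats::sd(x) * stats::sd(y))
}

# Rand index between two partitions (pair-counting agreement).
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      agree <- agree + ((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  agree / choose(n, 2)
}

# A tiny hand-built per-gene annotation table.
make_contigs <- function(sample_id, ko_id, read_count,
                         length_bp = 2000L, depth = 1,
                         lineage = "Bacteria;NA;NA;NA;NA;NA;NA") {
  df <- data.frame(sample_id = sample_id, ko_id = ko_id,
                   read_count = read_count, length_bp = length_bp,
                   depth = depth, lineage = lineage,
                   stringsAsFactors = FALSE)
  idx <- stats::ave(seq_len(nrow(df)), df$sample_id, FUN = seq_along)
  df$contig_id <- sprintf("%s_c%03d", df$sample_id, idx)
  df$gene_id <- paste0(df$contig_id, "_g1")
  df[, c("sample_id", "contig_id", "length_bp", "depth", "lineage",
         "gene_id", "ko_id", "read_count")]
}

# Normalized MFA table straight from a numeric matrix (total_reads 1e6,
# so normalized values equal the raw ones).
mfa_from_matrix <- function(values, stage = "normalized") {
  mfa_table(values,
            total_reads = setNames(rep(1e6, ncol(values)), colnames(values)),
            stage = stage)
}

# A small default synthetic cohort (full patient count, reduced KO
# repertoire) for unit tests that only need realistic structure.
small_cohort <- function(seed = 1, ...) {
  generate_cohort(cohort_params(seed = seed, n_kos_per_community = 60L, ...))
}

# Dominance-corrected recovery of a community's profile: per-KO mean of
# log2 normalized abundance minus the known dominance shift, over
# nonzero entries, summarized by fit_group_normal.
recover_profile <- function(cohort, community = "A") {
  norm <- normalize_mfa(build_mfa(cohort))
  comm <- cohort$truth$ko_community
  kos <- intersect(names(comm)[comm == community], rownames(norm$values))
  w <- cohort$truth$w_A[colnames(norm$values)]
  wc <- if (community == "A") w else 1 - w
  shift <- log2(2 * wc)
  v <- norm$values[kos, , drop = FALSE]
  m <- apply(v, 1, function(row) {
    nz <- row > 0
    if (!any(nz)) return(NA_real_)
    mean(log2(row[nz]) - shift[nz])
  })
  fit_group_normal(m[!is.na(m)])
}

# Fixed normal curve without going through data.
curve_of <- function(mu, sigma, source = NA_character_) {
  structure(list(mu = mu, sigma = sigma, n = 0L, source = source),
            class = "normal_curve")
}
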