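# Tumor-size groups and differential abundance.
#
# The comparison contrasts the 14 patients with the largest tumors
# (LT-group) against the 14 with the smallest (ST-group). Every feature
# found in at least one included sample is tested twice: Fisher's exact
# test on presence/absence and a two-sided Mann-Whitney test on
# abundances; a feature is selected when either unadjusted p-value falls
# below alpha. Direction follows the presence test when it is
# significant, otherwise the abundance-mean difference.

#' Assign largest/smallest tumor groups
#'
#' Sorts patients by tumor size (descending, ties broken by ascending
#' patient id) and labels the top `k` as `"LT"`, the bottom `k` as
#' `"ST"`, and the remainder `"unassigned"`.
#'
#' @param clinical clinical table with `patient_id` and `tumor_size_cm`.
#' @param k group size; `2k` must not exceed the number of patients.
#' @return data.frame with `patient_id`, `tumor_size_cm`, and `group`.
#' @export
assign_size_groups <- function(clinical, k = 14L) {
  n <- nrow(clinical)
  if (2L * k > n)
    stop("2k = ", 2L * k, " exceeds the number of patients (", n, ")")
  ord <- order(-clinical$tumor_size_cm, clinical$patient_id)
  group <- rep("unassigned", n)
  group[ord[seq_len(k)]] <- "LT"
  group[ord[seq.int(n - k + 1L, n)]] <- "ST"
  data.frame(patient_id = clinical$patient_id,
             tumor_size_cm = clinical$tumor_size_cm,
             group = group, stringsAsFactors = FALSE)
}

# Mann-Whitney: exact only for small tie-free groups, otherwise the
# normal approximation with continuity and tie correction.
.mw_test <- function(x, y) {
  if (length(unique(c(x, y))) == 1L) return(1)  # identical data: no signal
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && max(length(x), length(y)) <= 12L
  suppressWarnings(
    wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
  )
}

# Shared two-group testing engine for KO and taxon rows.
# route: "both" runs Fisher and MW on every row; "prevalence" routes rare
# rows (prevalence below `rare_threshold` of samples) to Fisher only and
# common rows to MW only.
.two_group_tests <- function(values, lt, st, alpha = 0.05,
                             route = c("both", "prevalence"),
                             rare_threshold = 0.5,
                             id_name = "ko_id") {
  route <- match.arg(route)
  n_lt <- length(lt); n_st <- length(st)
  if (n_lt < 2L || n_st < 2L)
    stop("each group needs at least 2 samples")
  sub <- values[, c(lt, st), drop = FALSE]
  found <- rowSums(sub != 0) > 0
  if (!any(found)) {
    warning("no feature found in any included sample; empty result")
    return(data.frame())
  }
  sub <- sub[found, , drop = FALSE]
  res <- lapply(seq_len(nrow(sub)), function(i) {
    x_lt <- sub[i, seq_len(n_lt)]
    x_st <- sub[i, n_lt + seq_len(n_st)]
    prev_lt <- sum(x_lt > 0); prev_st <- sum(x_st > 0)
    do_fisher <- route == "both" ||
      (prev_lt + prev_st) < rare_threshold * (n_lt + n_st)
    do_mw <- route == "both" || !do_fisher
    fisher_p <- if (do_fisher)
      fisher.test(matrix(c(prev_lt, n_lt - prev_lt,
                           prev_st, n_st - prev_st), 2L))$p.value
    else NA_real_
    mw_p <- if (do_mw) .mw_test(x_lt, x_st) else NA_real_
    mean_lt <- mean(x_lt); mean_st <- mean(x_st)
    direction <- NA_character_
    if (!is.na(fisher_p) && fisher_p < alpha) {
      direction <- if (prev_lt != prev_st) {
        if (prev_lt > prev_st) "LT" else "ST"
      } else if (mean_lt != mean_st) {
        # presence counts tie; fall back to the abundance means
        if (mean_lt > mean_st) "LT" else "ST"
      } else NA_character_
    } else if (!is.na(mw_p) && mw_p < alpha && mean_lt != mean_st) {
      direction <- if (mean_lt > mean_st) "LT" else "ST"
    }
    data.frame(id = rownames(sub)[i],
               fisher_p = fisher_p, mw_p = mw_p,
               direction = direction,
               mean_ST = mean_st, mean_LT = mean_lt,
               prevalence_ST = prev_st, prevalence_LT = prev_lt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  names(out)[1] <- id_name
  out$q_fisher <- p.adjust(out$fisher_p, "BH")
  out$q_mw <- p.adjust(out$mw_p, "BH")
  out$selected <- pmin(out$fisher_p, out$mw_p, na.rm = TRUE) < alpha &
    !is.na(out$direction)
  rownames(out) <- NULL
  out
}

# Extract LT / ST sample ids from an assign_size_groups() result (or an
# equivalently shaped data.frame / named vector).
.group_samples <- function(groups) {
  if (is.data.frame(groups)) {
    labels <- setNames(groups$group, groups$patient_id)
  } else labels <- groups
  list(lt = names(labels)[labels == "LT"],
       st = names(labels)[labels == "ST"])
}

#' Differentially abundant KOs between tumor-size groups
#'
#' Every KO found in at least one LT or ST sample is tested by Fisher's
#' exact test on the 2x2 presence/absence-by-group table and by a
#' two-sided Mann-Whitney test on normalized abundances. A KO is selected
#' when either unadjusted p-value is below `alpha`; the enrichment
#' direction follows the prevalence difference when Fisher is
#' significant, and the mean-abundance difference otherwise.
#' Benjamini-Hochberg q-value columns are reported for reference but play
#' no role in selection.
#'
#' @param mfa a normalized `mfa_table`.
#' @param groups an [assign_size_groups()] result (or a named
#'   `"LT"`/`"ST"` label vector).
#' @param alpha unadjusted significance cutoff (default 0.05).
#' @return data.frame with one row per tested KO: `ko_id`, `fisher_p`,
#'   `mw_p`, `direction` (`"LT"`, `"ST"` or `NA`), group means and
#'   prevalences, BH q-values, and a logical `selected`.
#' @export
differential_kos <- function(mfa, groups, alpha = 0.05) {
  stopifnot(inherits(mfa, "mfa_table"))
  if (mfa$stage != "normalized")
    warning("differential_kos is designed for a normalized MFA table (stage: ",
            mfa$stage, ")")
  g <- .group_samples(groups)
  .two_group_tests(mfa$values, g$lt, g$st, alpha = alpha, route = "both",
                   id_name = "ko_id")
}

#' Functional richness and its clinical associations
#'
#' Richness of a sample is its number of distinct KOs with a nonzero raw
#' count. Returns the per-sample counts, the Pearson correlation of
#' richness with tumor size, and a two-sided rank-sum comparison of
#' richness between early (I/II) and advanced (III/IV) FIGO stages.
#'
#' @param mfa a raw `mfa_table` covering all patients in `clinical`.
#' @param clinical clinical table with `patient_id`, `tumor_size_cm`,
#'   `stage`.
#' @return list with `richness` (data.frame `patient_id`, `richness`),
#'   `pearson_r`, `pearson_p` (both `NA` with `undefined = TRUE` when a
#'   variance is zero), and `stage_wilcox_p`.
#' @export
functional_richness <- function(mfa, clinical) {
  stopifnot(inherits(mfa, "mfa_table"))
  missing <- setdiff(clinical$patient_id, colnames(mfa$values))
  if (length(missing))
    stop("MFA table lacks samples: ", paste(missing, collapse = ", "))
  if (nrow(clinical) < 3L)
    stop("correlation undefined for fewer than 3 samples")
  rich <- colSums(mfa$values[, clinical$patient_id, drop = FALSE] != 0)
  size <- clinical$tumor_size_cm
  undefined <- sd(rich) == 0 || sd(size) == 0
  if (undefined) {
    r <- NA_real_; p <- NA_real_
  } else {
    ct <- cor.test(rich, size, method = "pearson")
    r <- unname(ct$estimate); p <- ct$p.value
  }
  advanced <- clinical$stage %in% c("III", "IV")
  stage_p <- if (length(unique(advanced)) == 2L)
    .mw_test(rich[advanced], rich[!advanced]) else NA_real_
  list(richness = data.frame(patient_id = clinical$patient_id,
                             richness = unname(rich),
                             stringsAsFactors = FALSE),
       pearson_r = r, pearson_p = p, undefined = undefined,
       stage_wilcox_p = stage_p)
}
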