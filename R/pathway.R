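# KO -> pathway and KO -> CAZy mappings, the pathway enrichment score
# over direction-specific differential KOs, and the per-sample pathway
# activity score.

.read_two_col <- function(path, col1, col2) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    out <- data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE)
    names(out) <- c(col1, col2)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path,
         ": expected 2 tab-separated columns")
  out <- data.frame(a = vapply(parts, `[[`, "", 1L),
                    b = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  names(out) <- c(col1, col2)
  # tolerate a header row naming the columns
  if (identical(unname(unlist(out[1, ])), c(col1, col2)))
    out <- out[-1, , drop = FALSE]
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Load a KO-to-pathway mapping
#'
#' Two-column TSV (`pathway_id`, `ko_id`; a matching header row is
#' tolerated). Duplicate rows are collapsed; a KO may belong to several
#' pathways.
#'
#' @param path TSV file path.
#' @return data.frame with columns `pathway_id`, `ko_id`.
#' @export
load_pathway_map <- function(path) .read_two_col(path, "pathway_id", "ko_id")

#' Load a KO-to-CAZy-family mapping
#'
#' Two-column TSV (`ko_id`, `family`, e.g. `GH13`).
#'
#' @param path TSV file path.
#' @return data.frame with columns `ko_id`, `family`.
#' @export
load_cazy_map <- function(path) .read_two_col(path, "ko_id", "family")

#' Write a KO-to-pathway mapping
#'
#' @param map data.frame with columns `pathway_id`, `ko_id`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_pathway_map <- function(map, path) {
  write.table(map[, c("pathway_id", "ko_id")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

.direction_sets <- function(diff) {
  list(lt = unique(diff$ko_id[!is.na(diff$direction) & diff$direction == "LT"]),
       st = unique(diff$ko_id[!is.na(diff$direction) & diff$direction == "ST"]))
}

#' Pathway enrichment scores over differential KOs
#'
#' For each pathway, `pct_G` is the percentage of group G's differential
#' KOs (G in ST, LT) that overlap the pathway; the score is
#' `(pct_ST - pct_LT) / (pct_ST + pct_LT)`, lying in `[-1, 1]` with
#' positive values marking ST-enrichment (the sign convention follows the
#' ST-minus-LT order of the formula). Pathways are reported when they
#' include at least `min_lt` LT-direction KOs or at least `min_st`
#' ST-direction KOs; pathways overlapping neither set are omitted.
#'
#' @param diff a [differential_kos()] result (directions assigned).
#' @param map pathway map data.frame (`pathway_id`, `ko_id`).
#' @param min_lt,min_st minimum overlap counts for reporting a
#'   LT-favoring (default 9) or ST-favoring (default 4) pathway.
#' @return data.frame `pathway_id`, `n_ST_overlap`, `n_LT_overlap`,
#'   `pct_ST`, `pct_LT`, `score`, ordered by decreasing `|score|`.
#' @export
enrichment_scores <- function(diff, map, min_lt = 9L, min_st = 4L) {
  sets <- .direction_sets(diff)
  pw <- split(map$ko_id, map$pathway_id)
  rows <- lapply(names(pw), function(p) {
    kos <- unique(pw[[p]])
    n_lt <- length(intersect(kos, sets$lt))
    n_st <- length(intersect(kos, sets$st))
    if (n_lt == 0L && n_st == 0L) return(NULL)
    pct_lt <- if (length(sets$lt)) 100 * n_lt / length(sets$lt) else 0
    pct_st <- if (length(sets$st)) 100 * n_st / length(sets$st) else 0
    score <- (pct_st - pct_lt) / (pct_st + pct_lt)
    keep <- n_lt >= min_lt || n_st >= min_st
    if (!keep) return(NULL)
    data.frame(pathway_id = p, n_ST_overlap = n_st, n_LT_overlap = n_lt,
               pct_ST = pct_st, pct_LT = pct_lt, score = score,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(pathway_id = character(), n_ST_overlap = integer(),
                      n_LT_overlap = integer(), pct_ST = numeric(),
                      pct_LT = numeric(), score = numeric(),
                      stringsAsFactors = FALSE))
  out <- out[order(-abs(out$score), out$pathway_id), ]
  rownames(out) <- NULL
  out
}

#' Per-sample pathway activity score
#'
#' The activity of a pathway in a sample is the mean of
#' `log2(normalized abundance + pseudocount)` over the pathway's KOs
#' present in the table. KOs outside the pathway do not influence the
#' score.
#'
#' @param mfa a normalized `mfa_table`.
#' @param pathway_kos character vector of KO ids, or a single pathway id
#'   resolved against `map`.
#' @param map optional pathway map used when `pathway_kos` is an id.
#' @param pseudocount offset added before the log (default 1).
#' @return named numeric vector of per-sample scores.
#' @export
activity_score <- function(mfa, pathway_kos, map = NULL, pseudocount = 1) {
  stopifnot(inherits(mfa, "mfa_table"))
  if (mfa$stage != "normalized")
    stop("activity_score expects a normalized MFA table")
  label <- "pathway"
  if (length(pathway_kos) == 1L && !is.null(map) &&
      pathway_kos %in% map$pathway_id) {
    label <- pathway_kos
    pathway_kos <- map$ko_id[map$pathway_id == pathway_kos]
  }
  kos <- intersect(unique(pathway_kos), rownames(mfa$values))
  if (!length(kos))
    stop("no KO of ", label, " is present in the MFA table")
  colMeans(log2(mfa$values[kos, , drop = FALSE] + pseudocount))
}

#' CAZy class tallies of differential KOs
#'
#' Maps each direction's differential KOs to CAZy families and counts the
#' families per class (GH glycoside hydrolases, GT glycosyltransferases,
#' PL polysaccharide lyases, CE carbohydrate esterases, CBM binding
#' modules).
#'
#' @param diff a [differential_kos()] result.
#' @param cazy_map data.frame (`ko_id`, `family`).
#' @return data.frame with `direction`, `class`, `n` (one row per
#'   direction x class).
#' @export
cazy_summary <- function(diff, cazy_map) {
  classes <- c("GH", "GT", "PL", "CE", "CBM")
  sets <- .direction_sets(diff)
  tally <- function(kos, dir) {
    fams <- cazy_map$family[cazy_map$ko_id %in% kos]
    cls <- sub("^(CBM|GH|GT|PL|CE).*$", "\\1", fams)
    data.frame(direction = dir, class = classes,
               n = as.integer(table(factor(cls, levels = classes))),
               stringsAsFactors = FALSE)
  }
  rbind(tally(sets$lt, "LT"), tally(sets$st, "ST"))
}
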