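# End-to-end orchestration: MFA construction -> clustering ->
# differential KOs -> pathway scores -> density decomposition ->
# taxonomy -> survival, with a manifest recording parameters and
# per-stage sizes. All randomness flows from the seed recorded in the
# configuration (the stages themselves are deterministic given inputs).

#' Assemble and validate a pipeline configuration
#'
#' @param k tumor-size group size (default 14).
#' @param alpha unadjusted significance cutoff.
#' @param min_samples prevalence filter before clustering.
#' @param pseudocount shared log2 pseudocount.
#' @param min_lt,min_st pathway enrichment reporting thresholds.
#' @param grid_n,bandwidth density decomposition controls (`NULL`
#'   bandwidth = Silverman's rule).
#' @param rank taxonomic rank for OTU tables.
#' @param rare_threshold rare/common routing fraction for taxa tests.
#' @param seed integer seed recorded in the manifest.
#' @param out_dir output directory, or `NULL` to skip writing files.
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(k = 14L, alpha = 0.05, min_samples = 30L,
                       pseudocount = 1, min_lt = 9L, min_st = 4L,
                       grid_n = 512L, bandwidth = NULL, rank = "order",
                       rare_threshold = 0.5, seed = 1L, out_dir = NULL) {
  cfg <- list(k = as.integer(k), alpha = alpha,
              min_samples = as.integer(min_samples),
              pseudocount = pseudocount, min_lt = as.integer(min_lt),
              min_st = as.integer(min_st), grid_n = as.integer(grid_n),
              bandwidth = bandwidth, rank = rank,
              rare_threshold = rare_threshold, seed = as.integer(seed),
              out_dir = out_dir)
  if (cfg$k < 2L || cfg$alpha <= 0 || cfg$alpha >= 1 || cfg$min_samples < 1L ||
      cfg$pseudocount < 0 || cfg$min_lt < 1L || cfg$min_st < 1L ||
      cfg$grid_n < 16L || cfg$rare_threshold < 0 || cfg$rare_threshold > 1)
    stop("invalid run_config: thresholds out of range")
  class(cfg) <- "run_config"
  cfg
}

.write_stage <- function(df, out_dir, name, header = NULL) {
  if (is.null(out_dir)) return(invisible(NULL))
  path <- file.path(out_dir, name)
  if (!is.null(header))
    writeLines(paste0("# ", header), path)
  suppressWarnings(
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                append = !is.null(header))
  )
  invisible(path)
}

#' Run the full downstream analysis
#'
#' Sequences every stage of the pipeline on an annotated-contig cohort:
#' raw/normalized MFA tables, prevalence filtering and log2 median
#' centering, hierarchical clustering with clinical association,
#' tumor-size groups and differential KOs, pathway enrichment and
#' activity scores plus CAZy tallies, the two-community density
#' decomposition, OTU tables with differential taxa and the
#' pathway-representative profile, and survival models. Re-running with
#' the same configuration and inputs reproduces identical outputs.
#'
#' @param cohort a `mucometa_cohort`, or a list with `contigs` and
#'   `clinical` read from disk.
#' @param pathway_map data.frame (`pathway_id`, `ko_id`); defaults to
#'   the cohort's ground-truth map when present.
#' @param cazy_map data.frame (`ko_id`, `family`); same default.
#' @param config a [run_config()].
#' @param survival_pathway pathway id whose activity score is carried
#'   into the survival stage (default: the top ST- and LT-favoring
#'   pathways by absolute enrichment score).
#' @return a list of class `mucometa_run` with every stage result and a
#'   `manifest` (parameters, package version, per-stage row counts).
#'   When `config$out_dir` is set, stage tables are written there as TSV
#'   and the manifest as JSON.
#' @export
run_all <- function(cohort, pathway_map = NULL, cazy_map = NULL,
                    config = run_config(), survival_pathway = NULL) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  if (is.null(pathway_map) && !is.null(cohort$truth))
    pathway_map <- cohort$truth$pathway_map
  if (is.null(cazy_map) && !is.null(cohort$truth))
    cazy_map <- cohort$truth$cazy_map
  if (is.null(pathway_map))
    stop("stage pathway: no pathway map supplied")
  clinical <- cohort$clinical
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    message(sprintf("[mucometa] stage %s", name))
    tryCatch(expr, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
  }

  res <- list(config = config)
  res$mfa_raw <- stage("mfa", {
    total_reads <- if ("total_reads" %in% names(clinical))
      setNames(clinical$total_reads, clinical$patient_id) else NULL
    build_mfa(cohort$contigs, total_reads = total_reads)
  })
  res$mfa_norm <- stage("mfa", normalize_mfa(res$mfa_raw))
  res$mfa_clustering_input <- stage("mfa", {
    log2_center(filter_prevalent(res$mfa_norm,
                                 min_samples = min(config$min_samples,
                                                   ncol(res$mfa_norm$values))),
                pseudocount = config$pseudocount)
  })
  .write_stage(data.frame(ko_id = rownames(res$mfa_raw$values),
                          res$mfa_raw$values, check.names = FALSE),
               out_dir, "mfa_raw.tsv",
               header = sprintf("raw MFA; seed=%d", config$seed))

  res$clustering <- stage("clustering", {
    cl <- hierarchical_cluster(res$mfa_clustering_input,
                               n_sample_clusters = 2L, n_ko_clusters = 2L)
    assoc <- cluster_clinical_association(cl, clinical)
    overlap <- ko_cluster_pathway_overlap(cl, pathway_map)
    list(assignment = cl, clinical_association = assoc,
         pathway_overlap = overlap)
  })
  .write_stage(res$clustering$clinical_association, out_dir,
               "cluster_clinical.tsv")

  res$groups <- stage("differential", assign_size_groups(clinical, k = config$k))
  res$diff <- stage("differential",
                    differential_kos(res$mfa_norm, res$groups,
                                     alpha = config$alpha))
  res$richness <- stage("differential",
                        functional_richness(res$mfa_raw, clinical))
  .write_stage(res$diff, out_dir, "differential_kos.tsv",
               header = sprintf("differential KOs; k=%d alpha=%g",
                                config$k, config$alpha))

  res$enrichment <- stage("pathway",
                          enrichment_scores(res$diff, pathway_map,
                                            min_lt = config$min_lt,
                                            min_st = config$min_st))
  res$cazy <- stage("pathway", if (!is.null(cazy_map))
    cazy_summary(res$diff, cazy_map) else NULL)
  .write_stage(res$enrichment, out_dir, "enrichment_scores.tsv")

  res$decomposition <- stage("decomposition",
                             dominance_report(res$groups, res$mfa_norm,
                                              res$diff,
                                              grid_n = config$grid_n,
                                              bandwidth = config$bandwidth))
  .write_stage(data.frame(
    group = c("LT", "ST"),
    coef_LT = c(res$decomposition$fit_LT_group$coef_LT,
                res$decomposition$fit_ST_group$coef_LT),
    coef_ST = c(res$decomposition$fit_LT_group$coef_ST,
                res$decomposition$fit_ST_group$coef_ST),
    r_squared = c(res$decomposition$fit_LT_group$r_squared,
                  res$decomposition$fit_ST_group$r_squared),
    mu_LT = res$decomposition$curve_LT$mu,
    sigma_LT = res$decomposition$curve_LT$sigma,
    mu_ST = res$decomposition$curve_ST$mu,
    sigma_ST = res$decomposition$curve_ST$sigma
  ), out_dir, "decomposition.tsv")

  res$otu <- stage("taxonomy", taxa_abundance(cohort$contigs,
                                              rank = config$rank))
  res$diff_taxa <- stage("taxonomy",
                         differential_taxa(res$otu, res$groups,
                                           alpha = config$alpha,
                                           rare_threshold = config$rare_threshold))
  .write_stage(res$diff_taxa, out_dir, "differential_taxa.tsv")

  if (is.null(survival_pathway)) {
    survival_pathway <- res$enrichment$pathway_id[
      order(-abs(res$enrichment$score))][seq_len(min(2L, nrow(res$enrichment)))]
  }
  res$survival <- stage("survival", {
    lapply(setNames(survival_pathway, survival_pathway), function(p) {
      score <- activity_score(res$mfa_norm, p, map = pathway_map,
                              pseudocount = config$pseudocount)
      labels <- categorize_score(score)
      km <- km_logrank(labels, clinical)
      cox <- cox_ph(data.frame(patient_id = names(score),
                               activity = unname(score)), clinical)
      profile <- pathway_taxa_profile(
        cohort$contigs, pathway_map$ko_id[pathway_map$pathway_id == p],
        rank = config$rank)
      taxa_cor <- correlate_pathway_taxa(score, profile)
      list(pathway = p, score = score, labels = labels, km = km, cox = cox,
           taxa_profile = profile, taxa_correlation = taxa_cor)
    })
  })
  res$clinical_categories <- stage("survival", categorize_clinical(clinical))

  res$manifest <- list(
    package = "mucometa",
    version = as.character(packageVersion("mucometa")),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(unclass(config)), "out_dir")],
    stage_rows = list(
      mfa_kos = nrow(res$mfa_raw$values),
      mfa_samples = ncol(res$mfa_raw$values),
      clustering_kos = nrow(res$mfa_clustering_input$values),
      differential_tested = nrow(res$diff),
      differential_selected = sum(res$diff$selected),
      pathways_scored = nrow(res$enrichment),
      taxa = nrow(res$otu$values),
      survival_pathways = length(res$survival)
    )
  )
  if (!is.null(out_dir))
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  class(res) <- "mucometa_run"
  res
}

#' @export
print.mucometa_run <- function(x, ...) {
  m <- x$manifest$stage_rows
  cat(sprintf(paste0(
    "mucometa run: %d KOs x %d samples; %d differential KOs (of %d tested), ",
    "%d pathways scored, %d taxa, %d survival pathway(s)\n"),
    m$mfa_kos, m$mfa_samples, m$differential_selected, m$differential_tested,
    m$pathways_scored, m$taxa, m$survival_pathways))
  invisible(x)
}
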