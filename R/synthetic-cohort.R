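# Synthetic cohort generator.
#
# Emulates the statistical structure the downstream analysis assumes: two
# latent KO communities per metagenome (A: mucus-degrading, wide/low
# log2-abundance profile, carried mostly by a Clostridiales-like order;
# B: proliferating, tight/high profile, Bacteroidales-like) whose relative
# dominance shifts with tumor size, plus a clinical table with
# recurrence-free survival whose hazard rises with community-A dominance.

.taxa_pools <- function() {
  a <- c(
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Blautia_sim;Blautia_sim_sp1",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Lachnospiraceae;Roseburia_sim;Roseburia_sim_sp1",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;Faecalibacterium_sim;Faecalibacterium_sim_sp1",
    "Bacteria;Firmicutes;Clostridia;Clostridiales;Ruminococcaceae;Ruminococcus_sim;Ruminococcus_sim_sp2"
  )
  b <- c(
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella_sim;Prevotella_sim_sp1",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Prevotellaceae;Prevotella_sim;Prevotella_sim_sp2",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Porphyromonadaceae;Porphyromonas_sim;Porphyromonas_sim_sp1",
    "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;Porphyromonadaceae;Porphyromonas_sim;Porphyromonas_sim_sp2"
  )
  other <- c(
    "Bacteria;Proteobacteria;Gammaproteobacteria;Enterobacterales;Enterobacteriaceae;Escherichia_sim;Escherichia_sim_sp1",
    "Bacteria;Actinobacteria;Actinomycetia;Actinomycetales;Actinomycetaceae;Actinomyces_sim;Actinomyces_sim_sp1",
    "Bacteria;NA;NA;NA;NA;NA;NA"
  )
  list(A = a, B = b, other = other)
}

#' Parameters of a synthetic mucus-associated metagenome cohort
#'
#' Bundles and validates the generator parameters. Defaults describe the
#' study conditions the analysis is designed for: 41 patients, tumor sizes
#' 1.8--11.5 cm, 500 KOs per community, community log2-abundance profiles
#' with standard deviations 2.6 (A, mucus-degrading / large-tumor) and 1.3
#' (B, proliferating / small-tumor) and the A mean at half the B mean on
#' the log2 counts-per-million scale.
#'
#' @param n_patients number of patients (>= 2).
#' @param n_kos_per_community KO repertoire size per community; a single
#'   count used for both communities, or a length-2 vector `c(A, B)`.
#' @param community_mu_A,community_mu_B mean log2 normalized abundance
#'   (log2 counts per million) of each community's KO baseline profile.
#' @param community_sigma_A,community_sigma_B standard deviation of the
#'   KO baseline profile (log2 scale, > 0).
#' @param dominance_slope change in the community-A mixing weight per cm of
#'   tumor size; weights are clamped to `[0.05, 0.95]`.
#' @param tumor_size_range length-2 cm interval tumor sizes are drawn from.
#' @param within_sigma within-KO between-sample log2 noise sd.
#' @param zero_inflation structural-absence strength: a community-c KO is
#'   absent from a sample with probability `zero_inflation * (1 - w_c)`,
#'   where `w_c` is the community's mixing weight in that sample.
#' @param n_noise_contigs unannotated (no-KO) contigs per sample.
#' @param read_length sequencing read length in bp.
#' @param mean_total_reads expected sequenced reads per sample.
#' @param base_hazard monthly recurrence hazard at balanced dominance.
#' @param dominance_log_hr log hazard ratio per unit of community-A weight
#'   above 0.5 (times 2, i.e. over the full 0--1 weight range).
#' @param seed integer RNG seed; identical parameters give byte-identical
#'   cohorts.
#' @return an object of class `cohort_params` (a validated list).
#' @export
cohort_params <- function(n_patients = 41L,
                          n_kos_per_community = 500L,
                          community_mu_A = 4,
                          community_sigma_A = 2.6,
                          community_mu_B = 8,
                          community_sigma_B = 1.3,
                          dominance_slope = 0.08,
                          tumor_size_range = c(1.8, 11.5),
                          within_sigma = 0.5,
                          zero_inflation = 0.6,
                          n_noise_contigs = 60L,
                          read_length = 150L,
                          mean_total_reads = 2e6,
                          base_hazard = 0.02,
                          dominance_log_hr = 2,
                          seed = 1L) {
  if (length(n_kos_per_community) == 1L)
    n_kos_per_community <- rep(n_kos_per_community, 2L)
  p <- list(
    n_patients = as.integer(n_patients),
    n_kos_per_community = as.integer(n_kos_per_community),
    community_mu_A = community_mu_A, community_sigma_A = community_sigma_A,
    community_mu_B = community_mu_B, community_sigma_B = community_sigma_B,
    dominance_slope = dominance_slope,
    tumor_size_range = as.numeric(tumor_size_range),
    within_sigma = within_sigma, zero_inflation = zero_inflation,
    n_noise_contigs = as.integer(n_noise_contigs),
    read_length = as.integer(read_length),
    mean_total_reads = mean_total_reads,
    base_hazard = base_hazard, dominance_log_hr = dominance_log_hr,
    seed = as.integer(seed)
  )
  if (p$n_patients < 2L)
    stop("invalid cohort_params: n_patients must be >= 2")
  if (length(p$n_kos_per_community) != 2L || any(p$n_kos_per_community < 1L))
    stop("invalid cohort_params: n_kos_per_community must be 1 or 2 positive counts")
  if (p$community_sigma_A <= 0 || p$community_sigma_B <= 0)
    stop("invalid cohort_params: community sigmas must be > 0")
  if (length(p$tumor_size_range) != 2L ||
      p$tumor_size_range[1] >= p$tumor_size_range[2])
    stop("invalid cohort_params: tumor_size_range must be an increasing interval")
  if (p$within_sigma < 0 || p$zero_inflation < 0 || p$zero_inflation > 1)
    stop("invalid cohort_params: within_sigma >= 0 and zero_inflation in [0,1] required")
  if (p$read_length < 1L || p$mean_total_reads <= 0)
    stop("invalid cohort_params: read_length and mean_total_reads must be positive")
  class(p) <- "cohort_params"
  p
}

# community-A mixing weight as a function of tumor size, clamped
.dominance_weight <- function(size, params) {
  mid <- mean(params$tumor_size_range)
  pmin(pmax(0.5 + params$dominance_slope * (size - mid), 0.05), 0.95)
}

# disjoint pathway blocks over each community's KO repertoire + CAZy map
.truth_maps <- function(ko_A, ko_B) {
  nA <- length(ko_A); nB <- length(ko_B)
  blk <- function(ids, props, names) {
    sizes <- pmax(1L, floor(props * length(ids)))
    ends <- cumsum(sizes)
    out <- list()
    for (i in seq_along(names)) {
      lo <- if (i == 1L) 1L else ends[i - 1L] + 1L
      out[[names[i]]] <- ids[lo:min(ends[i], length(ids))]
    }
    out
  }
  pw <- c(
    blk(ko_A, c(0.4, 0.3, 0.2),
        c("glycan_degradation", "galactose_metabolism", "pts_system")),
    blk(ko_B, c(0.4, 0.3),
        c("ribosome", "oxidative_phosphorylation"))
  )
  pathway_map <- data.frame(
    pathway_id = rep(names(pw), lengths(pw)),
    ko_id = unlist(pw, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  gh_pool <- c("GH2", "GH13", "GH20", "GH29", "GH33", "GH95", "GH16", "GH3",
               "GH31", "GH35", "GH38", "GH42", "GH51", "GH78", "GH92", "GH97")
  gh_kos <- pw$glycan_degradation[seq_len(min(16L, length(pw$glycan_degradation)))]
  gt_kos <- ko_B[seq_len(min(3L, nB))]
  cazy_map <- data.frame(
    ko_id = c(gh_kos, gt_kos),
    family = c(gh_pool[seq_along(gh_kos)], c("GT2", "GT4", "GT51")[seq_along(gt_kos)]),
    stringsAsFactors = FALSE
  )
  list(pathway_map = pathway_map, cazy_map = cazy_map)
}

#' Generate a synthetic annotated-contig cohort
#'
#' Draws tumor sizes, per-sample community mixing weights, per-KO baseline
#' log2 abundances, read counts, contig placements with community-specific
#' taxonomy, a clinical table, and recurrence-free survival outcomes.
#'
#' Each community-c KO k in sample s has latent log2 normalized abundance
#' `b_k + log2(2 * w_c(s)) + noise`, where `b_k ~ N(mu_c, sigma_c)` is the
#' KO-level baseline and `w_c(s)` the community's mixing weight (so at
#' balanced dominance the KO density is the community's normal profile).
#' Observed gene read counts are Poisson with mean equal to the latent
#' normalized abundance times `total_reads / 1e6`, thinned by a structural
#' absence layer tied to the opposite community's dominance. Each observed
#' KO occupies one gene on its own contig; the contig's recorded depth is
#' the realized coverage `read_count * read_length / length_bp`, so a
#' contig's length-by-depth mass equals `read_length * read_count`.
#' Unannotated noise contigs (genes without a KO) are added per sample.
#'
#' @param params a [cohort_params()] object.
#' @return a list of class `mucometa_cohort` with elements
#'   \describe{
#'     \item{contigs}{per-gene annotation table (one row per gene):
#'       `sample_id`, `contig_id`, `length_bp`, `depth`, `lineage`,
#'       `gene_id`, `ko_id` (`NA` if unannotated), `read_count`.}
#'     \item{clinical}{`patient_id`, `age`, `bmi`, `stage`, `tumor_size_cm`,
#'       `node_positive`, `rfs_months`, `rfs_event`, `total_reads`.}
#'     \item{truth}{latent ground truth: the parameters, per-sample
#'       community-A weights, per-KO community membership and baselines,
#'       and the pathway/CAZy maps tied to the planted communities.}
#'   }
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!inherits(params, "cohort_params"))
    params <- do.call(cohort_params, as.list(params))
  set.seed(params$seed)
  n <- params$n_patients
  nA <- params$n_kos_per_community[1]
  nB <- params$n_kos_per_community[2]
  sample_id <- sprintf("P%02d", seq_len(n))

  tumor_size <- runif(n, params$tumor_size_range[1], params$tumor_size_range[2])
  w_A <- .dominance_weight(tumor_size, params)
  total_reads <- round(rlnorm(n, log(params$mean_total_reads), 0.15))

  ko_A <- sprintf("K9%04d", seq_len(nA))
  ko_B <- sprintf("K8%04d", seq_len(nB))
  b_A <- params$community_mu_A + params$community_sigma_A * rnorm(nA)
  b_B <- params$community_mu_B + params$community_sigma_B * rnorm(nB)

  pools <- .taxa_pools()
  draw_lineage <- function(m, community) {
    src <- runif(m)
    own <- if (community == "A") pools$A else pools$B
    cross <- if (community == "A") pools$B else pools$A
    out <- character(m)
    i1 <- src < 0.8
    i2 <- src >= 0.8 & src < 0.9
    out[i1] <- sample(own, sum(i1), replace = TRUE)
    out[i2] <- sample(cross, sum(i2), replace = TRUE)
    out[!i1 & !i2] <- sample(pools$other, sum(!i1 & !i2), replace = TRUE)
    out
  }

  community_block <- function(kos, b, community) {
    nk <- length(kos)
    w_c <- if (community == "A") w_A else 1 - w_A
    # latent log2 CPM for every (ko, sample)
    x <- outer(b, log2(2 * w_c), `+`) +
      matrix(rnorm(nk * n, 0, params$within_sigma), nk, n)
    lambda <- 2^x * rep(total_reads / 1e6, each = nk)
    present <- matrix(
      rbinom(nk * n, 1L, rep(1 - params$zero_inflation * (1 - w_c), each = nk)),
      nk, n
    )
    counts <- matrix(rpois(nk * n, as.vector(lambda)), nk, n) * present
    idx <- which(counts > 0, arr.ind = TRUE)
    m <- nrow(idx)
    len <- sample(1000:8000, m, replace = TRUE)
    cnt <- counts[idx]
    data.frame(
      sample_id = sample_id[idx[, 2]],
      ko_id = kos[idx[, 1]],
      length_bp = len,
      read_count = cnt,
      depth = cnt * params$read_length / len,
      lineage = draw_lineage(m, community),
      stringsAsFactors = FALSE
    )
  }

  genes <- rbind(
    community_block(ko_A, b_A, "A"),
    community_block(ko_B, b_B, "B")
  )

  # unannotated filler contigs (no KO): part of the taxonomy denominator
  if (params$n_noise_contigs > 0L) {
    m <- n * params$n_noise_contigs
    len <- sample(1000:8000, m, replace = TRUE)
    dep <- rlnorm(m, log(2), 0.8)
    noise <- data.frame(
      sample_id = rep(sample_id, each = params$n_noise_contigs),
      ko_id = NA_character_,
      length_bp = len,
      read_count = rpois(m, dep * 900 / params$read_length),
      depth = dep,
      lineage = sample(unlist(pools), m, replace = TRUE),
      stringsAsFactors = FALSE
    )
    genes <- rbind(genes, noise)
  }

  genes <- genes[order(genes$sample_id, is.na(genes$ko_id), genes$ko_id), ]
  cidx <- stats::ave(seq_along(genes$sample_id), genes$sample_id, FUN = seq_along)
  genes$contig_id <- sprintf("%s_c%05d", genes$sample_id, cidx)
  genes$gene_id <- paste0(genes$contig_id, "_g1")
  contigs <- genes[, c("sample_id", "contig_id", "length_bp", "depth",
                       "lineage", "gene_id", "ko_id", "read_count")]
  rownames(contigs) <- NULL

  # clinical table: stage and nodal status loosely track tumor size
  mid <- mean(params$tumor_size_range)
  age <- pmin(pmax(round(rnorm(n, 49, 9)), 29), 72)
  bmi <- round(pmin(pmax(rnorm(n, 28.6, 4.5), 17.5), 46.7), 1)
  advanced <- rbinom(n, 1L, stats::plogis(0.5 * (tumor_size - mid)))
  stage <- ifelse(advanced == 1L,
                  sample(c("III", "IV"), n, replace = TRUE, prob = c(0.7, 0.3)),
                  sample(c("I", "II"), n, replace = TRUE, prob = c(0.3, 0.7)))
  node_positive <- rbinom(n, 1L, stats::plogis(0.4 * (tumor_size - mid))) == 1L
  hazard <- params$base_hazard * exp(params$dominance_log_hr * (w_A - 0.5))
  t_event <- rexp(n, hazard)
  t_censor <- runif(n, 36, 72)
  clinical <- data.frame(
    patient_id = sample_id,
    age = age, bmi = bmi, stage = stage,
    tumor_size_cm = round(tumor_size, 1),
    node_positive = node_positive,
    rfs_months = round(pmin(t_event, t_censor), 1),
    rfs_event = t_event <= t_censor,
    total_reads = total_reads,
    stringsAsFactors = FALSE
  )

  maps <- .truth_maps(ko_A, ko_B)
  truth <- list(
    params = params,
    w_A = setNames(w_A, sample_id),
    tumor_size = setNames(tumor_size, sample_id),
    ko_community = setNames(c(rep("A", nA), rep("B", nB)), c(ko_A, ko_B)),
    baseline = setNames(c(b_A, b_B), c(ko_A, ko_B)),
    taxa_pools = pools,
    community_order = c(A = "Clostridiales", B = "Bacteroidales"),
    hazard = setNames(hazard, sample_id),
    pathway_map = maps$pathway_map,
    cazy_map = maps$cazy_map
  )
  structure(list(contigs = contigs, clinical = clinical, truth = truth),
            class = "mucometa_cohort")
}

#' @export
print.mucometa_cohort <- function(x, ...) {
  cat(sprintf(
    "Synthetic mucus-associated metagenome cohort: %d patients, %d gene records, %d KOs\n",
    nrow(x$clinical), nrow(x$contigs),
    length(unique(na.omit(x$contigs$ko_id)))
  ))
  invisible(x)
}

#' The two-metagenome toy fixture behind the MFA worked example
#'
#' Encodes the didactic two-metagenome community used to define the MFA
#' quantity: metagenome A holds 18 bacterial cells and metagenome B 19,
#' drawn from 4 species; circle-shaped cells carry function F1, oval-shaped
#' cells carry F2, and every gene is covered by exactly one sequencing
#' read, so the MFA of a function is simply the number of cells carrying
#' it. Metagenome A has 4 F1 cells and 14 F2 cells; metagenome B has 4 F2
#' cells. The source description of B's F1 cells is internally inconsistent
#' (a count token that would give 20 cells against a stated total of 19);
#' the fixture honors the stated cell total and stores 15 F1 cells for B,
#' so B's F1 value should not be used as a reference quantity.
#'
#' Each cell is one contig carrying one annotated gene with
#' `read_count = 1`.
#'
#' @return a per-gene annotation table in the same layout as
#'   `generate_cohort()$contigs`, with samples `"A"` and `"B"` and
#'   functions `"F1"`, `"F2"`.
#' @export
toy_figs2 <- function() {
  species <- c(
    circle1 = "Bacteria;Firmicutes;Clostridia;Clostridiales;NA;NA;Circle_species_red",
    circle2 = "Bacteria;Firmicutes;Clostridia;Clostridiales;NA;NA;Circle_species_green",
    oval1 = "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;NA;NA;Oval_species_yellow",
    oval2 = "Bacteria;Bacteroidetes;Bacteroidia;Bacteroidales;NA;NA;Oval_species_blue"
  )
  cell <- function(sample, shape, k) {
    n_half <- ceiling(k / 2)
    sp <- rep(species[paste0(shape, 1:2)], c(n_half, k - n_half))
    data.frame(
      sample_id = sample,
      lineage = unname(sp),
      ko_id = if (shape == "circle") "F1" else "F2",
      read_count = 1L,
      stringsAsFactors = FALSE
    )
  }
  cells <- rbind(
    cell("A", "circle", 4L), cell("A", "oval", 14L),
    cell("B", "circle", 15L), cell("B", "oval", 4L)
  )
  cells$length_bp <- 1000L
  cells$depth <- 0.15
  idx <- stats::ave(seq_len(nrow(cells)), cells$sample_id, FUN = seq_along)
  cells$contig_id <- sprintf("%s_cell%02d", cells$sample_id, idx)
  cells$gene_id <- paste0(cells$contig_id, "_g1")
  cells[, c("sample_id", "contig_id", "length_bp", "depth", "lineage",
            "gene_id", "ko_id", "read_count")]
}
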