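---
title: "Methods: function-centric analysis of mucus-associated metagenomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: function-centric analysis of mucus-associated metagenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mucometa` analyzes shotgun metagenomes of rectal (mucus-associated) swabs
downstream of assembly and annotation. Its input is a per-gene table of
annotated contigs — sample, contig, contig length (bp), mean read depth,
7-rank lineage, gene, optional KEGG ortholog (KO), mapped-read count — plus
a clinical table. Everything upstream (read QC, assembly, gene prediction,
KO assignment, contig taxonomy) is out of scope; the package consumes that
pipeline's output format.

## The MFA table

The central object is the Metagenome Function Abundance (MFA) table. The
quantity of a molecular function (KO) in a metagenome is the total number
of sequencing reads covering genes annotated with that KO, summed over all
organisms; genes without a functional annotation are ignored. This makes a
function's abundance comparable to a gene-expression profile: organisms
are deliberately integrated out, and the KO x sample matrix can be
normalized, transformed, and clustered like an expression matrix.
`toy_figs2()` ships a didactic two-metagenome community (18 and 19
bacterial cells of 4 species, every gene covered by exactly one read) on
which the MFA values are countable by eye; `build_mfa()` reproduces them
exactly, and `scripts/acceptance.R` recomputes them. One caveat is encoded
in the fixture's documentation: the source description of the second toy
metagenome is internally inconsistent about one cell count, so the fixture
honors the stated cell totals, stores 15 carrier cells for that function,
and that single cell count is not used as a reference value anywhere.

Normalization divides each raw count by the sample's **total sequenced
reads** (not the sum of annotated counts — the denominator includes reads
outside known functions) and multiplies by 1e6, giving counts per million
(CPM). Two further transforms serve specific analyses:

* `filter_prevalent()` keeps KOs found (strictly nonzero) in at least
  `min_samples` samples (default 30) before unsupervised clustering.
* `log2_center()` computes `log2(CPM + pseudocount)` and median-centers
  each KO row. The pseudocount defaults to 1 CPM; it is shared with the
  pathway activity score and configurable, with 0 permitted when the
  caller guarantees positivity. Centering is per KO row by default (the
  convention of expression-heatmap tools); per-sample centering is exposed
  because the choice is not forced by anything upstream.

## Unsupervised clustering

`hierarchical_cluster()` clusters both axes of the transformed table
agglomeratively with distance `1 - Pearson correlation` and average
linkage — the defaults of the classic expression-clustering tool lineage.
The two main sample clusters are compared on clinical variables
(rank-sum for age, BMI, tumor size; Fisher's exact for stage I/II vs
III/IV and nodal status), and KO clusters are screened for pathway
concentration with a hypergeometric over-representation test against the
clustered-KO universe. Sub-clusters are a second cut of the same trees
(k = 4), the simplest reading of a two-level cluster structure.

## Tumor-size groups and differential KOs

Patients are sorted by tumor size; the top 14 form the LT (largest-tumor)
group and the bottom 14 the ST group (deterministic tie-break: size
descending, then patient id). Every KO found in at least one included
sample is tested twice, unadjusted:

* **Fisher's exact test** on the 2x2 presence/absence x group table
  (two-sided by the minimum-likelihood rule, the conventional
  definition);
* **Mann-Whitney** on CPM abundances, two-sided; exact only for tie-free
  groups of at most 12, otherwise the normal approximation with
  continuity and tie correction (at the default 14 vs 14 the
  approximation is used).

A KO is selected when either p < 0.05. Direction follows the presence
test when it is significant — the more-prevalent group — else the higher
abundance mean; when a significant Fisher p coincides with equal
prevalence counts the mean difference decides (a documented fallback for
a case the selection rule leaves open). No multiplicity adjustment is
applied, deliberately; Benjamini-Hochberg q-values are reported as extra
columns but never drive selection. Functional richness (distinct KOs per
sample) is related to tumor size by Pearson correlation and to stage by a
rank-sum test.

## Pathway scores

Differential KOs are mapped to pathways through a user-supplied
two-column KO-to-pathway table (KEGG licensing prevents bundling the real
map; a miniature fixture ships for tests). Two scores are computed:

* **Enrichment score.** For pathway P, `pct_G` is the percentage of group
  G's differential KOs overlapping P (denominator = the size of that
  direction's KO set, reading "percentage of the group's KOs" literally);
  the score is `(pct_ST - pct_LT) / (pct_ST + pct_LT)`, in [-1, 1].
  **Positive favors ST** — the sign convention follows the ST-minus-LT
  order of the formula and is stated here because it is otherwise easy to
  invert. Pathways qualify with at least 9 LT-direction or 4 ST-direction
  overlapping KOs (both configurable); pathways overlapping neither set
  are omitted.
* **Activity score.** Per sample, the mean of `log2(CPM + pseudocount)`
  over the pathway's KOs — a per-patient scalar reused by the survival
  stage. KOs outside the pathway never influence it.

CAZy tallies map each direction's KOs to carbohydrate-active enzyme
families and count classes (GH, GT, PL, CE, CBM); glycoside hydrolases
are the mucus-degradation signal of interest.

## Two-community decomposition

The density of log2 KO abundances in a tumor group is modeled as a
superposition of two normal components, one per microbial community.
The procedure is deliberately two-stage, not an EM mixture fit:

1. `fit_group_normal()` freezes each community's curve as the sample
   mean/sd of the log2 abundances of that direction's differential KOs
   (LT-direction KOs within LT-group samples, and conversely).
2. `decompose_density()` evaluates a Gaussian KDE (Silverman's
   rule-of-thumb bandwidth, 512-point grid spanning the data range plus
   3 x the wider sd — both exposed) of **all** KOs found in a group and
   regresses it on the two fixed normal densities by **non-negative least
   squares** with no intercept: density amplitudes cannot be negative and
   a mixture of densities has no baseline offset. Identical curves are a
   collinearity error.

The amplitude of a community's curve measures its dominance in the group;
`dominance_report()` reports each curve's LT-group/ST-group amplitude
ratio (and difference — the source analyses do not say which of the two
they print, so both are emitted, and the package's own acceptance surface
relies on synthetic recovery instead of those two printed shift values).

**Identifiability under the null.** When tumor size carries no signal,
the two stage-1 curves are estimated from false-positive KOs drawn from
the same overall mixture and come out nearly collinear. NNLS attribution
between two near-identical regressors is then unidentifiable: tiny
density differences between groups flip which curve receives the
amplitude, so per-curve cross-group ratios are unstable even though the
summed amplitude is stable. This is a property of the two-stage design
itself. Consequently (a) a curve with numerically zero amplitude in both
groups reports a cross-group ratio of 1 (equally absent), and (b) the
package's null-behaviour test fixes well-separated curves (from the
generator's planted communities) and checks that cross-group amplitude
ratios stay near 1 — which they do — rather than asserting stability of
an attribution the model cannot identify. With well-separated curves
(means apart by a few sd, as in the motivating data: sd 2.6 vs 1.3) the
decomposition recovers planted 50/50 mixtures to within a few percent.

## Taxonomy

A contig's read mass is approximated by `length_bp x mean depth`; a
taxon's abundance at a rank is the summed mass of its contigs, normalized
by the sample's total contig mass (columns of the OTU table sum to 1).
Lineages use one fixed 7-rank semicolon dialect with unassigned ranks
pooled into `"unclassified"` — upstream taxonomy tools vary, and a single
dialect keeps rank extraction positional and exact. Differential taxa
reuse the KO machinery with prevalence routing: taxa found in fewer than
50% of included samples go to Fisher (rare), the rest to Mann-Whitney
(common). The 50% threshold is a package choice — the routing criterion
is not specified by the analyses this package systematizes — and is
configurable and recorded in the output. Pathway-representative taxonomy
restricts the mass computation to contigs encoding at least one pathway
KO, renormalizes within that subtotal, and correlates each taxon's
profile with the pathway activity score (Pearson, two-sided).

## Survival

Pathway activity scores are categorized at the first quartile (type-7
linear-interpolation quantile; ties go Low, i.e. score <= Q1 is "Low") —
so the labels are invariant to monotone transforms of the score. BMI
splits at the WHO overweight boundary (>= 25 kg/m2); age and tumor size
at the cohort median. Kaplan-Meier curves per label with a two-group
log-rank test (zero events anywhere yields flat curves and an undefined
statistic, reported as NA), and Cox proportional hazards models with the
Efron tie correction, fitted univariately per covariate: with 41
patients and few events a joint model is fragile, and the question asked
of each pathway or clinical variable is marginal anyway.

## The synthetic cohort generator

`generate_cohort()` is first-class, tested code that emulates the
statistical structure the analysis assumes; it defines the conditions
all recovery tests run under.

* **Two communities.** Community A (mucus-degrading; carried 80% by a
  Clostridiales-like order) and community B (proliferating;
  Bacteroidales-like). Each community-c KO k has a baseline
  `b_k ~ N(mu_c, sigma_c)` on the log2 CPM scale. Defaults
  `sigma_A = 2.6`, `sigma_B = 1.3` are the dispersions reported for the
  large- and small-tumor KO populations in the motivating cohort;
  `mu_A = 4`, `mu_B = 8` place the A mean at half the B mean, matching
  the reported relation, at a depth where Poisson zeros are informative
  but not dominant.
* **Dominance.** Patient tumor sizes are uniform on 1.8-11.5 cm (the
  reported range; n = 41). The community-A mixing weight is
  `w_A = clamp(0.5 + 0.08 x (size - midpoint), 0.05, 0.95)`; a KO's
  latent log2 CPM in a sample is `b_k + log2(2 w_c) + eps`,
  `eps ~ N(0, 0.5)`. At balanced dominance the KO density is exactly the
  community profile; the 0.08/cm slope spreads weights over ~0.11-0.89
  across the size range, a strong but not deterministic signal.
* **Zeros and counts.** A KO is structurally absent from a sample with
  probability `0.6 x (1 - w_c)` — presence carries dominance signal for
  the Fisher route, abundance for the Mann-Whitney route, as in
  zero-inflated microbiome data. Observed gene counts are Poisson with
  mean `CPM x total_reads / 1e6` (total reads log-normal around 2e6);
  each observed KO sits as one gene on its own contig (length uniform
  1000-8000 bp, honoring the >= 1000 bp assembly filter so downstream
  filters are no-ops), whose recorded depth is the realized coverage
  `reads x read_length / length` — contig mass is then exactly
  `read_length x reads`. Per-sample unannotated noise contigs join the
  taxonomy denominator.
* **Clinical and survival.** Stage and nodal status follow logistic
  models in tumor size; RFS is exponential with hazard
  `0.02 x exp(2 (w_A - 0.5))` per month under uniform 36-72 month
  censoring, giving roughly 30% censoring — few enough events to be
  realistic, enough for the models to fit.
* **Determinism.** All draws flow from one seed; identical parameters
  give byte-identical cohorts and pipeline outputs.

What the generator does **not** emulate: compositionality constraints,
phylogenetic correlation between KOs, strain-level variation, batch
effects, or non-log-normal abundance families. The abundance family
itself is an assumption — the analyses operate on log2 abundances and fit
normal curves to them, so log-normality is adopted as the working model.
Passing recovery tests therefore show the pipeline is correct and
well-powered *under its own model*, not that the model is true of any
real cohort.

## Problem sizes and numerical choices

The bundled tests and analysis scripts run the full cohort at 41 patients
with 500 KOs per community (the scale the recovery claims are stated at),
and 60-KO cohorts where only structure matters; multi-seed checks use 20
seeds (10,000 draws for pure-mixture recovery). Degenerate inputs fail
loudly and specifically: zero total reads name the sample, empty pathway
intersections name the pathway, all-equal scores refuse quartile
categorization, constant tables refuse clustering and normal fits, zero
events refuse Cox. Correlation against a zero-variance vector is reported
as undefined (flagged NA) rather than an error, since single degenerate
taxa should not abort a profile-wide scan.

## Reproducing the analysis

The `analysis/` directory holds numbered drivers
(`01_simulate.R` ... `08_survival.R`) that run the workflow over one
simulated cohort and write tables under `results/`; `run_all()` performs
the same sequence in one call with a manifest. `scripts/acceptance.R`
recomputes the worked-example MFA values from scratch.
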