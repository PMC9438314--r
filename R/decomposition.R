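# Two-community decomposition of KO abundance densities.
#
# Stage 1: each direction's differential KOs define a normal curve
# (mean, sd of their log2 abundances) characterizing the molecular
# functions of the community dominating that tumor group. Stage 2: the
# two fixed curves are fitted to the kernel density of all KO abundances
# in each group by non-negative least squares; the fitted amplitudes
# quantify how dominant each community is in the group. This is a
# deliberate two-stage design (curve parameters are not re-estimated
# during the amplitude fit), not a full Gaussian-mixture EM.

#' Fit a normal curve to a set of log2 abundances
#'
#' @param x numeric vector of log2 abundances (>= 3 finite values with
#'   nonzero variance).
#' @param source optional label, e.g. `"LT-abundant"` or `"ST-abundant"`.
#' @return object of class `normal_curve` with fields `mu` (sample
#'   mean), `sigma` (sample sd, denominator n-1), `n`, `source`.
#' @export
fit_group_normal <- function(x, source = NA_character_) {
  x <- x[is.finite(x)]
  if (length(x) < 3L)
    stop("fit_group_normal needs at least 3 finite values")
  s <- sd(x)
  if (s == 0) stop("zero variance: cannot fit a normal curve")
  structure(list(mu = mean(x), sigma = s, n = length(x), source = source),
            class = "normal_curve")
}

#' @export
print.normal_curve <- function(x, ...) {
  cat(sprintf("Normal curve (%s): mu = %.3f, sigma = %.3f, n = %d\n",
              ifelse(is.na(x$source), "unlabelled", x$source),
              x$mu, x$sigma, x$n))
  invisible(x)
}

#' Decompose an abundance density into two fixed normal components
#'
#' Evaluates a Gaussian kernel density of `x` on a regular grid spanning
#' the data range plus 3 times the wider curve's sd, then regresses it on
#' the two normal densities (no intercept: a mixture of densities has no
#' baseline offset) with non-negative least squares. The coefficient
#' scale follows the density scale; the LT/ST coefficient ratio is
#' scale-invariant.
#'
#' @param x numeric vector of log2 abundances (>= 10 values).
#' @param curve_LT,curve_ST [fit_group_normal()] curves; must not be
#'   identical.
#' @param grid_n grid resolution (default 512).
#' @param bandwidth KDE bandwidth; default Silverman's rule-of-thumb
#'   (`stats::bw.nrd0`).
#' @return object of class `decomposition_fit`: `coef_LT`, `coef_ST`
#'   (non-negative amplitudes), `r_squared`, `grid`, `density`,
#'   `fitted`, and the two curves.
#' @export
decompose_density <- function(x, curve_LT, curve_ST, grid_n = 512L,
                              bandwidth = NULL) {
  stopifnot(inherits(curve_LT, "normal_curve"),
            inherits(curve_ST, "normal_curve"))
  x <- x[is.finite(x)]
  if (length(x) < 10L)
    stop("decompose_density needs at least 10 abundance values")
  tol <- 1e-8
  if (abs(curve_LT$mu - curve_ST$mu) < tol &&
      abs(curve_LT$sigma - curve_ST$sigma) < tol)
    stop("collinear design: the two normal curves are identical")
  pad <- 3 * max(curve_LT$sigma, curve_ST$sigma)
  bw <- if (is.null(bandwidth)) stats::bw.nrd0(x) else bandwidth
  d <- density(x, bw = bw, from = min(x) - pad, to = max(x) + pad,
               n = grid_n)
  design <- cbind(LT = dnorm(d$x, curve_LT$mu, curve_LT$sigma),
                  ST = dnorm(d$x, curve_ST$mu, curve_ST$sigma))
  fit <- pracma::lsqnonneg(design, d$y)
  coefs <- fit$x
  fitted <- as.vector(design %*% coefs)
  ss_res <- sum((d$y - fitted)^2)
  ss_tot <- sum((d$y - mean(d$y))^2)
  structure(list(coef_LT = coefs[1], coef_ST = coefs[2],
                 r_squared = 1 - ss_res / ss_tot,
                 grid = d$x, density = d$y, fitted = fitted,
                 curve_LT = curve_LT, curve_ST = curve_ST),
            class = "decomposition_fit")
}

#' @export
print.decomposition_fit <- function(x, ...) {
  cat(sprintf(
    "Two-community decomposition: coef_LT = %.4f, coef_ST = %.4f, R^2 = %.3f\n",
    x$coef_LT, x$coef_ST, x$r_squared))
  invisible(x)
}

# log2 of the strictly positive ("found") entries of selected rows/columns
.log2_found <- function(values, rows = NULL, cols = NULL) {
  v <- values
  if (!is.null(rows)) v <- v[intersect(rows, rownames(v)), , drop = FALSE]
  if (!is.null(cols)) v <- v[, intersect(cols, colnames(v)), drop = FALSE]
  log2(v[v > 0])
}

#' Community dominance across the tumor-size groups
#'
#' Fits the LT-abundant curve on LT-direction KO abundances within the
#' LT-group samples and the ST-abundant curve on ST-direction KOs within
#' the ST-group, then decomposes the density of all KOs found in each
#' group against those two fixed curves. The coefficient ratio of a curve
#' between the groups (LT-group over ST-group) expresses how much more
#' dominant that community is among patients with large tumors.
#'
#' @param groups an [assign_size_groups()] result.
#' @param mfa a normalized `mfa_table`.
#' @param diff a [differential_kos()] result.
#' @param grid_n,bandwidth passed to [decompose_density()].
#' @return list with `curve_LT`, `curve_ST`, `fit_LT_group`,
#'   `fit_ST_group`, the per-curve cross-group coefficient ratios
#'   (`ratio_LT`, `ratio_ST`) and differences (`diff_LT`, `diff_ST`).
#' @export
dominance_report <- function(groups, mfa, diff, grid_n = 512L,
                             bandwidth = NULL) {
  stopifnot(inherits(mfa, "mfa_table"))
  g <- .group_samples(groups)
  sets <- .direction_sets(diff)
  curve_LT <- fit_group_normal(.log2_found(mfa$values, sets$lt, g$lt),
                               source = "LT-abundant")
  curve_ST <- fit_group_normal(.log2_found(mfa$values, sets$st, g$st),
                               source = "ST-abundant")
  fit_lt <- decompose_density(.log2_found(mfa$values, cols = g$lt),
                              curve_LT, curve_ST, grid_n, bandwidth)
  fit_st <- decompose_density(.log2_found(mfa$values, cols = g$st),
                              curve_LT, curve_ST, grid_n, bandwidth)
  # a community with numerically zero amplitude in both groups has an
  # undefined (0/0) cross-group ratio; report 1 (equally absent)
  safe_ratio <- function(a, b) {
    if (a < 1e-10 && b < 1e-10) 1 else a / b
  }
  list(curve_LT = curve_LT, curve_ST = curve_ST,
       fit_LT_group = fit_lt, fit_ST_group = fit_st,
       ratio_LT = safe_ratio(fit_lt$coef_LT, fit_st$coef_LT),
       ratio_ST = safe_ratio(fit_lt$coef_ST, fit_st$coef_ST),
       diff_LT = fit_lt$coef_LT - fit_st$coef_LT,
       diff_ST = fit_lt$coef_ST - fit_st$coef_ST)
}
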