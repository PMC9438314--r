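# Recurrence-free survival: quartile/median/WHO categorization of
# pathway activity scores and clinical variables, Kaplan-Meier curves
# with log-rank tests, and Cox proportional hazards models.

#' Categorize a pathway activity score at the first quartile
#'
#' Observations falling within the first quarter (score <= Q1, linear
#' interpolation quantile, ties going Low) are `"Low"`; the rest are
#' `"High"`. Labels are invariant to monotone transforms of the score.
#'
#' @param scores named per-sample numeric vector with >= 4 values.
#' @return named character vector of `"Low"`/`"High"` labels.
#' @export
categorize_score <- function(scores) {
  if (length(scores) < 4L)
    stop("categorize_score needs at least 4 samples")
  if (length(unique(scores)) == 1L)
    stop("degenerate categorization: all scores are equal")
  q1 <- unname(quantile(scores, 0.25, type = 7))
  setNames(ifelse(scores <= q1, "Low", "High"), names(scores))
}

#' Categorize clinical variables for survival analysis
#'
#' BMI splits at the WHO overweight boundary (>= 25 kg/m2 is
#' `"Overweight/Obese"`); age and tumor size split at the cohort median
#' (<= median is `"Low"`); FIGO stage collapses to I/II vs III/IV and
#' nodal status to Negative/Positive. Degenerate (all-equal) continuous
#' variables are flagged with a warning.
#'
#' @param clinical clinical table (see [read_clinical()]).
#' @return data.frame keyed by `patient_id` with columns `bmi_cat`,
#'   `age_cat`, `tumor_size_cat`, `stage_cat`, `node_cat`.
#' @export
categorize_clinical <- function(clinical) {
  need <- c("patient_id", "age", "bmi", "stage", "tumor_size_cm",
            "node_positive")
  missing <- setdiff(need, names(clinical))
  if (length(missing))
    stop("clinical table lacks variable(s): ", paste(missing, collapse = ", "))
  med_split <- function(x, what) {
    if (length(unique(x)) == 1L) {
      warning("degenerate split: all values of ", what, " are equal")
      return(rep("Low", length(x)))
    }
    ifelse(x <= median(x), "Low", "High")
  }
  data.frame(
    patient_id = clinical$patient_id,
    bmi_cat = ifelse(clinical$bmi >= 25, "Overweight/Obese",
                     "Underweight/Normal weight"),
    age_cat = med_split(clinical$age, "age"),
    tumor_size_cat = med_split(clinical$tumor_size_cm, "tumor size"),
    stage_cat = ifelse(clinical$stage %in% c("III", "IV"), "III/IV", "I/II"),
    node_cat = ifelse(clinical$node_positive, "Positive", "Negative"),
    stringsAsFactors = FALSE
  )
}

.surv_frame <- function(labels, clinical) {
  if (is.null(names(labels)))
    stop("labels must be named by patient_id")
  idx <- match(names(labels), clinical$patient_id)
  if (anyNA(idx))
    stop("clinical table lacks patient(s): ",
         paste(names(labels)[is.na(idx)], collapse = ", "))
  data.frame(time = clinical$rfs_months[idx],
             event = as.integer(clinical$rfs_event[idx]),
             group = labels, stringsAsFactors = FALSE)
}

#' Kaplan-Meier curves and the two-group log-rank test
#'
#' Product-limit estimates per label group and the log-rank statistic
#' for their difference. The p-value is invariant to swapping the group
#' labels.
#'
#' @param labels named `"Low"`/`"High"` (or any two-level) vector keyed
#'   by `patient_id`.
#' @param clinical clinical table with `rfs_months`, `rfs_event`.
#' @return list with `fit` (a [survival::survfit] object), `chisq`, and
#'   the log-rank `p`.
#' @export
km_logrank <- function(labels, clinical) {
  df <- .surv_frame(labels, clinical)
  if (length(unique(df$group)) < 2L || any(table(df$group) == 0L))
    stop("log-rank needs two non-empty groups")
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  if (sum(df$event) == 0L) {
    # no events anywhere: curves are flat at 1 and the statistic undefined
    return(list(fit = fit, chisq = NA_real_, p = NA_real_))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- pchisq(sd$chisq, df = length(sd$n) - 1L, lower.tail = FALSE)
  list(fit = fit, chisq = unname(sd$chisq), p = p)
}

#' Univariate Cox proportional hazards models
#'
#' Fits one Cox model (Efron ties) per supplied covariate against
#' recurrence-free survival and reports the hazard ratio with its 95%
#' Wald confidence interval and p-value. Character/factor covariates are
#' modeled by their levels; continuous ones per unit.
#'
#' @param covariates data.frame of covariates keyed by `patient_id`.
#' @param clinical clinical table with `rfs_months`, `rfs_event` (at
#'   least one event required).
#' @return data.frame `covariate`, `term`, `hr`, `ci_lower`, `ci_upper`,
#'   `p`, `n_events`.
#' @export
cox_ph <- function(covariates, clinical) {
  if (!"patient_id" %in% names(covariates))
    stop("covariates need a patient_id column")
  idx <- match(covariates$patient_id, clinical$patient_id)
  if (anyNA(idx))
    stop("clinical table lacks patient(s): ",
         paste(covariates$patient_id[is.na(idx)], collapse = ", "))
  time <- clinical$rfs_months[idx]
  event <- as.integer(clinical$rfs_event[idx])
  if (sum(event) < 1L) stop("no recurrence events: Cox model is degenerate")
  vars <- setdiff(names(covariates), "patient_id")
  rows <- lapply(vars, function(v) {
    x <- covariates[[v]]
    if (length(unique(x)) < 2L)
      stop("constant covariate: ", v)
    df <- data.frame(time = time, event = event, x = x)
    fit <- survival::coxph(survival::Surv(time, event) ~ x, data = df,
                           ties = "efron")
    if (any(!is.finite(sqrt(diag(fit$var)))) || any(abs(fit$coef) > 15))
      stop("Cox fit failed to converge for covariate ", v,
           " (possible perfect separation)")
    s <- summary(fit)
    data.frame(covariate = v,
               term = sub("^x", "", rownames(s$coefficients)),
               hr = unname(s$coefficients[, "exp(coef)"]),
               ci_lower = unname(s$conf.int[, "lower .95"]),
               ci_upper = unname(s$conf.int[, "upper .95"]),
               p = unname(s$coefficients[, "Pr(>|z|)"]),
               n_events = sum(event),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
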