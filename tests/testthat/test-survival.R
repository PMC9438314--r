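test_that("quartile categorization labels the first quarter Low", {
  s <- setNames(c(1, 2, 3, 4), paste0("p", 1:4))
  lab <- categorize_score(s)
  expect_equal(unname(lab), c("Low", "High", "High", "High"))

  # rank-invariance: any strictly monotone transform keeps the labels
  set.seed(15)
  x <- setNames(rnorm(30), paste0("p", 1:30))
  expect_identical(categorize_score(x), categorize_score(exp(x)))
  expect_identical(categorize_score(x), categorize_score(10 + 3 * x))

  # about a quarter of a large uniform sample lands in Low
  set.seed(16)
  u <- setNames(runif(100), paste0("p", 1:100))
  frac <- mean(categorize_score(u) == "Low")
  expect_gte(frac, 0.20)
  expect_lte(frac, 0.30)

  expect_error(categorize_score(setNames(rep(2, 5), paste0("p", 1:5))),
               "degenerate")
  expect_error(categorize_score(setNames(1:3, paste0("p", 1:3))), "4")
})

test_that("clinical categorization follows WHO and median cut-offs", {
  cl <- data.frame(
    patient_id = paste0("p", 1:4),
    age = c(30, 45, 50, 70),
    bmi = c(24.9, 25.0, 19, 31),
    stage = c("I", "II", "III", "IV"),
    tumor_size_cm = c(2, 4, 6, 9),
    node_positive = c(FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
  cc <- categorize_clinical(cl)
  expect_equal(cc$bmi_cat,
               c("Underweight/Normal weight", "Overweight/Obese",
                 "Underweight/Normal weight", "Overweight/Obese"))
  expect_equal(cc$age_cat, c("Low", "Low", "High", "High"))
  expect_equal(cc$tumor_size_cat, c("Low", "Low", "High", "High"))
  expect_equal(cc$stage_cat, c("I/II", "I/II", "III/IV", "III/IV"))
  expect_equal(cc$node_cat, c("Negative", "Positive", "Negative", "Positive"))

  # the median cut agrees with the direct median on synthetic data
  co <- small_cohort(seed = 27)
  cats <- categorize_clinical(co$clinical)
  med <- median(co$clinical$tumor_size_cm)
  expect_identical(cats$tumor_size_cat,
                   ifelse(co$clinical$tumor_size_cm <= med, "Low", "High"))

  flat <- cl; flat$age <- rep(50, 4)
  expect_warning(categorize_clinical(flat), "degenerate")
  expect_error(categorize_clinical(cl[, -2]), "age")
})

test_that("KM estimates match the hand-computed product-limit toy", {
  # 6 subjects: event times 1, 3, 4, 6; censored at 2 and 5
  clinical <- data.frame(
    patient_id = paste0("p", 1:10),
    rfs_months = c(1, 2, 3, 4, 5, 6, 4, 8, 9, 10),
    rfs_event = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE,
                  TRUE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
  labels <- setNames(rep(c("Low", "High"), c(6, 4)), clinical$patient_id)
  km <- km_logrank(labels, clinical)
  sm <- summary(km$fit)
  low <- sm$surv[grepl("Low", as.character(sm$strata))]
  # hand product-limit: 5/6, 5/6*3/4, 5/12*? -> 5/6, 0.625, 5/12, 0
  expect_equal(low, c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 2 / 3, 0),
               tolerance = 1e-12)
  # curves start at 1 and never increase within a stratum
  per_stratum <- split(km$fit$surv,
                       rep(seq_along(km$fit$strata), km$fit$strata))
  for (s in per_stratum) {
    expect_lte(s[1], 1)
    expect_true(all(diff(s) <= 1e-12))
  }

  # identical survival in both groups: statistic ~ 0, p ~ 1
  cl2 <- data.frame(patient_id = paste0("q", 1:12),
                    rfs_months = rep(c(3, 6, 9, 12, 15, 18), 2),
                    rfs_event = rep(c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE), 2),
                    stringsAsFactors = FALSE)
  lab2 <- setNames(rep(c("Low", "High"), each = 6), cl2$patient_id)
  km2 <- km_logrank(lab2, cl2)
  expect_lt(km2$chisq, 1e-10)
  expect_gt(km2$p, 0.99)

  # label swap leaves the log-rank p unchanged
  lab3 <- setNames(c(Low = "High", High = "Low")[lab2], names(lab2))
  expect_equal(km_logrank(lab3, cl2)$p, km2$p, tolerance = 1e-12)

  # no events at all: curves stay flat at 1
  cl3 <- cl2; cl3$rfs_event <- FALSE
  km3 <- km_logrank(lab2, cl3)
  expect_true(all(km3$fit$surv == 1))

  expect_error(km_logrank(setNames(rep("Low", 12), cl2$patient_id), cl2),
               "two non-empty groups")
})

test_that("Cox models recover hazards and respect degeneracy errors", {
  # known HR = 2 on a large simulated cohort
  set.seed(9)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.05 * 2^x)
  cens <- runif(n, 10, 40)
  cl <- data.frame(patient_id = as.character(1:n),
                   rfs_months = pmin(t_ev, cens),
                   rfs_event = t_ev <= cens, stringsAsFactors = FALSE)
  fit <- cox_ph(data.frame(patient_id = cl$patient_id, x = x), cl)
  expect_gte(fit$hr, 1.6)
  expect_lte(fit$hr, 2.5)

  # rescaling a continuous covariate rescales the log-hazard exactly
  z <- rnorm(n)
  f1 <- cox_ph(data.frame(patient_id = cl$patient_id, z = z), cl)
  f2 <- cox_ph(data.frame(patient_id = cl$patient_id, z = z / 10), cl)
  expect_equal(log(f2$hr), 10 * log(f1$hr), tolerance = 1e-6)
  expect_equal(f1$p, f2$p, tolerance = 1e-8)

  expect_error(cox_ph(data.frame(patient_id = cl$patient_id,
                                 k = rep(1, n)), cl), "constant")
  cl0 <- cl; cl0$rfs_event <- FALSE
  expect_error(cox_ph(data.frame(patient_id = cl$patient_id, x = x), cl0),
               "events")
})

test_that("null-covariate Cox intervals cover 1 and dominance drives hazard", {
  covered <- sapply(1:50, function(s) {
    set.seed(s)
    n <- 100
    x <- rnorm(n)
    t_ev <- rexp(n, 0.05)
    cens <- runif(n, 24, 60)
    cl <- data.frame(patient_id = as.character(1:n),
                     rfs_months = pmin(t_ev, cens),
                     rfs_event = t_ev <= cens, stringsAsFactors = FALSE)
    r <- cox_ph(data.frame(patient_id = cl$patient_id, x = x), cl)
    r$ci_lower <= 1 && r$ci_upper >= 1
  })
  expect_gte(mean(covered), 0.9)

  hr_pos <- sapply(1:10, function(s) {
    co <- small_cohort(seed = 500 + s)
    cox_ph(data.frame(patient_id = co$clinical$patient_id,
                      dominance = unname(co$truth$w_A)), co$clinical)$hr
  })
  expect_gt(mean(hr_pos > 1), 0.5)
})
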