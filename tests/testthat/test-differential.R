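test_that("size-group assignment takes extremes with a stable tie-break", {
  cl <- data.frame(patient_id = sprintf("P%02d", 1:41),
                   tumor_size_cm = seq(1.8, 11.5, length.out = 41))
  g <- assign_size_groups(cl, 14L)
  expect_equal(sum(g$group == "LT"), 14L)
  expect_equal(sum(g$group == "ST"), 14L)
  expect_equal(sum(g$group == "unassigned"), 13L)
  expect_true(min(g$tumor_size_cm[g$group == "LT"]) >=
                max(g$tumor_size_cm[g$group == "ST"]))

  # even split at the median when k = n/2 and sizes are distinct
  cl2 <- data.frame(patient_id = sprintf("P%02d", 1:10),
                    tumor_size_cm = sample(seq(2, 11, length.out = 10)))
  g2 <- assign_size_groups(cl2, 5L)
  expect_true(all(g2$group[g2$tumor_size_cm > median(g2$tumor_size_cm)] == "LT"))
  expect_true(all(g2$group[g2$tumor_size_cm < median(g2$tumor_size_cm)] == "ST"))

  # ties straddling rank k resolve deterministically and survive shuffling
  cl3 <- data.frame(patient_id = sprintf("P%02d", 1:6),
                    tumor_size_cm = c(9, 7, 7, 7, 3, 2))
  g3 <- assign_size_groups(cl3, 2L)
  for (rep in 1:5) {
    perm <- sample(nrow(cl3))
    gp <- assign_size_groups(cl3[perm, ], 2L)
    gp <- gp[match(g3$patient_id, gp$patient_id), ]
    expect_equal(gp$group, g3$group)
  }
  expect_equal(g3$group[g3$patient_id == "P02"], "LT")

  expect_error(assign_size_groups(cl3, 4L), "exceeds")
})

test_that("a fully separating KO gets the hypergeometric point-mass p", {
  # present in all 14 LT samples, absent from all 14 ST samples
  v <- matrix(0, 1, 28, dimnames = list("K1", sprintf("s%02d", 1:28)))
  v[1, 1:14] <- 5
  groups <- setNames(rep(c("LT", "ST"), each = 14), colnames(v))
  d <- differential_kos(mfa_from_matrix(v), groups)
  expect_equal(d$fisher_p, fisher_enum_p(14, 0, 0, 14), tolerance = 1e-12)
  expect_equal(d$fisher_p, stats::dhyper(14, 14, 14, 14) * 2, tolerance = 1e-12)
  expect_equal(d$direction, "LT")
  expect_true(d$selected)
})

test_that("implementation Fisher p matches enumeration across margins <= 14", {
  set.seed(7)
  cases <- expand.grid(n_lt = c(3L, 8L, 14L), n_st = c(3L, 9L, 14L))
  for (i in seq_len(nrow(cases))) {
    n_lt <- cases$n_lt[i]; n_st <- cases$n_st[i]
    for (a in 0:n_lt) {
      for (c0 in 0:n_st) {
        p_impl <- fisher.test(matrix(c(a, n_lt - a, c0, n_st - c0), 2))$p.value
        expect_equal(p_impl, fisher_enum_p(a, n_lt - a, c0, n_st - c0),
                     tolerance = 1e-9,
                     label = sprintf("table (%d/%d vs %d/%d)", a, n_lt, c0, n_st))
      }
    }
  }
})

test_that("differential selection follows the two-test direction rule", {
  set.seed(10)
  samples <- sprintf("s%02d", 1:28)
  groups <- setNames(rep(c("LT", "ST"), each = 14), samples)
  v <- rbind(
    flat = rep(3, 28),                                 # identical: never picked
    lt_shift = c(rnorm(14, 40, 3), rnorm(14, 10, 3)),  # MW route, LT mean higher
    st_prev = c(rep(0, 12), 5, 5, rnorm(14, 8, 1))     # Fisher route, ST prevalent
  )
  colnames(v) <- samples
  v[v < 0] <- 0
  d <- differential_kos(mfa_from_matrix(v), groups)
  d <- d[match(c("flat", "lt_shift", "st_prev"), d$ko_id), ]
  expect_false(d$selected[1])
  expect_true(is.na(d$direction[1]))
  expect_true(d$selected[2])
  expect_equal(d$direction[2], "LT")
  expect_lt(d$mw_p[2], 0.05)
  expect_true(d$selected[3])
  expect_equal(d$direction[3], "ST")
  expect_lt(d$fisher_p[3], 0.05)
  expect_gt(d$prevalence_ST[3], d$prevalence_LT[3])
})

test_that("swapping group labels flips directions and keeps p-values", {
  co <- small_cohort(seed = 6)
  norm <- normalize_mfa(build_mfa(co))
  g <- assign_size_groups(co$clinical)
  swapped <- g
  swapped$group <- c(LT = "ST", ST = "LT",
                     unassigned = "unassigned")[g$group]
  d1 <- differential_kos(norm, g)
  d2 <- differential_kos(norm, swapped)
  d2 <- d2[match(d1$ko_id, d2$ko_id), ]
  expect_equal(d1$fisher_p, d2$fisher_p)
  expect_equal(d1$mw_p, d2$mw_p)
  flip <- c(LT = "ST", ST = "LT")
  has_dir <- !is.na(d1$direction)
  expect_equal(unname(flip[d1$direction[has_dir]]), d2$direction[has_dir])
})

test_that("the number of selected KOs is monotone in alpha", {
  co <- small_cohort(seed = 9)
  norm <- normalize_mfa(build_mfa(co))
  g <- assign_size_groups(co$clinical)
  counts <- sapply(c(0.01, 0.05, 0.1, 0.2),
                   function(a) sum(differential_kos(norm, g, alpha = a)$selected))
  expect_true(all(diff(counts) >= 0))
})

test_that("planted large-tumor community KOs are called LT-directional", {
  co <- generate_cohort(cohort_params(seed = 13))
  norm <- normalize_mfa(build_mfa(co))
  g <- assign_size_groups(co$clinical)
  d <- differential_kos(norm, g)
  A <- names(co$truth$ko_community)[co$truth$ko_community == "A"]
  dA <- d[d$ko_id %in% A, ]
  expect_gte(mean(!is.na(dA$direction) & dA$direction == "LT"), 0.9)
})

test_that("functional richness correlates with tumor size as planted", {
  # a richer community-A repertoire makes large tumors function-richer
  co <- generate_cohort(cohort_params(seed = 17,
                                      n_kos_per_community = c(120L, 60L)))
  mfa <- build_mfa(co)
  fr <- functional_richness(mfa, co$clinical)
  expect_gt(fr$pearson_r, 0)
  expect_equal(fr$richness$richness,
               unname(colSums(mfa$values[, co$clinical$patient_id] != 0)))

  # exact value on a hand-made table
  v <- matrix(c(1, 0, 0, 1, 1, 0, 1, 1, 1), 3, 3,
              dimnames = list(paste0("K", 1:3), paste0("s", 1:3)))
  cl <- data.frame(patient_id = paste0("s", 1:3), tumor_size_cm = c(1, 2, 3),
                   stage = c("I", "II", "III"))
  fr2 <- functional_richness(mfa_table(v), cl)
  expect_equal(fr2$pearson_r, 1.0, tolerance = 1e-12)

  # degenerate richness is flagged, not silently correlated
  v3 <- matrix(1, 2, 3, dimnames = list(paste0("K", 1:2), paste0("s", 1:3)))
  fr3 <- functional_richness(mfa_table(v3), cl)
  expect_true(fr3$undefined)
  expect_true(is.na(fr3$pearson_r))
  expect_error(functional_richness(mfa_table(v[, 1:2]), cl[1:2, ]), "3")
})
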