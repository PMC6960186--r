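test_that("packaged screening cohort has the documented structure", {
  cohort <- load_cohort_table()
  expect_identical(nrow(cohort), 25L)
  expect_identical(sum(cohort$group == "shorter"), 11L)
  expect_identical(sum(cohort$group == "longer"), 14L)
  expect_true(all(cohort$survival_months[cohort$group == "shorter"] >= 15))
  expect_true(all(cohort$survival_months[cohort$group == "shorter"] <= 75))
  expect_true(all(cohort$survival_months[cohort$group == "longer"] >= 101))
  expect_true(all(cohort$survival_months[cohort$group == "longer"] <= 288))
  expect_equal(as.numeric(stats::median(cohort$survival_months)), 101)
  expect_equal(as.numeric(range(cohort$survival_months)), c(15, 288))
  expect_true(all(cohort$ihc_tumor %in% 0:3) && all(cohort$ihc_biopsy %in% 0:3))
  expect_type(cohort$recurrence, "logical")
  expect_identical(sum(!cohort$recurrence), 2L)
})

test_that("cohort loader validates out-of-range records and missing columns", {
  cohort <- load_cohort_table()
  bad <- cohort
  bad$ihc_tumor[3] <- 5
  path <- tempfile(fileext = ".csv")
  write.csv(bad[, 1:6], path, row.names = FALSE)
  expect_error(load_cohort_table(path), "row 3")
  bad2 <- cohort
  bad2$survival_months[7] <- -1
  write.csv(bad2[, 1:6], path, row.names = FALSE)
  expect_error(load_cohort_table(path), "row 7")
  write.csv(cohort[, 1:4], path, row.names = FALSE)
  expect_error(load_cohort_table(path), "missing column")
  # survival inside the unclassified gap warns
  gap <- cohort
  gap$survival_months[1] <- 90
  write.csv(gap[, 1:6], path, row.names = FALSE)
  expect_warning(load_cohort_table(path), "between 75 and 101")
  unlink(path)
})

test_that("aggregate_specimen averages tile metrics arithmetically", {
  tiles <- data.frame(CC = c(0.2, 0.4), CP = c(1, 3))
  sp <- aggregate_specimen(tiles, "P1", "biopsy")
  expect_equal(sp$mean_CC, 0.3)
  expect_equal(sp$mean_CP, 2)
  expect_identical(sp$n_tiles_used, 2L)
  one <- aggregate_specimen(data.frame(CC = 0.7, CP = 2.5), "P1", "primary_tumor")
  expect_equal(one$mean_CC, 0.7)
  expect_error(aggregate_specimen(data.frame(CC = numeric(0), CP = numeric(0)),
                                  "P1", "biopsy"), "empty specimen")
  # mean of many iid tiles concentrates on the true value
  set.seed(41)
  sim <- data.frame(CC = 0.5 + rnorm(100, sd = 0.05), CP = 2 + rnorm(100, sd = 0.1))
  spm <- aggregate_specimen(sim, "P2", "biopsy")
  expect_lt(abs(spm$mean_CC - 0.5), 3 * 0.05 / sqrt(100))
})

test_that("tumor_biopsy_ratios pairs specimens and is order-invariant", {
  specimens <- rbind(
    aggregate_specimen(data.frame(CC = 0.30, CP = 1.2), "A", "primary_tumor"),
    aggregate_specimen(data.frame(CC = 0.30, CP = 0.6), "A", "biopsy"),
    aggregate_specimen(data.frame(CC = 0.10, CP = 2.0), "B", "biopsy"),
    aggregate_specimen(data.frame(CC = 0.25, CP = 2.0), "B", "primary_tumor")
  )
  r <- tumor_biopsy_ratios(specimens)
  expect_equal(r$cc_ratio[r$patient_id == "A"], 1.0)
  expect_equal(r$cp_ratio[r$patient_id == "A"], 2.0)
  expect_equal(r$cc_ratio[r$patient_id == "B"], 2.5)
  shuffled <- tumor_biopsy_ratios(specimens[c(3, 1, 4, 2), ])
  m <- merge(r, shuffled, by = "patient_id")
  expect_equal(m$cc_ratio.x, m$cc_ratio.y)
  expect_error(tumor_biopsy_ratios(specimens[1:3, ]), "unpaired")
  degen <- specimens
  degen$mean_CC[2] <- 0
  expect_error(tumor_biopsy_ratios(degen), "degenerate ratio")
})

test_that("subgroup association reports Pearson R and the sign-test closed form", {
  set.seed(44)
  surv <- c(10, 20, 30, 40, 50)
  expect_equal(subgroup_association(surv * 0.01 + 1, surv)$R, 1)
  a11 <- subgroup_association(runif(11, 0.9, 1.1), seq(15, 75, length.out = 11))
  expect_equal(a11$p_sign, 9.765625e-04, tolerance = 1e-10)
  a14 <- subgroup_association(runif(14, 0.9, 1.1), seq(101, 288, length.out = 14))
  expect_equal(a14$p_sign, 1.220703125e-04, tolerance = 1e-10)
  expect_identical(a14$n, 14L)
  expect_error(subgroup_association(c(1, 2), c(3, 4)), "group too small")
  expect_error(subgroup_association(rep(1, 5), surv), "undefined correlation")
})

test_that("permutation p-value flags a perfect association", {
  surv <- seq(10, 140, by = 10)
  a <- subgroup_association(surv / 100, surv, n_perm = 999, seed = 5)
  expect_lt(a$p_perm, 0.01)
  b <- subgroup_association(c(1.2, 0.8, 1.1, 0.9, 1.05, 0.95, 1, 1.3),
                            c(50, 60, 40, 70, 55, 45, 65, 52), n_perm = 999, seed = 5)
  expect_gt(b$p_perm, 0.05)
})

test_that("survival_range_probability reproduces worked k/n examples", {
  # 15 patients in the ratio band, 11 of them in the survival band
  ratios <- data.frame(patient_id = 1:20,
                       cc_ratio = c(rep(1, 15), rep(2, 5)))
  cohort <- data.frame(patient_id = 1:20,
                       survival_months = c(rep(150, 11), rep(50, 4), rep(150, 5)))
  p <- survival_range_probability(ratios, cohort, "cc_ratio", c(0.97, 1.05), c(101, 288))
  expect_identical(p$k, 11L)
  expect_identical(p$n, 15L)
  expect_equal(p$probability, 11 / 15, tolerance = 1e-12)
  expect_equal(round(p$probability, 4), 0.7333)
  # 9 in band, 7 surviving long
  ratios2 <- data.frame(patient_id = 1:12, cp_ratio = c(rep(1.05, 9), rep(3, 3)))
  cohort2 <- data.frame(patient_id = 1:12,
                        survival_months = c(rep(200, 7), rep(60, 2), rep(200, 3)))
  p2 <- survival_range_probability(ratios2, cohort2, "cp_ratio", c(0.99, 1.10), c(126, 288))
  expect_equal(p2$probability, 7 / 9, tolerance = 1e-12)
  expect_equal(round(p2$probability, 4), 0.7778)
})

test_that("survival_range_probability is order-invariant and monotone in the band", {
  set.seed(43)
  ratios <- data.frame(patient_id = 1:30, cc_ratio = runif(30, 0.8, 1.3))
  cohort <- data.frame(patient_id = 1:30, survival_months = sample(10:300, 30))
  p1 <- survival_range_probability(ratios, cohort, "cc_ratio", c(0.9, 1.2), c(100, 200))
  perm <- sample(30)
  p2 <- survival_range_probability(ratios[perm, ], cohort[sample(30), ],
                                   "cc_ratio", c(0.9, 1.2), c(100, 200))
  expect_identical(p1, p2)
  # widening the survival band can only add successes
  p_wide <- survival_range_probability(ratios, cohort, "cc_ratio", c(0.9, 1.2), c(100, 300))
  expect_gte(p_wide$probability, p1$probability)
  # all-covering bands give probability 1
  p_all <- survival_range_probability(ratios, cohort, "cc_ratio", c(0, 2), c(0, 1000))
  expect_equal(p_all$probability, 1)
  expect_error(survival_range_probability(ratios, cohort, "cc_ratio", c(5, 6), c(0, 10)),
               "empty denominator")
})
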