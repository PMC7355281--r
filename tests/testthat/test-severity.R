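test_that("difference summary matches hand arithmetic and handles degenerate input", {
  coh <- make_cohort(c(40, 55), c(45.5, 49.5),
                     config = analysis_config())
  coh$raw_t1 <- c(10, 30); coh$raw_t2 <- c(20, 10)  # toy raw values
  ds <- difference_summary(coh, "raw")
  expect_equal(ds$mean_absdiff, 15.0)
  expect_equal(ds$sd_absdiff, sqrt(((10 - 15)^2 + (20 - 15)^2) / 1))  # 7.0711
  same <- make_cohort(c(50, 60, 70), c(50, 60, 70))
  ds0 <- difference_summary(same, "T")
  expect_equal(ds0$mean_absdiff, 0)
  expect_equal(ds0$sd_absdiff, 0)
  one <- make_cohort(55, 60)
  expect_error(difference_summary(one, "T"), "at least 2")
  # histogram densities integrate to 1
  epi <- generate_preset_cohort("epidemiologic", seed = 21)
  h <- difference_summary(epi, "raw", bin_width = 5)$histogram
  expect_equal(sum(h$density) * 5, 1, tolerance = 1e-9)
})

test_that("calibrated cohorts recover the difference summaries of both sampling regimes", {
  epi <- generate_preset_cohort("epidemiologic", seed = 31, n_pairs = 1e4)
  ds <- difference_summary(epi, "raw")
  expect_lt(abs(ds$mean_absdiff - 7.7), 3 * ds$sd_absdiff / sqrt(ds$n_pairs))
  cl <- generate_preset_cohort("clinical_combined", seed = 32, n_pairs = 1e4)
  dc <- difference_summary(cl, "raw")
  expect_lt(abs(dc$mean_absdiff - 33.0), 3 * dc$sd_absdiff / sqrt(dc$n_pairs))
})

test_that("twin correlations: perfect agreement, pipeline r-squared, and clinical recovery", {
  perf <- make_cohort(c(40, 55, 70, 85), c(40, 55, 70, 85))
  r <- twin_correlation(perf, "SRS_total")
  expect_equal(r$r, 1)
  expect_equal(r$r2_percent, 100L)
  cl <- generate_preset_cohort("clinical_combined", seed = 41, n_pairs = 1e4)
  rc <- twin_correlation(cl, "SRS_total")
  expect_lt(abs(rc$r - 0.27), 3 * (1 - 0.27^2) / sqrt(1e4))
  const <- make_cohort(c(50, 50, 50), c(51, 55, 60))
  expect_error(twin_correlation(const, "SRS_total"), "zero variance")
  expect_error(twin_correlation(make_cohort(c(50, 60), c(51, 61)), "SRS_total"),
               "at least 3")
})

test_that("familiality arithmetic matches the printed conventions", {
  expect_equal(familiality_variance(0.754), 57L)
  expect_equal(familiality_variance(0.27), 7L)
  expect_equal(familiality_variance(0), 0L)
  expect_equal(familiality_variance(1), 100L)
  expect_equal(familiality_variance(-0.5), familiality_variance(0.5))
  expect_error(familiality_variance(1.2), "<= 1")
})

test_that("Pearson r is affine-invariant across raw/T scales; Spearman survives monotone rescaling", {
  coh <- generate_preset_cohort("epidemiologic", seed = 51)
  r_t <- twin_correlation(coh, "SRS_total", scale = "T")$r
  r_raw <- twin_correlation(coh, "SRS_total", scale = "raw")$r
  expect_equal(r_t, r_raw, tolerance = 1e-12)
  cp1 <- stats::cor(coh$score_t1, coh$score_t2, method = "spearman")
  cp2 <- stats::cor(exp(coh$score_t1 / 20), exp(coh$score_t2 / 20),
                    method = "spearman")
  expect_equal(cp1, cp2, tolerance = 1e-12)
})

test_that("double-entry ICC is invariant to within-pair order; Pearson need not be", {
  set.seed(61)
  coh <- generate_preset_cohort("IAN", seed = 62)
  swap <- runif(nrow(coh)) < 0.5
  df <- tibble::as_tibble(coh)
  tmp <- df$score_t1[swap]
  df$score_t1[swap] <- df$score_t2[swap]
  df$score_t2[swap] <- tmp
  shuffled <- twin_cohort(df, label = "IAN-shuffled", config = analysis_config(),
                          validate = FALSE)
  icc_a <- twin_correlation(coh, "SRS_total", "icc_double_entry")$r
  icc_b <- twin_correlation(shuffled, "SRS_total", "icc_double_entry")$r
  expect_equal(icc_a, icc_b, tolerance = 1e-12)
})

test_that("estimated twin correlation converges to the generator target with n", {
  p <- calibrate_generator(0.6, 12)
  for (n in c(100, 1000, 10000)) {
    coh <- generate_cohort(p, n, seed = 70 + n)
    r <- cor(coh$score_t1, coh$score_t2)
    expect_lt(abs(r - 0.6), 3 * (1 - 0.6^2) / sqrt(n))
  }
})

test_that("severity/difference association: monotone toy, null without regime, positive sign with regime", {
  # |d| strictly increasing in pair mean by construction
  mono <- make_cohort(c(50, 55, 60, 65, 70) - c(1, 2, 3, 4, 5),
                      c(50, 55, 60, 65, 70) + c(1, 2, 3, 4, 5))
  expect_equal(severity_difference_association(mono)$rho, 1)
  # no regime effect: rho ~ 0 across replicates
  p_flat <- calibrate_generator(0.5, 10)
  set.seed(81)
  rhos <- replicate(30, {
    coh <- generate_cohort(p_flat, 400, seed = sample.int(1e6, 1))
    severity_difference_association(coh)$rho
  })
  expect_lt(abs(mean(rhos)), 3 * sd(rhos) / sqrt(length(rhos)))
  # amplified regime in the epidemiologic preset: positive in >= 95% of replicates
  set.seed(82)
  pos <- replicate(200, {
    coh <- generate_preset_cohort("epidemiologic",
                                  seed = sample.int(1e6, 1), n_pairs = 5000)
    severity_difference_association(coh)$rho > 0
  })
  expect_gte(mean(pos), 0.95)
  # clinical preset (single regime): association stays near zero
  set.seed(83)
  rhos_cl <- replicate(30, {
    coh <- generate_preset_cohort("clinical_combined",
                                  seed = sample.int(1e6, 1), n_pairs = 400)
    severity_difference_association(coh)$rho
  })
  expect_lt(abs(mean(rhos_cl)), 0.1)
})

test_that("age associations: null by construction, identity toy, degenerate error", {
  coh <- generate_preset_cohort("clinical_combined", seed = 91, n_pairs = 2000)
  aa <- age_association(coh)
  expect_lt(abs(aa$pearson_r), 3 / sqrt(2000))
  expect_lt(abs(aa$spearman_rho), 3 / sqrt(2000))
  # |d| equal to age gives r = 1
  ages <- c(4, 6, 8, 10, 12)
  toy <- make_cohort(rep(60, 5) - ages / 2, rep(60, 5) + ages / 2, ages = ages)
  expect_equal(age_association(toy)$pearson_r, 1, tolerance = 1e-12)
  const <- make_cohort(c(50, 60, 70, 55, 65), c(52, 62, 72, 57, 67),
                       ages = rep(8, 5))
  expect_error(age_association(const), "constant")
})
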