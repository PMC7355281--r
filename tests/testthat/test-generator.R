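test_that("closed-form calibration reproduces the stated component SDs", {
  p <- calibrate_generator(0.754, 7.7)
  expect_equal(p$sd_diff_below, 7.7 * sqrt(pi / 2), tolerance = 1e-12)
  expect_equal(p$sd_diff_below, 9.651, tolerance = 1e-4)
  expect_equal(p$sd_severity, 12.8845, tolerance = 1e-4)
  # r = 0 degenerates to sigma_mu^2 = sigma_d^2 / 4 exactly
  p0 <- calibrate_generator(0, 12)
  expect_equal(p0$sd_severity^2, p0$sd_diff_below^2 / 4, tolerance = 1e-12)
  expect_error(calibrate_generator(1, 10), "degenerate")
  expect_error(calibrate_generator(-0.1, 10), "not supported")
  expect_error(calibrate_generator(0.5, 0), "> 0")
})

test_that("calibration moments check out against brute-force Monte Carlo", {
  # independent route: draw directly from the mu/d model and compare moments
  p <- calibrate_generator(0.754, 7.7)
  set.seed(101)
  n <- 2e5
  mu <- rnorm(n, 0, p$sd_severity)
  d <- rnorm(n, 0, p$sd_diff_below)
  t1 <- mu + d / 2; t2 <- mu - d / 2
  se_absdiff <- sd(abs(d)) / sqrt(n)
  expect_lt(abs(mean(abs(d)) - 7.7), 3 * se_absdiff)
  se_r <- (1 - 0.754^2) / sqrt(n)
  expect_lt(abs(cor(t1, t2) - 0.754), 3 * se_r)
})

test_that("clinical calibration implies a T-score SD consistent with a clinical population", {
  cfg <- analysis_config()
  p <- calibrate_generator(0.27, 33.0, cfg, mean_t = 78)
  implied_sd_t <- cfg$raw_to_t_slope * sqrt(p$sd_severity^2 + p$sd_diff_below^2 / 4)
  expect_gt(implied_sd_t, 17.5)
  expect_lt(implied_sd_t, 19.5)
})

test_that("generated cohorts recover the calibration targets within 3 SE at n = 10^4", {
  cfg <- analysis_config()
  for (tgt in list(c(r = 0.754, m = 7.7, mean_t = 49),
                   c(r = 0.27, m = 33.0, mean_t = 78))) {
    p <- calibrate_generator(tgt[["r"]], tgt[["m"]], cfg, mean_t = tgt[["mean_t"]])
    coh <- generate_cohort(p, 1e4, cfg, seed = 20191218)
    absdiff <- abs(coh$raw_t1 - coh$raw_t2)
    expect_lt(abs(mean(absdiff) - tgt[["m"]]), 3 * sd(absdiff) / sqrt(1e4))
    se_r <- (1 - tgt[["r"]]^2) / sqrt(1e4)
    expect_lt(abs(cor(coh$score_t1, coh$score_t2) - tgt[["r"]]), 3 * se_r)
  }
})

test_that("preset cohorts keep target moments under the regime mixture", {
  coh <- generate_preset_cohort("epidemiologic", seed = 77, n_pairs = 1e4)
  absdiff <- abs(coh$raw_t1 - coh$raw_t2)
  expect_lt(abs(mean(absdiff) - 7.7), 3 * sd(absdiff) / sqrt(1e4))
  expect_lt(abs(cor(coh$score_t1, coh$score_t2) - 0.754),
            3 * (1 - 0.754^2) / sqrt(1e4))
  # study-sized draw has the right shape too (looser, small n)
  small <- generate_preset_cohort("epidemiologic", seed = 78)
  expect_equal(nrow(small), 288)
  expect_lt(abs(mean(abs(small$raw_t1 - small$raw_t2)) - 7.7),
            3 * 10.1 / sqrt(288))
})

test_that("identical seeds give identical cohorts; different seeds differ", {
  p <- calibrate_generator(0.5, 10)
  a <- generate_cohort(p, 200, seed = 42)
  b <- generate_cohort(p, 200, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(p, 200, seed = 43)
  expect_false(identical(a$score_t1, c$score_t1))
})

test_that("raw and T columns satisfy the affine map exactly after generation", {
  cfg <- analysis_config()
  coh <- generate_preset_cohort("clinical_combined", cfg, seed = 5, n_pairs = 2000)
  expect_equal(coh$score_t1, raw_to_t(coh$raw_t1, cfg), tolerance = 1e-9)
  expect_equal(coh$score_t2, raw_to_t(coh$raw_t2, cfg), tolerance = 1e-9)
  expect_true(all(coh$score_t1 >= cfg$t_range[1] & coh$score_t1 <= cfg$t_range[2]))
})

test_that("subscale and ADOS structure hit their target correlations", {
  coh <- generate_preset_cohort("AGRE", seed = 9, n_pairs = 2e4)
  r_sci <- cor(coh$sci_t1, coh$sci_t2)
  r_rrb <- cor(coh$rrb_t1, coh$rrb_t2)
  expect_lt(abs(r_sci^2 - 0.06), 3 * 0.01)
  expect_lt(abs(r_rrb^2 - 0.20), 3 * 0.012)
  r_ados <- cor(coh$ados_t1, coh$ados_t2)
  expect_lt(abs(r_ados - 0.21), 0.04)  # rounding/clamping to 0-20 adds a little bias
})

test_that("regime amplification is monotone: larger sigma1/sigma0 means larger above-threshold differences and weaker above-threshold correlation", {
  cfg <- analysis_config()
  stats_at <- function(ratio) {
    p <- calibrate_generator(0.27, 33.0, cfg, regime_ratio = ratio, mean_t = 78)
    coh <- generate_cohort(p, 2e4, cfg, seed = 1234)
    above <- coh$score_t1 >= 65 & coh$score_t2 >= 65
    c(mean(abs(coh$raw_t1 - coh$raw_t2)[above]),
      cor(coh$score_t1[above], coh$score_t2[above]))
  }
  res <- vapply(c(1, 2, 4), stats_at, numeric(2))
  expect_true(all(diff(res[1, ]) > 0))
  expect_true(all(diff(res[2, ]) < 0))
})

test_that("reclassification fixture has the documented deterministic structure", {
  fix <- make_reclassification_fixture()
  expect_equal(nrow(fix), 23)
  rep_disc <- fix$dx_t1 != fix$dx_t2
  expect_equal(sum(rep_disc), 9)
  lower <- pmin(fix$score_t1, fix$score_t2)
  diff_t <- abs(fix$score_t1 - fix$score_t2)
  expect_equal(sum(rep_disc & lower > 65), 3)
  expect_equal(sum(rep_disc & lower <= 65 & diff_t < 18.1), 4)
  expect_equal(sum(rep_disc & lower <= 65 & diff_t >= 18.1), 2)
  # hard-coded, hence identical across calls
  expect_identical(as.data.frame(fix), as.data.frame(make_reclassification_fixture()))
})
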