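# Frozen Monte-Carlo oracle for the correlation of a standard bivariate
# normal truncated to {X >= h, Y >= h}: 10^7 rejection draws per cell,
# computed once with an independent brute-force sampler. `se` is the MC
# standard error of each frozen value.
BVN_BOTH_ABOVE_ORACLE <- tibble::tribble(
  ~rho,  ~h,   ~r_mc,    ~se,
  0.00,  0.0, -0.0001,  0.0006,
  0.00,  1.0, -0.0020,  0.0020,
  0.00,  1.5,  0.0040,  0.0047,
  0.40,  0.0,  0.1976,  0.0005,
  0.40,  1.0,  0.1230,  0.0013,
  0.40,  1.5,  0.0981,  0.0026,
  0.77,  0.0,  0.5532,  0.0004,
  0.77,  1.0,  0.4238,  0.0008,
  0.77,  1.5,  0.3669,  0.0015
)

test_that("the truncated-BVN quadrature matches the frozen Monte-Carlo oracle", {
  for (i in seq_len(nrow(BVN_BOTH_ABOVE_ORACLE))) {
    row <- BVN_BOTH_ABOVE_ORACLE[i, ]
    got <- bvn_truncated_corr(row$rho, row$h, "both_above")
    expect_lt(abs(got - row$r_mc), 3 * row$se,
              label = sprintf("quadrature at rho=%g h=%g (got %.4f, MC %.4f)",
                              row$rho, row$h, got, row$r_mc))
  }
})

test_that("single truncation agrees with the classical selection formula", {
  # independent closed form: X selected above h, Y = rho X + e
  for (rho in c(0.3, 0.77)) for (h in c(0, 1.5)) {
    lam <- dnorm(h) / pnorm(h, lower.tail = FALSE)
    vx <- 1 + h * lam - lam^2
    expected <- rho * sqrt(vx) / sqrt(rho^2 * vx + 1 - rho^2)
    expect_equal(bvn_truncated_corr(rho, h, "one_above"), expected,
                 tolerance = 1e-6)
  }
})

test_that("truncated-BVN limits behave: independence, no truncation, near-degeneracy", {
  for (h in c(-1, 0, 1.5)) {
    expect_lt(abs(bvn_truncated_corr(0, h, "both_above")), 1e-6)
    expect_lt(abs(bvn_truncated_corr(0, h, "one_above")), 1e-6)
  }
  expect_equal(bvn_truncated_corr(0.5, -8), 0.5, tolerance = 1e-4)
  expect_gt(bvn_truncated_corr(0.999, 1), 0.99)
  expect_error(bvn_truncated_corr(1, 1), "< 1")
  expect_error(bvn_truncated_corr(0.5, Inf), "finite")
})

test_that("attenuation is monotone toward zero as the threshold rises", {
  hs <- c(-2, 0, 1, 1.5, 2)
  for (rho in c(0.4, 0.77)) {
    vals <- vapply(hs, function(h) bvn_truncated_corr(rho, h), numeric(1))
    expect_true(all(diff(vals) < 1e-6))
    expect_true(all(vals > -1e-6))
  }
})

test_that("copula calibration hits the constraint and is deterministic", {
  pool <- synthetic_score_pool(seed = 13)
  cal <- calibrate_latent_rho(pool, 0.77, seed = 13)
  expect_lt(abs(cal$realized_r - 0.77), 0.01)
  pairs <- simulate_constrained_pairs(pool, 0.77, n = 1e4, seed = 14,
                                      rho_latent = cal$rho_latent)
  expect_lt(abs(cor(pairs[, 1], pairs[, 2]) - 0.77), 0.02)
  again <- simulate_constrained_pairs(pool, 0.77, n = 1e4, seed = 14,
                                      rho_latent = cal$rho_latent)
  expect_identical(pairs, again)
  # independence case
  p0 <- simulate_constrained_pairs(pool, 0, n = 1e5, seed = 15)
  expect_lt(abs(attr(p0, "rho_latent")), 0.02)
  expect_lt(abs(cor(p0[, 1], p0[, 2])), 0.01)
  # marginals are preserved exactly (with-replacement semantics)
  expect_true(all(pairs %in% pool$values))
  # a nearly constant pool cannot reach a high correlation... but a constant
  # pool is rejected outright
  expect_error(score_pool(rep(60, 500)), "degenerate")
})

test_that("standard-normal-pool simulation reproduces the latent correlation nearly unchanged", {
  # exact normal quantile grid as the pool: the copula map is the identity
  # up to discretization
  pool <- score_pool(qnorm(ppoints(2e4)) * 10 + 65, scale = "T",
                     source = "synthetic_population")
  pairs <- simulate_constrained_pairs(pool, 0.77, n = 1e5, seed = 16)
  expect_lt(abs(attr(pairs, "rho_latent") - 0.77), 0.02)
  expect_lt(abs(cor(pairs[, 1], pairs[, 2]) - 0.77), 0.01)
})

test_that("truncation of simulated pairs matches the analytic oracle on a normal pool", {
  pool <- score_pool(qnorm(ppoints(2e4)), scale = "T",
                     source = "synthetic_population")
  for (rho in c(0, 0.4, 0.77)) for (h in c(0, 1, 1.5)) {
    pairs <- simulate_constrained_pairs(pool, rho, n = 1e5,
                                        seed = 1000 + round(100 * rho) + round(10 * h),
                                        rho_latent = rho)
    tc <- truncated_correlation(pairs, h)
    oracle <- bvn_truncated_corr(rho, h, "both_above")
    mc_se <- (1 - oracle^2) / sqrt(tc$n_survivors)
    expect_lt(abs(tc$r_truncated - oracle), 3 * mc_se,
              label = sprintf("sim vs oracle at rho=%g h=%g", rho, h))
  }
})

test_that("truncated_correlation handles identity and degenerate cases", {
  pool <- synthetic_score_pool(seed = 17)
  pairs <- simulate_constrained_pairs(pool, 0.5, n = 1e4, seed = 18)
  # threshold below the pool minimum keeps everything
  tc <- truncated_correlation(pairs, min(pool$values) - 1)
  expect_equal(tc$n_survivors, 1e4)
  expect_equal(tc$r_truncated, cor(pairs[, 1], pairs[, 2]), tolerance = 1e-12)
  expect_error(truncated_correlation(pairs, max(pool$values) + 1),
               "insufficient survivors")
  degen <- cbind(c(70, 75, 80, 85), rep(70, 4))
  expect_error(truncated_correlation(degen, 60), "constant")
})

test_that("expected vs observed packages the comparison; self-comparison closes", {
  cfg <- analysis_config()
  pool <- synthetic_score_pool(seed = 19)
  res <- expected_vs_observed(pool, 0.77, 65, config = cfg, n = 1e4, seed = 20)
  expect_lt(abs(res$r_full - 0.77), 0.02)
  expect_true(res$n_survivors <= res$n_simulated)
  expect_true(is.na(res$r_observed))
  # feeding the simulated pairs back as the "observed" cohort reproduces
  # the truncated correlation
  pairs <- simulate_constrained_pairs(pool, 0.77, n = 1e4, seed = 20,
                                      rho_latent = res$latent_rho)
  self <- twin_cohort(tibble::tibble(
    pair_id = sprintf("s%05d", seq_len(nrow(pairs))),
    cohort = "other", score_t1 = pairs[, 1], score_t2 = pairs[, 2]
  ), config = cfg, validate = FALSE)
  res2 <- expected_vs_observed(pool, 0.77, 65, observed_cohort = self,
                               config = cfg, n = 1e4, seed = 20,
                               rho_latent = res$latent_rho)
  expect_equal(res2$r_observed, res2$r_truncated, tolerance = 1e-12)
})
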